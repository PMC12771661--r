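.row_max <- function(m) do.call(pmax, as.data.frame(m))

# Core IndVal computation shared by the observed statistic and the
# permutation null. Returns A (specificity, group-mean corrected), B
# (fidelity), stat = sqrt(A * B) as species x group matrices.
.indval_core <- function(comm, groups) {
  lev <- levels(groups)
  mean_cov <- vapply(lev, function(g) colMeans(comm[groups == g, , drop = FALSE]),
                     numeric(ncol(comm)))
  occ <- vapply(lev, function(g) colMeans(comm[groups == g, , drop = FALSE] > 0),
                numeric(ncol(comm)))
  A <- mean_cov / rowSums(mean_cov)
  list(A = A, B = occ, stat = sqrt(A * occ))
}

#' Dufrene-Legendre indicator value statistic
#'
#' Per species and group g: specificity `A_g` is the group mean cover
#' divided by the sum of group mean covers (the group-size-corrected
#' variant), fidelity `B_g` is the fraction of g's plots where the species
#' occurs, and the indicator value is `sqrt(A_g * B_g)`. The species'
#' reported group is the one maximizing the statistic; ties are broken
#' toward the earlier factor level, with a message. The classic sum-based
#' specificity (sensitive to unequal group sizes) is available via
#' `size_corrected = FALSE`.
#'
#' @param comm Plot x species cover matrix.
#' @param groups Group label per plot; >= 2 groups, each with >= 1 plot.
#' @param size_corrected Use group means in A (default `TRUE`).
#' @return Data frame: `species`, `best_group`, `A`, `B`, `stat`. Species
#'   with zero total cover are dropped with a warning.
#' @export
indval_stat <- function(comm, groups, size_corrected = TRUE) {
  comm <- validate_community(comm)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(groups) != nrow(comm)) stop("need one group label per plot")
  zero <- colSums(comm) == 0
  if (any(zero)) {
    warning("excluding species with zero total cover: ",
            paste(colnames(comm)[zero], collapse = ", "))
    comm <- comm[, !zero, drop = FALSE]
  }
  if (!size_corrected) {
    # classic variant: A from group cover sums rather than means
    core <- .indval_core_sums(comm, groups)
  } else {
    core <- .indval_core(comm, groups)
  }
  best <- max.col(core$stat, ties.method = "first")
  rowmax <- .row_max(core$stat)
  ties <- rowSums(core$stat == rowmax) > 1
  if (any(ties))
    message("best-group ties broken toward the first group for: ",
            paste(colnames(comm)[ties], collapse = ", "))
  idx <- cbind(seq_len(ncol(comm)), best)
  data.frame(species = colnames(comm),
             best_group = levels(groups)[best],
             A = core$A[idx], B = core$B[idx], stat = core$stat[idx],
             stringsAsFactors = FALSE)
}

.indval_core_sums <- function(comm, groups) {
  lev <- levels(groups)
  sum_cov <- vapply(lev, function(g) colSums(comm[groups == g, , drop = FALSE]),
                    numeric(ncol(comm)))
  occ <- vapply(lev, function(g) colMeans(comm[groups == g, , drop = FALSE] > 0),
                numeric(ncol(comm)))
  A <- sum_cov / rowSums(sum_cov)
  list(A = A, B = occ, stat = sqrt(A * occ))
}

#' Indicator species analysis with a permutation test
#'
#' Observed indicator values per [indval_stat()]; significance from
#' permuting group labels across plots (the same permutations are shared by
#' all species), with `p = (1 + #{permuted max-group stat >= observed}) /
#' (n_perm + 1)`.
#'
#' @param comm Plot x species cover matrix.
#' @param groups Group label per plot.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @param size_corrected Use group-mean specificity (default `TRUE`).
#' @return Data frame of class `indval_result`: columns of [indval_stat()]
#'   plus `p_value`.
#' @export
indval_test <- function(comm, groups, n_perm = 999, seed = NULL,
                        size_corrected = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- indval_stat(comm, groups, size_corrected = size_corrected)
  comm <- validate_community(comm)
  comm <- comm[, obs$species, drop = FALSE]
  groups <- factor(groups)
  if (!is.null(seed)) set.seed(seed)
  core_fun <- if (size_corrected) .indval_core else .indval_core_sums
  obs_max <- .row_max(core_fun(comm, groups)$stat)
  exceed <- integer(length(obs_max))
  n <- nrow(comm)
  for (b in seq_len(n_perm)) {
    gp <- groups[sample.int(n)]
    perm_max <- .row_max(core_fun(comm, gp)$stat)
    exceed <- exceed + (perm_max >= obs_max - 1e-12)
  }
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  attr(obs, "n_perm") <- n_perm
  class(obs) <- c("indval_result", "data.frame")
  obs
}

#' Filter indicator species on significance, specificity and fidelity
#'
#' Retains species with `p_value < alpha_level`, `A >= min_A` and
#' `B >= min_B`. The occurrence threshold is applied as "retain B >= 0.25",
#' i.e. species with relative occurrence below 0.25 are excluded, in
#' parallel with the relative-abundance clause.
#'
#' @param results An `indval_result` from [indval_test()].
#' @param min_A Minimum specificity (default 0.6).
#' @param min_B Minimum fidelity (default 0.25).
#' @param alpha_level Significance threshold (default 0.05).
#' @return `results` with a logical `retained` column.
#' @export
filter_indicators <- function(results, min_A = 0.6, min_B = 0.25,
                              alpha_level = 0.05) {
  stopifnot(all(c("A", "B", "p_value") %in% names(results)))
  results$retained <- results$p_value < alpha_level &
    results$A >= min_A & results$B >= min_B
  results
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else `n.s.`.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' Indicator-species table for reporting
#'
#' Long-format table mirroring a publication layout: species, group, A, B,
#' IndVal with significance stars, p.
#'
#' @param results An `indval_result`, optionally filtered.
#' @param retained_only Keep only retained species if a `retained` column
#'   is present (default `TRUE`).
#' @return Data frame sorted by group then decreasing IndVal.
#' @export
indval_table <- function(results, retained_only = TRUE) {
  df <- as.data.frame(results)
  if (retained_only && "retained" %in% names(df)) df <- df[df$retained, ]
  df <- df[order(df$best_group, -df$stat), ]
  data.frame(species = df$species, group = df$best_group,
             A = round(df$A, 3), B = round(df$B, 3),
             IndVal = round(df$stat, 3),
             p_value = df$p_value,
             significance = significance_stars(df$p_value),
             stringsAsFactors = FALSE, row.names = NULL)
}
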
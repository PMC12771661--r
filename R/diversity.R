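#' Taxonomic dissimilarity matrix
#'
#' The 0/1 species dissimilarity under which Rao's quadratic entropy reduces
#' to the Gini-Simpson index: d_ij = 1 for i != j and 0 on the diagonal.
#'
#' @param species Character vector of unique species labels.
#' @return A species x species matrix.
#' @export
taxonomic_dissimilarity <- function(species) {
  species <- as.character(species)
  if (length(species) < 1) stop("need at least one species")
  if (anyDuplicated(species)) stop("species labels must be unique")
  d <- 1 - diag(length(species))
  dimnames(d) <- list(species, species)
  d
}

#' Relative abundances within one plot
#'
#' @param x Non-negative cover vector for one plot.
#' @return Proportions summing to one.
#' @export
relative_abundance <- function(x) {
  if (any(x < 0)) stop("covers must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("plot has zero total cover")
  x / s
}

#' Rao's quadratic entropy
#'
#' Q = sum_ij d_ij p_i p_j: the expected dissimilarity between two
#' individuals drawn at random from the community. With the taxonomic 0/1
#' dissimilarity this equals 1 - sum(p_i^2), the Gini-Simpson index; with a
#' unit-scaled phylogenetic dissimilarity it is bounded above by that value.
#'
#' @param p Relative-abundance vector (sums to 1).
#' @param d Species dissimilarity matrix in matching order.
#' @return Q, a scalar in `[0, 1)` for unit-scaled `d`.
#' @export
rao_q <- function(p, d) {
  d <- as.matrix(d)
  if (length(p) != nrow(d) || nrow(d) != ncol(d))
    stop("dimension mismatch between abundances and dissimilarity matrix")
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stop("relative abundances must sum to 1")
  drop(crossprod(p, d %*% p))
}

#' Rao gamma diversity of a pooled plot pair
#'
#' Pools two plots with equal weights (mean of the relative-abundance
#' vectors; plots are equal-area quadrats) and returns the Rao Q of the
#' pooled community. Abundance-weighted pooling is available for unequal
#' sampling effort.
#'
#' @param p_a,p_b Relative-abundance vectors on a shared species order.
#' @param d Species dissimilarity matrix.
#' @param w Weight of plot a in the pool (default 0.5, equal weights).
#' @return Pooled Q.
#' @export
pooled_gamma <- function(p_a, p_b, d, w = 0.5) {
  if (length(p_a) != length(p_b)) stop("plots must share the species order")
  if (w < 0 || w > 1) stop("pooling weight must be in [0, 1]")
  rao_q(w * p_a + (1 - w) * p_b, d)
}

#' Jost equivalent-number transform
#'
#' Converts a concave entropy Q in `[0, 1)` into an effective number of
#' species, 1 / (1 - Q), so that alpha and beta components partition without
#' the dependence of raw additive beta on alpha.
#'
#' @param q Rao Q (or any Gini-Simpson-type entropy) in `[0, 1)`.
#' @return 1 / (1 - q).
#' @export
jost_equivalent <- function(q) {
  if (any(q < 0)) stop("q must be non-negative")
  if (any(q >= 1)) stop("q must be < 1 for the equivalent-number transform")
  1 / (1 - q)
}

#' Plot-pairwise additive beta diversity with Jost correction
#'
#' For every unordered pair of plots: mean alpha `abar = (Q_a + Q_b)/2`,
#' pooled gamma `Q_g`, and -- with the Jost correction (default) --
#' `alpha_eq = 1/(1 - abar)`, `gamma_eq = 1/(1 - Q_g)`,
#' `beta_add = gamma_eq - alpha_eq` and `beta_norm = beta_add / gamma_eq`.
#' Without the correction, `beta_add = Q_g - abar` and `beta_norm` divides by
#' `Q_g` (0 when `Q_g` is 0). The normalized beta is a bounded `[0, 1)`
#' dissimilarity suitable for the group-dispersion stage and is the default
#' reported matrix.
#'
#' @param comm Plot x species cover matrix (rows = plots; need not sum to 100).
#' @param d Species dissimilarity matrix matching `colnames(comm)`.
#' @param jost Apply the equivalent-number correction (default `TRUE`).
#' @param normalized Report `beta_norm` as the `beta` element (default
#'   `TRUE`); `FALSE` selects `beta_add`. Both matrices are always returned.
#' @param pooling `"equal"` (mean of relative-abundance vectors) or
#'   `"abundance"` (pool raw covers, weighting plots by total cover).
#' @return A list of class `rao_partition`: per-plot `alpha`, matrices
#'   `beta`, `beta_add`, `beta_norm`, `gamma`, and the settings used.
#' @export
pairwise_beta <- function(comm, d, jost = TRUE, normalized = TRUE,
                          pooling = c("equal", "abundance")) {
  pooling <- match.arg(pooling)
  comm <- validate_community(comm)
  d <- as.matrix(d)
  if (!identical(colnames(comm), rownames(d)) && !is.null(rownames(d))) {
    if (!all(colnames(comm) %in% rownames(d)))
      stop("species missing from the dissimilarity matrix: ",
           paste(setdiff(colnames(comm), rownames(d)), collapse = ", "))
    d <- d[colnames(comm), colnames(comm), drop = FALSE]
  }
  if (ncol(comm) != nrow(d)) stop("dimension mismatch between community and d")
  if (nrow(comm) < 2) stop("pairwise beta needs at least 2 plots")

  totals <- rowSums(comm)
  P <- comm / totals                       # plot x species relative abundances
  # C[i, j] = p_i' D p_j; alpha_i = C[i, i]; equal-weight pooled gamma of a
  # pair is (C_ii + 2 C_ij + C_jj) / 4.
  C <- P %*% d %*% t(P)
  C <- (C + t(C)) / 2
  alpha <- diag(C)
  n <- nrow(comm)
  if (pooling == "equal") {
    gamma <- (outer(alpha, alpha, "+") + 2 * C) / 4
  } else {
    W <- totals / outer(totals, totals, "+")      # weight of plot i in pair (i, j)
    gamma <- W^2 * outer(alpha, rep(1, n)) +
      t(W)^2 * outer(rep(1, n), alpha) + 2 * W * t(W) * C
  }
  abar <- outer(alpha, alpha, "+") / 2
  if (jost) {
    if (any(gamma >= 1)) stop("pooled Q >= 1; Jost correction undefined")
    alpha_eq <- 1 / (1 - abar)
    gamma_eq <- 1 / (1 - gamma)
    beta_add <- gamma_eq - alpha_eq
    beta_norm <- beta_add / gamma_eq
  } else {
    alpha_eq <- abar
    gamma_eq <- gamma
    beta_add <- gamma - abar
    beta_norm <- ifelse(gamma > 0, beta_add / gamma, 0)
  }
  # pooling/Jost arithmetic guarantees symmetry; clean up residual noise
  for (m in c("beta_add", "beta_norm", "gamma", "alpha_eq", "gamma_eq")) {
    x <- get(m)
    x <- (x + t(x)) / 2
    diag(x) <- if (m %in% c("gamma", "alpha_eq", "gamma_eq")) diag(x) else 0
    dimnames(x) <- list(rownames(comm), rownames(comm))
    assign(m, x)
  }
  beta_add[beta_add < 0 & beta_add > -1e-12] <- 0
  beta_norm[beta_norm < 0 & beta_norm > -1e-12] <- 0
  names(alpha) <- rownames(comm)
  structure(list(alpha = alpha,
                 beta = if (normalized) beta_norm else beta_add,
                 beta_add = beta_add, beta_norm = beta_norm,
                 gamma = gamma, alpha_equiv = alpha_eq, gamma_equiv = gamma_eq,
                 jost = jost, normalized = normalized, pooling = pooling),
            class = "rao_partition")
}

#' @export
print.rao_partition <- function(x, ...) {
  cat("Rao diversity partition:", length(x$alpha), "plots;",
      if (x$jost) "Jost-corrected" else "raw additive", "beta",
      sprintf("(default matrix: beta_%s)\n", if (x$normalized) "norm" else "add"))
  cat("alpha: ", sprintf("mean %.4f, range [%.4f, %.4f]\n",
                         mean(x$alpha), min(x$alpha), max(x$alpha)))
  ut <- x$beta[upper.tri(x$beta)]
  cat("beta:  ", sprintf("mean %.4f, range [%.4f, %.4f]\n",
                         mean(ut), min(ut), max(ut)))
  invisible(x)
}

#' Taxonomic and phylogenetic Rao partitions of a community table
#'
#' Convenience front end running [pairwise_beta()] under the taxonomic 0/1
#' dissimilarity and, when a tree is supplied, under the unit-scaled
#' phylogenetic cophenetic dissimilarity. The phylogenetic matrix is scaled
#' once, on the full species set of the table, so that both facets share a
#' 0-1 dissimilarity scale.
#'
#' @param comm Plot x species cover matrix.
#' @param tree Optional rooted `phylo` whose tips cover `colnames(comm)`.
#' @param drop_missing Drop (with a message) table species absent from the
#'   tree instead of erroring, for the phylogenetic facet only. Default
#'   `FALSE`: silent pruning changes Q.
#' @param ... Passed to [pairwise_beta()].
#' @return Named list with elements `taxonomic` and (if `tree` is given)
#'   `phylogenetic`, each a `rao_partition`.
#' @export
rao_diversity <- function(comm, tree = NULL, drop_missing = FALSE, ...) {
  comm <- validate_community(comm)
  out <- list(taxonomic = pairwise_beta(comm, taxonomic_dissimilarity(colnames(comm)), ...))
  if (!is.null(tree)) {
    missing <- setdiff(colnames(comm), tree$tip.label)
    comm_p <- comm
    if (length(missing) > 0) {
      if (!drop_missing)
        stop("species absent from the tree: ", paste(missing, collapse = ", "),
             " (set drop_missing = TRUE to prune them)")
      message("dropping ", length(missing), " species absent from the tree: ",
              paste(missing, collapse = ", "))
      comm_p <- comm[, setdiff(colnames(comm), missing), drop = FALSE]
      if (any(rowSums(comm_p) == 0))
        stop("pruning tree-absent species left plots with zero cover")
    }
    d_phy <- scale_unit(cophenetic_distances(tree)[colnames(comm_p), colnames(comm_p)])
    out$phylogenetic <- pairwise_beta(comm_p, d_phy, ...)
  }
  out
}

#' Validate a plot x species cover table
#'
#' @param comm Matrix or data frame, plots in rows, species in columns.
#' @return A numeric matrix with dimnames.
#' @export
validate_community <- function(comm) {
  comm <- as.matrix(comm)
  if (!is.numeric(comm)) stop("community table must be numeric")
  if (is.null(rownames(comm))) rownames(comm) <- paste0("plot_", seq_len(nrow(comm)))
  if (is.null(colnames(comm))) stop("community table must have species names")
  if (anyDuplicated(colnames(comm))) stop("duplicate species labels")
  if (anyDuplicated(rownames(comm))) stop("duplicate plot ids")
  if (anyNA(comm)) stop("community table has missing values")
  if (any(comm < 0)) stop("negative cover values")
  if (any(rowSums(comm) <= 0))
    stop("plots with zero total cover: ",
         paste(rownames(comm)[rowSums(comm) <= 0], collapse = ", "))
  comm
}
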
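#' Principal-coordinate embedding of a dissimilarity matrix
#'
#' Gower double-centering of `-D^2 / 2` followed by an eigendecomposition.
#' Axes are kept for every eigenvalue with `|lambda| > 1e-10 * max|lambda|`
#' and split by sign: coordinates on negative-eigenvalue axes form the
#' "imaginary" block that arises when the dissimilarity is not Euclidean
#' (as a Jost-corrected beta matrix can be). Squared inter-plot distances
#' are recovered as the positive-block squared distance minus the
#' negative-block squared distance. No Lingoes/Cailliez correction is
#' applied by default.
#'
#' @param dm Symmetric zero-diagonal plot dissimilarity matrix.
#' @param correction `"none"` (default) or `"lingoes"` (adds the constant
#'   that makes the matrix Euclidean).
#' @return List of class `pcoa_embedding`: `pos` and `neg` coordinate
#'   matrices (plots x axes), `eigenvalues` (decreasing), `labels`.
#' @export
pcoa_decompose <- function(dm, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  dm <- check_dissimilarity(dm, tol = 1e-8)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("plot_", seq_len(nrow(dm)))
  n <- nrow(dm)
  A <- -0.5 * dm^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(A))
  G <- G + mean(A)
  G <- (G + t(G)) / 2
  if (correction == "lingoes") {
    lmin <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (lmin < 0) {
      dm2 <- dm^2 - 2 * lmin
      diag(dm2) <- 0
      return(pcoa_decompose(sqrt(dm2)))
    }
  }
  e <- eigen(G, symmetric = TRUE)
  thr <- 1e-10 * max(abs(e$values), 0)
  keep_pos <- e$values > thr
  keep_neg <- e$values < -thr
  mk <- function(keep) {
    if (!any(keep)) {
      m <- matrix(0, n, 0)
    } else {
      m <- e$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(abs(e$values[keep])), sum(keep))
    }
    rownames(m) <- labels
    m
  }
  structure(list(pos = mk(keep_pos), neg = mk(keep_neg),
                 eigenvalues = e$values, labels = labels),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat("PCoA embedding:", length(x$labels), "plots;",
      ncol(x$pos), "positive and", ncol(x$neg), "negative axes\n")
  if (ncol(x$neg) > 0)
    cat("negative eigenvalue mass:",
        sprintf("%.3g\n", -sum(x$eigenvalues[x$eigenvalues < 0])))
  invisible(x)
}

# Squared distances of rows of the embedding to a center given as
# list(pos=, neg=); negative values (non-Euclidean input) are clamped to 0.
.disp_sqdist <- function(emb, center, warn_clamp = TRUE) {
  dp <- sweep(emb$pos, 2, center$pos)
  dn <- sweep(emb$neg, 2, center$neg)
  sq <- rowSums(dp^2) - rowSums(dn^2)
  if (any(sq < 0)) {
    if (warn_clamp && any(sq < -1e-8))
      warning("negative squared distances to center clamped to 0 (non-Euclidean dissimilarity)")
    sq[sq < 0] <- 0
  }
  sq
}

# Geometric median of the rows of X by Weiszfeld iteration, started at the
# centroid; points at the current estimate get a capped weight.
.geometric_median <- function(X, tol = 1e-12, maxit = 500) {
  if (ncol(X) == 0) return(numeric(0))
  ctr <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2, ctr)^2))
    w <- 1 / pmax(d, 1e-12)
    new <- colSums(X * w) / sum(w)
    if (sum((new - ctr)^2) < tol^2) return(new)
    ctr <- new
  }
  ctr
}

#' Distance of each plot to its group's center in PCoA space
#'
#' The multivariate group-dispersion response: each plot's distance to the
#' center (centroid or spatial median) of its management group in the
#' principal-coordinate embedding of the plot-pairwise beta matrix. Plots
#' far from their group center carry high beta diversity relative to the
#' group. Squared distances are positive-block minus negative-block;
#' negatives are clamped to zero with a warning.
#'
#' @param emb A `pcoa_embedding` from [pcoa_decompose()].
#' @param groups Group label per plot (factor or character), in `emb` order
#'   or named by plot.
#' @param center_type `"centroid"` (group mean; default) or
#'   `"spatial_median"` (geometric median computed per eigenvalue block by
#'   Weiszfeld iteration; coincides with the sum-of-distances minimizer for
#'   Euclidean input).
#' @return Data frame of class `dispersion_result`: `plot`, `group`,
#'   `distance`.
#' @export
distance_to_center <- function(emb, groups,
                               center_type = c("centroid", "spatial_median")) {
  center_type <- match.arg(center_type)
  stopifnot(inherits(emb, "pcoa_embedding"))
  n <- length(emb$labels)
  if (!is.null(names(groups))) {
    missing <- setdiff(emb$labels, names(groups))
    if (length(missing) > 0)
      stop("no group label for plots: ", paste(missing, collapse = ", "))
    groups <- groups[emb$labels]
  }
  if (length(groups) != n) stop("need one group label per plot")
  groups <- factor(groups)
  if (anyNA(groups)) stop("missing group labels")
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("singleton groups: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  dist <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- list(pos = emb$pos[idx, , drop = FALSE],
                neg = emb$neg[idx, , drop = FALSE])
    ctr <- list(pos = colMeans(sub$pos), neg = colMeans(sub$neg))
    if (center_type == "spatial_median") {
      # geometric (L1 spatial) median per eigenvalue block: minimizing the
      # clamped combined distance instead is degenerate for non-Euclidean
      # input (the center can exploit the negative block until every
      # clamped distance is zero)
      ctr <- list(pos = .geometric_median(sub$pos),
                  neg = .geometric_median(sub$neg))
    }
    dist[idx] <- sqrt(.disp_sqdist(sub, ctr))
  }
  structure(data.frame(plot = emb$labels, group = as.character(groups),
                       distance = dist, stringsAsFactors = FALSE),
            class = c("dispersion_result", "data.frame"),
            center_type = center_type)
}

#' Group-dispersion response from a beta matrix in one call
#'
#' @param beta Plot-pairwise beta dissimilarity matrix.
#' @param groups Group label per plot (named by plot or in matrix order).
#' @param ... Passed to [distance_to_center()].
#' @return A `dispersion_result` data frame.
#' @export
beta_dispersion <- function(beta, groups, ...) {
  distance_to_center(pcoa_decompose(beta), groups, ...)
}
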
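#' Interaction regression of a diversity response on cover and management
#'
#' Ordinary least squares of `y ~ cover * management` with the management
#' factor releveled so the stated reference (default `"abandoned"`) carries
#' the intercept; the management coefficient is then the mown contrast at
#' zero expansive cover and the interaction is the mown-specific change in
#' the per-percent cover slope. AIC follows the Gaussian log-likelihood
#' convention of [stats::AIC()]. R-squared values are reported in percent.
#'
#' @param y Numeric response, one value per plot (raw Rao Q by default;
#'   standardization is the caller's choice via `standardize`).
#' @param cover Expansive-species cover per plot (% of plot surface).
#' @param management Two-level factor (or character) of management types.
#' @param reference Reference management level (default `"abandoned"`).
#' @param standardize Z-score the response before fitting (default
#'   `FALSE`); leaves R-squared unchanged, rescales coefficients.
#' @return List of class `interaction_fit`: `coefficients` (data frame with
#'   estimate, std_error, t, p_value, stars), `r2_pct`, `adj_r2_pct`,
#'   `model_p`, `aic`, `n`, `model` (the `lm`), and `diagnostics` (fitted,
#'   residuals, theoretical normal quantiles).
#' @export
fit_interaction_model <- function(y, cover, management,
                                  reference = "abandoned",
                                  standardize = FALSE) {
  n <- length(y)
  if (n < 5) stop("need at least 5 plots")
  if (length(cover) != n || length(management) != n)
    stop("y, cover and management must have equal length")
  management <- factor(management)
  if (nlevels(management) != 2) stop("management must have exactly 2 levels")
  if (reference %in% levels(management))
    management <- stats::relevel(management, ref = reference)
  if (standardize) y <- standardize(y)
  dat <- data.frame(y = y, cover = cover, management = management)
  fit <- stats::lm(y ~ cover * management, data = dat)
  if (fit$rank < 4)
    stop("rank-deficient design (cover constant or collinear within a level)")
  sm <- summary(fit)
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "std_error", "t", "p_value")
  ct <- cbind(term = rownames(ct), ct, stars = significance_stars(ct$p_value))
  rownames(ct) <- NULL
  fstat <- sm$fstatistic
  model_p <- unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  res <- stats::residuals(fit)
  structure(list(
    coefficients = ct,
    r2_pct = 100 * sm$r.squared,
    adj_r2_pct = 100 * sm$adj.r.squared,
    model_p = model_p,
    aic = stats::AIC(fit),
    n = n,
    reference = levels(management)[1],
    model = fit,
    diagnostics = data.frame(
      fitted = stats::fitted(fit), residual = res,
      std_residual = res / stats::sd(res),
      theoretical_quantile = stats::qnorm(stats::ppoints(n))[order(order(res))])),
    class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("interaction model (n = %d, reference = %s): adj R2 = %.1f%%%s, AIC = %.1f\n",
              x$n, x$reference, x$adj_r2_pct, significance_stars(x$model_p), x$aic))
  print(cbind(x$coefficients[, c("term", "estimate", "std_error", "p_value")],
              stars = x$coefficients$stars), row.names = FALSE)
  invisible(x)
}

# Goodness of fit (R2 or adjusted R2, as a fraction) of an OLS fit of y on
# an intercept plus the given predictor columns.
.subset_gof <- function(y, X, cols, gof) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (length(cols) == 0) {
    r2 <- 0
    p <- 0
  } else {
    f <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2 <- 1 - sum(f$residuals^2) / tss
    p <- length(cols)
  }
  if (gof == "adjR2") 1 - (1 - r2) * (n - 1) / (n - p - 1) else r2
}

#' Hierarchical partitioning of explained variance
#'
#' Fits all `2^k` predictor subsets and decomposes the full model's
#' goodness of fit into per-predictor independent contributions `I_k` (the
#' average, over all orderings of the predictors, of the gain in fit when
#' predictor k enters) and joint contributions `J_k = gof({k}) - I_k`. With
#' `gof = "R2"` the independent contributions sum exactly to the full
#' model's R-squared; with `"adjR2"` the identity holds only approximately.
#'
#' @param y Numeric response.
#' @param predictors Data frame (or matrix) of predictor columns, `k <= 12`.
#'   Factors are expanded to their numeric codes minus one (two-level
#'   factors become 0/1 indicators).
#' @param gof `"R2"` (default) or `"adjR2"`, reported in percent.
#' @return Data frame of class `hier_part`: `predictor`, `independent`,
#'   `joint` (percent), `independent_share_pct` (`I_k / sum(I) * 100`);
#'   attribute `full_gof_pct`.
#' @export
hierarchical_partition <- function(y, predictors, gof = c("R2", "adjR2")) {
  gof <- match.arg(gof)
  X <- as.data.frame(predictors)
  X[] <- lapply(X, function(v) if (is.numeric(v)) v else as.numeric(factor(v)) - 1)
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 1) stop("need at least one predictor")
  if (k > 12) stop("hierarchical partitioning limited to k <= 12 predictors")
  if (length(y) != nrow(X)) stop("response/predictor length mismatch")

  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  gofs <- apply(subsets, 1, function(s) .subset_gof(y, X, which(s), gof))
  key <- apply(subsets, 1, function(s) paste(which(s), collapse = ","))
  names(gofs) <- key

  lf <- lgamma(seq_len(k + 1))          # log factorials 0! .. k!
  I <- numeric(k)
  for (j in seq_len(k)) {
    others <- setdiff(seq_len(k), j)
    without <- !subsets[[j]]
    for (row in which(without)) {
      s <- which(unlist(subsets[row, ]))
      sz <- length(s)
      w <- exp(lf[sz + 1] + lf[k - sz] - lf[k + 1])   # sz! (k-1-sz)! / k!
      g_with <- gofs[[paste(sort(c(s, j)), collapse = ",")]]
      I[j] <- I[j] + w * (g_with - gofs[[row]])
    }
  }
  single <- vapply(seq_len(k), function(j) gofs[[paste(j, collapse = ",")]],
                   numeric(1))
  J <- single - I
  out <- data.frame(predictor = colnames(X),
                    independent = 100 * I,
                    joint = 100 * J,
                    independent_share_pct = 100 * I / sum(I),
                    stringsAsFactors = FALSE)
  attr(out, "full_gof_pct") <- 100 * gofs[[paste(seq_len(k), collapse = ",")]]
  attr(out, "gof") <- gof
  class(out) <- c("hier_part", "data.frame")
  out
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance two-sample t-test (Welch's unequal-variance
#' test as an option), two-sided.
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List: `t`, `df`, `p_value`, and the two sample means.
#' @export
unpaired_ttest <- function(x1, x2, var_equal = TRUE) {
  if (length(x1) < 2 || length(x2) < 2) stop("each sample needs n >= 2")
  if (stats::var(x1) == 0 && stats::var(x2) == 0)
    stop("zero variance in both samples; t-test undefined")
  ht <- stats::t.test(x1, x2, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean1 = mean(x1), mean2 = mean(x2))
}

#' Fold compass aspect onto a north-south linear scale
#'
#' Maps aspect in degrees (0-360) to `180 - |180 - aspect|`: north (0 or
#' 360) maps to 0, south (180) to 180, with east and west treated
#' symmetrically. Puts the circular aspect variable on a linear scale
#' before group comparisons.
#'
#' @param aspect Aspect in degrees, in `[0, 360]`.
#' @return Folded aspect in `[0, 180]`.
#' @export
fold_aspect <- function(aspect) {
  if (any(aspect < 0 | aspect > 360)) stop("aspect must be within [0, 360] degrees")
  180 - abs(180 - aspect)
}

#' Standardize to zero mean and unit variance
#'
#' @param y Numeric vector, `n >= 2`, non-constant.
#' @return Z-scores (sample SD).
#' @export
standardize <- function(y) {
  if (length(y) < 2) stop("need n >= 2")
  s <- stats::sd(y)
  if (s == 0) stop("constant vector cannot be standardized")
  (y - mean(y)) / s
}
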
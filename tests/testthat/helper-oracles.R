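# Independent brute-force oracles, kept deliberately naive: each re-derives
# its quantity from the definition, not through the package's code path.

# Cophenetic distances by walking each tip's path to the root and summing
# branch lengths below the most recent common ancestor.
naive_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_up <- function(i) {
    nodes <- integer(0); dists <- numeric(0)
    cur <- i; acc <- 0
    while (cur != root) {
      acc <- acc + elen[cur]
      cur <- parent[cur]
      nodes <- c(nodes, cur); dists <- c(dists, acc)
    }
    stats::setNames(dists, nodes)
  }
  paths <- lapply(seq_len(n), path_up)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    mrca <- common[which.min(paths[[i]][common])]
    D[i, j] <- D[j, i] <- paths[[i]][[mrca]] + paths[[j]][[mrca]]
  }
  D
}

# Rao Q by explicit double loop over ordered species pairs.
naive_rao <- function(p, d) {
  p <- unname(p)
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) q <- q + d[i, j] * p[i] * p[j]
  q
}

# One plot pair's Jost-corrected additive beta, from scratch.
naive_beta_pair <- function(xa, xb, d, jost = TRUE) {
  pa <- xa / sum(xa); pb <- xb / sum(xb)
  qa <- naive_rao(pa, d); qb <- naive_rao(pb, d)
  qg <- naive_rao((pa + pb) / 2, d)
  abar <- (qa + qb) / 2
  if (jost) {
    a_eq <- 1 / (1 - abar); g_eq <- 1 / (1 - qg)
    add <- g_eq - a_eq
    list(add = add, norm = add / g_eq)
  } else {
    list(add = qg - abar, norm = if (qg > 0) (qg - abar) / qg else 0)
  }
}

# IndVal statistic per species by explicit loops (group-mean specificity).
naive_indval <- function(comm, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  t(vapply(seq_len(ncol(comm)), function(s) {
    mu <- vapply(lev, function(g) mean(comm[groups == g, s]), numeric(1))
    A <- mu / sum(mu)
    B <- vapply(lev, function(g) mean(comm[groups == g, s] > 0), numeric(1))
    stat <- sqrt(A * B)
    c(stat = max(stat), best = unname(which.max(stat)))
  }, numeric(2)))
}

# All label assignments with the observed group sizes (for exhaustive
# permutation p-values on small designs).
all_label_assignments <- function(groups) {
  groups <- factor(groups)
  n <- length(groups)
  k1 <- sum(groups == levels(groups)[1])
  combos <- utils::combn(n, k1)
  lapply(seq_len(ncol(combos)), function(i) {
    g <- rep(levels(groups)[2], n)
    g[combos[, i]] <- levels(groups)[1]
    factor(g, levels = levels(groups))
  })
}

# Hierarchical partitioning by enumerating every ordering of the predictors
# and averaging the sequential goodness-of-fit improvements.
oracle_hierpart <- function(y, X, gof = "R2") {
  X <- as.matrix(X)
  k <- ncol(X)
  gf <- function(cols) {
    if (length(cols) == 0) return(0)
    sm <- summary(stats::lm(y ~ X[, cols, drop = FALSE]))
    if (gof == "adjR2") sm$adj.r.squared else sm$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  I <- numeric(k)
  for (ord in perms(seq_len(k))) {
    prev <- integer(0)
    for (j in ord) {
      I[j] <- I[j] + gf(c(prev, j)) - gf(prev)
      prev <- c(prev, j)
    }
  }
  I / factorial(k)
}

# --- small fixture builders ---------------------------------------------

tree_from_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(text, path)
  path
}

random_community <- function(n_plots, n_species, seed = NULL,
                             prevalence = 0.6) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(n_plots * n_species, rate = 0.2) *
                (stats::runif(n_plots * n_species) < prevalence),
              n_plots, n_species,
              dimnames = list(sprintf("plot_%02d", seq_len(n_plots)),
                              sprintf("sp%03d", seq_len(n_species))))
  # guarantee every plot occupied
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_species, sum(empty), replace = TRUE))] <- 1
  m
}
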
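test_that("taxonomic dissimilarity is 1 minus identity", {
  d <- taxonomic_dissimilarity(c("a", "b", "c"))
  expect_equal(unname(d), 1 - diag(3))
  expect_equal(taxonomic_dissimilarity("a"), matrix(0, 1, 1, dimnames = list("a", "a")))
  d10 <- taxonomic_dissimilarity(letters[1:10])
  expect_equal(sum(diag(d10)), 0)
  expect_equal(sum(d10), 10 * 9)
})

test_that("Rao Q reduces to Gini-Simpson under unit distances", {
  p4 <- rep(0.25, 4)
  expect_equal(rao_q(p4, taxonomic_dissimilarity(letters[1:4])), 0.75)
  expect_equal(rao_q(1, matrix(0, 1, 1)), 0)
  # two species at distance 1: Q = 2 * 0.5 * 0.5 * 1
  expect_equal(rao_q(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2)), 0.5)

  set.seed(3)
  for (rep in 1:50) {
    S <- sample(2:12, 1)
    p <- stats::rexp(S); p <- p / sum(p)
    d <- taxonomic_dissimilarity(paste0("s", 1:S))
    expect_equal(rao_q(p, d), 1 - sum(p^2), tolerance = 1e-14)
    expect_equal(rao_q(p, d), naive_rao(p, d), tolerance = 1e-14)
  }
  expect_error(rao_q(c(0.5, 0.5), matrix(0, 3, 3)), "dimension")
})

test_that("pooled gamma: identity on equal plots, hand value on disjoint pair", {
  d <- taxonomic_dissimilarity(c("a", "b"))
  p <- c(0.3, 0.7)
  expect_equal(pooled_gamma(p, p, d), rao_q(p, d))
  # two disjoint single-species plots: pooled p = (0.5, 0.5), Q = 0.5
  expect_equal(pooled_gamma(c(1, 0), c(0, 1), d), 0.5)
})

test_that("pooled gamma is at least the mean alpha (Rao concavity)", {
  set.seed(9)
  for (rep in 1:30) {
    S <- sample(3:10, 1)
    d <- if (rep %% 2) taxonomic_dissimilarity(paste0("s", 1:S))
         else scale_unit(cophenetic_distances(simulate_tree(S)))
    pa <- stats::rexp(S); pa <- pa / sum(pa)
    pb <- stats::rexp(S); pb <- pb / sum(pb)
    qg <- pooled_gamma(pa, pb, unname(d))
    expect_gte(qg, mean(c(rao_q(pa, unname(d)), rao_q(pb, unname(d)))) - 1e-12)
  }
})

test_that("Jost equivalent numbers transform", {
  expect_equal(jost_equivalent(0), 1)
  expect_equal(jost_equivalent(0.75), 4)
  expect_equal(jost_equivalent(0.5), 2)
  expect_error(jost_equivalent(1), "< 1")
  expect_error(jost_equivalent(-0.1), "non-negative")
})

test_that("pairwise beta: hand-computed disjoint pair and identical plots", {
  comm <- rbind(p1 = c(a = 1, b = 0), p2 = c(a = 0, b = 1))
  d <- taxonomic_dissimilarity(c("a", "b"))
  res <- pairwise_beta(comm, d)
  # alpha = 0 each, alpha_eq = 1, Q_gamma = 0.5, gamma_eq = 2
  expect_equal(unname(res$alpha), c(0, 0))
  expect_equal(res$beta_add["p1", "p2"], 1)
  expect_equal(res$beta_norm["p1", "p2"], 0.5)
  expect_identical(res$beta, res$beta_norm)

  same <- rbind(p1 = c(a = 2, b = 6), p2 = c(a = 1, b = 3))  # equal proportions
  for (jost in c(TRUE, FALSE)) for (norm in c(TRUE, FALSE)) {
    r <- pairwise_beta(same, d, jost = jost, normalized = norm)
    expect_equal(r$beta["p1", "p2"], 0, tolerance = 1e-14)
  }
})

test_that("pairwise beta matches naive per-pair recomputation", {
  comm <- random_community(10, 8, seed = 21)
  for (facet_d in list(taxonomic_dissimilarity(colnames(comm)),
                       {set.seed(22)
                        d <- scale_unit(cophenetic_distances(simulate_tree(8)))
                        dimnames(d) <- list(colnames(comm), colnames(comm)); d})) {
    for (jost in c(TRUE, FALSE)) {
      res <- pairwise_beta(comm, facet_d, jost = jost)
      for (i in 1:9) for (j in (i + 1):10) {
        ref <- naive_beta_pair(comm[i, ], comm[j, ], facet_d, jost = jost)
        expect_equal(res$beta_add[i, j], ref$add, tolerance = 1e-12)
        expect_equal(res$beta_norm[i, j], ref$norm, tolerance = 1e-12)
      }
    }
  }
})

test_that("beta matrix is symmetric, zero-diagonal, and beta_norm in [0, 1)", {
  comm <- random_community(12, 15, seed = 5)
  res <- pairwise_beta(comm, taxonomic_dissimilarity(colnames(comm)))
  expect_equal(res$beta, t(res$beta))
  expect_equal(diag(res$beta), stats::setNames(rep(0, 12), rownames(comm)))
  expect_true(all(res$beta_norm >= 0 & res$beta_norm < 1))
})

test_that("outputs are invariant to species-order permutation", {
  comm <- random_community(6, 9, seed = 13)
  set.seed(14)
  perm <- sample(ncol(comm))
  r1 <- pairwise_beta(comm, taxonomic_dissimilarity(colnames(comm)))
  r2 <- pairwise_beta(comm[, perm], taxonomic_dissimilarity(colnames(comm)[perm]))
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-12)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
})

test_that("phylogenetic Q never exceeds taxonomic Q; star tree makes them equal", {
  set.seed(31)
  tree <- simulate_tree(12)
  comm <- random_community(8, 12, seed = 32)
  colnames(comm) <- tree$tip.label
  div <- rao_diversity(comm, tree)
  expect_true(all(div$phylogenetic$alpha <= div$taxonomic$alpha + 1e-12))

  # star-equivalent rooted binary tree: zero-length internal edges, unit
  # tip edges, so every tip pair sits at distance 2
  star <- ape::rtree(12, br = NULL)
  star$edge.length <- as.numeric(star$edge[, 2] <= 12)
  star$tip.label <- colnames(comm)
  div_star <- rao_diversity(comm, star)
  expect_equal(div_star$phylogenetic$alpha, div_star$taxonomic$alpha,
               tolerance = 1e-12)
  expect_equal(div_star$phylogenetic$beta, div_star$taxonomic$beta,
               tolerance = 1e-12)
})

test_that("species absent from the tree error by default, prune on request", {
  set.seed(41)
  tree <- simulate_tree(6)
  comm <- random_community(5, 7, seed = 42)
  colnames(comm) <- c(tree$tip.label, "orphan_species")
  comm[, "orphan_species"] <- 1
  expect_error(rao_diversity(comm, tree), "orphan_species")
  expect_message(div <- rao_diversity(comm, tree, drop_missing = TRUE), "dropping")
  expect_length(div$phylogenetic$alpha, 5)
})

test_that("community validation catches bad tables", {
  good <- random_community(3, 3, seed = 1)
  bad <- good; bad[1, ] <- 0
  expect_error(validate_community(bad), "zero total cover")
  bad2 <- good; bad2[2, 1] <- -1
  expect_error(validate_community(bad2), "negative")
  expect_error(pairwise_beta(good[1, , drop = FALSE],
                             taxonomic_dissimilarity(colnames(good))),
               "2 plots")
})
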
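test_that("simulated trees are ultrametric with unit depth and deterministic", {
  tree <- simulate_tree(50, seed = 81)
  depths <- ape::node.depth.edgelength(tree)[1:50]
  expect_equal(depths, rep(1, 50), tolerance = 1e-9)
  expect_true("expansive" %in% tree$tip.label)

  t2 <- simulate_tree(2, seed = 82)
  expect_equal(cophenetic_distances(t2)[1, 2], 2, tolerance = 1e-9)

  a <- ape::write.tree(simulate_tree(20, seed = 83))
  b <- ape::write.tree(simulate_tree(20, seed = 83))
  expect_identical(a, b)
  expect_error(simulate_tree(1), "at least 2")
})

test_that("simulation config validates its inputs", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(pool_size = c(mown = 3, abandoned = 50)), ">= 5")
  expect_error(simulation_config(cover_range = list(mown = c(50, 5),
                                                    abandoned = c(0, 50))), "min <= max")
  expect_error(simulation_config(richness_intercept = c(mown = 5, abandoned = 8),
                                 richness_slope = c(mown = -0.5, abandoned = 0)),
               "richness < 1")
  expect_error(simulation_config(phylo_clustering = c(mown = -1, abandoned = 0)),
               ">= 0")
})

test_that("datasets honour the configured design and are byte-identical under a seed", {
  cfg <- simulation_config()
  tree <- simulate_tree(81, seed = 84)
  ds <- simulate_dataset(cfg, tree, seed = 85)
  expect_equal(nrow(ds$community), 61)
  expect_equal(sum(ds$metadata$management == "mown"), 31)
  expect_equal(sum(ds$metadata$management == "abandoned"), 30)
  expect_true(all(ds$community >= 0))
  # expansive cover column equals the drawn gradient; residual cover sums to 100 - c
  expect_equal(unname(ds$community[, "expansive"]), ds$metadata$expansive_cover)
  expect_equal(unname(rowSums(ds$community)), rep(100, 61), tolerance = 1e-9)
  cr <- cfg$cover_range$mown
  expect_true(all(ds$metadata$expansive_cover >= min(cr, cfg$cover_range$abandoned)))

  ds2 <- simulate_dataset(cfg, tree, seed = 85)
  expect_identical(ds$community, ds2$community)
  expect_identical(ds$metadata, ds2$metadata)
})

test_that("degenerate config gives constant richness S0 + 1", {
  cfg <- simulation_config(richness_intercept = c(mown = 7, abandoned = 7),
                           richness_slope = c(mown = 0, abandoned = 0),
                           phylo_clustering = c(mown = 0, abandoned = 0),
                           noise_sd = 0,
                           cover_range = list(mown = c(10, 60),
                                              abandoned = c(10, 60)))
  ds <- simulate_dataset(cfg, simulate_tree(81, seed = 86), seed = 87)
  expect_equal(unname(rowSums(ds$community > 0)), rep(8, 61))
})

test_that("phylogenetic clustering pulls abandoned assemblages toward the expansive tip", {
  cfg <- simulation_config(phylo_clustering = c(mown = 0, abandoned = 4),
                           n_plots = c(mown = 150, abandoned = 150),
                           pool_size = c(mown = 55, abandoned = 55),
                           pool_overlap = 1)  # identical pools isolate the effect
  tree <- simulate_tree(60, seed = 88)
  ds <- simulate_dataset(cfg, tree, seed = 89)
  d_exp <- scale_unit(cophenetic_distances(tree))["expansive", ]
  mean_d <- function(m) {
    rows <- which(ds$metadata$management == m)
    mean(vapply(rows, function(i) {
      sp <- setdiff(colnames(ds$community)[ds$community[i, ] > 0], "expansive")
      mean(d_exp[sp])
    }, numeric(1)))
  }
  expect_lt(mean_d("abandoned"), mean_d("mown"))
})

test_that("generated alpha diversity declines with expansive cover", {
  cfg <- simulation_config(n_plots = c(mown = 500, abandoned = 500))
  ds <- simulate_dataset(cfg, simulate_tree(81, seed = 90), seed = 91)
  P <- ds$community / rowSums(ds$community)
  alpha <- 1 - rowSums(P^2)
  for (m in c("mown", "abandoned")) {
    idx <- ds$metadata$management == m
    expect_lt(stats::cor(ds$metadata$expansive_cover[idx], alpha[idx]), -0.5)
  }
})

test_that("infeasible pools and trees are rejected", {
  cfg <- simulation_config()
  expect_error(simulate_dataset(cfg, simulate_tree(40, seed = 92)), "tree too small")
  tree <- simulate_tree(81, seed = 93)
  tree$tip.label[tree$tip.label == "expansive"] <- "sp999"
  attr(tree, "expansive_tip") <- NULL
  expect_error(simulate_dataset(cfg, tree), "expansive tip")
})

test_that("recovery experiment summarises sign recovery and is reproducible", {
  cfg <- simulation_config(n_plots = c(mown = 20, abandoned = 20))
  r1 <- recovery_experiment(cfg, n_reps = 5, seed = 94, facets = "taxonomic")
  r2 <- recovery_experiment(cfg, n_reps = 5, seed = 94, facets = "taxonomic")
  expect_identical(r1$summary, r2$summary)
  expect_setequal(r1$summary$term,
                  c("cover", "managementmown", "cover:managementmown"))
  expect_true(all(r1$summary$sign_recovery >= 0 & r1$summary$sign_recovery <= 1))
})
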
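#' Configuration for the synthetic grassland community generator
#'
#' Defaults emulate the sampling design of a mown vs. abandoned
#' semi-natural grassland contrast: 31 mown and 30 abandoned quadrats of
#' 0.5 x 0.5 m, species pools of 60 (mown) and 50 (abandoned) species that
#' overlap partially, one expansive tussock grass whose cover varies
#' between plots, and subordinate richness declining with expansive cover
#' -- more steeply under mowing (the biotic filter modulated by
#' management). Under abandonment, subordinate species are drawn with
#' weights favouring tips phylogenetically close to the expansive grass
#' (clustering), and the richness intercept is lower (litter and tussock
#' matrix suppressing the community regardless of live cover).
#'
#' @param n_plots Named integer vector, plots per management.
#' @param pool_size Named integer vector, species-pool size per management.
#' @param pool_overlap Fraction of the smaller pool shared between
#'   managements (default 0.6).
#' @param cover_range Named list of length-2 cover ranges (%) for the
#'   expansive species per management.
#' @param richness_intercept Named vector: expected subordinate richness at
#'   zero expansive cover, per management.
#' @param richness_slope Named vector: change in expected subordinate
#'   richness per percent expansive cover (negative = biotic filtering).
#' @param phylo_clustering Named vector lambda >= 0: subordinate sampling
#'   weight is `exp(-lambda * d)` with `d` the unit-scaled cophenetic
#'   distance to the expansive tip; 0 = neutral sampling.
#' @param noise_sd SD of the Gaussian noise on expected richness (species).
#' @param dirichlet_conc Concentration of the symmetric Dirichlet that
#'   splits the residual cover among subordinates (1 = uniform simplex).
#' @param expansive_monopolizes If `TRUE` (default) the expansive species
#'   receives exactly the drawn cover c and subordinates share `100 - c`;
#'   if `FALSE` the drawn gradient is recorded in the metadata but the
#'   expansive tip competes as an ordinary community member, giving a
#'   fully null response-predictor relationship (see [null_config()]).
#' @param seed Optional default seed used by [simulate_dataset()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_plots = c(mown = 31, abandoned = 30),
                              pool_size = c(mown = 60, abandoned = 50),
                              pool_overlap = 0.6,
                              cover_range = list(mown = c(5, 70),
                                                 abandoned = c(5, 70)),
                              richness_intercept = c(mown = 12, abandoned = 8),
                              richness_slope = c(mown = -0.15, abandoned = -0.05),
                              phylo_clustering = c(mown = 0, abandoned = 1.5),
                              noise_sd = 1,
                              dirichlet_conc = 1,
                              expansive_monopolizes = TRUE,
                              seed = NULL) {
  mgmt <- c("mown", "abandoned")
  as_named <- function(x, what) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 2), mgmt)
    if (!all(mgmt %in% names(x))) stop(what, " must be named mown/abandoned")
    x[mgmt]
  }
  cfg <- list(n_plots = as_named(n_plots, "n_plots"),
              pool_size = as_named(pool_size, "pool_size"),
              pool_overlap = pool_overlap,
              cover_range = if (!is.list(cover_range))
                list(mown = cover_range, abandoned = cover_range)[mgmt]
              else cover_range[mgmt],
              richness_intercept = as_named(richness_intercept, "richness_intercept"),
              richness_slope = as_named(richness_slope, "richness_slope"),
              phylo_clustering = as_named(phylo_clustering, "phylo_clustering"),
              noise_sd = noise_sd, dirichlet_conc = dirichlet_conc,
              expansive_monopolizes = isTRUE(expansive_monopolizes), seed = seed)
  if (any(cfg$pool_size < 5)) stop("pool sizes must be >= 5")
  if (cfg$pool_overlap < 0 || cfg$pool_overlap > 1) stop("pool_overlap in [0, 1]")
  for (m in mgmt) {
    r <- cfg$cover_range[[m]]
    if (length(r) != 2 || any(r < 0) || any(r > 100) || r[1] > r[2])
      stop("cover_range must be within [0, 100] with min <= max")
    smin <- cfg$richness_intercept[[m]] + cfg$richness_slope[[m]] * r[2]
    if (smin < 1)
      stop("derived subordinate richness < 1 at maximum cover for ", m)
  }
  if (any(cfg$phylo_clustering < 0)) stop("phylo_clustering must be >= 0")
  if (cfg$noise_sd < 0 || cfg$dirichlet_conc <= 0) stop("invalid noise/concentration")
  structure(cfg, class = "simulation_config")
}

#' Null configuration: every effect switched off
#'
#' Identical generating process in both managements -- equal pools, cover
#' ranges, richness intercepts and slopes, no phylogenetic clustering --
#' and the recorded expansive-cover gradient decoupled from community
#' assembly (`expansive_monopolizes = FALSE`), so that cover, management
#' and interaction coefficients of downstream models are all truly null.
#' Used for type-I error calibration.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_config <- function(...) {
  defaults <- list(pool_size = c(mown = 55, abandoned = 55),
                   cover_range = list(mown = c(5, 70), abandoned = c(5, 70)),
                   richness_intercept = c(mown = 12, abandoned = 12),
                   richness_slope = c(mown = 0, abandoned = 0),
                   phylo_clustering = c(mown = 0, abandoned = 0),
                   expansive_monopolizes = FALSE)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Simulate an ultrametric species-pool phylogeny
#'
#' Yule (pure-birth) tree rescaled to unit root-to-tip depth, with one tip
#' relabeled `"expansive"` to play the expansive grass.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return A rooted ultrametric `phylo`; the expansive tip's name is also
#'   stored in `attr(tree, "expansive_tip")`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  exp_tip <- sample(tree$tip.label, 1)
  tree$tip.label[tree$tip.label == exp_tip] <- "expansive"
  attr(tree, "expansive_tip") <- "expansive"
  validate_phylogeny(tree)
  tree
}

#' Simulate a plot x species cover table and plot metadata
#'
#' Per plot of management m: expansive cover `c ~ Uniform(cover_range_m)`;
#' subordinate richness `S = max(1, round(S0_m + b_m c + eps))` with
#' Gaussian noise; S subordinates drawn without replacement from the
#' management's pool with weights `exp(-lambda_m * d)` where d is the
#' unit-scaled cophenetic distance to the expansive tip; the expansive
#' species receives cover c and the remaining `100 - c` is split among the
#' subordinates by a symmetric Dirichlet. Metadata emulate the
#' environmental contrast of such grasslands (litter far higher under
#' abandonment; small altitude/aspect/slope differences).
#'
#' @param config A [simulation_config()].
#' @param tree Phylogeny from [simulate_tree()]; needs at least
#'   `max(pool_size) + 1` tips including the expansive tip.
#' @param seed Integer seed (default `config$seed`).
#' @return List of class `synthetic_dataset`: `community` (plot x species
#'   matrix, expansive column included), `metadata` (data frame: plot_id,
#'   management, expansive_cover, altitude, aspect, slope, litter),
#'   `ground_truth` (generating parameters and realized per-plot values),
#'   `tree`.
#' @export
simulate_dataset <- function(config, tree, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  exp_tip <- attr(tree, "expansive_tip")
  if (is.null(exp_tip)) exp_tip <- "expansive"
  if (!exp_tip %in% tree$tip.label) stop("tree lacks the expansive tip")
  if (!is.null(seed)) set.seed(seed)
  pool_all <- setdiff(tree$tip.label, exp_tip)
  need <- sum(config$pool_size) -
    round(config$pool_overlap * min(config$pool_size))
  if (length(pool_all) < need)
    stop("tree too small: need >= ", need + 1, " tips for the configured pools")

  d_exp <- scale_unit(cophenetic_distances(tree))[exp_tip, ]

  n_shared <- round(config$pool_overlap * min(config$pool_size))
  shared <- sample(pool_all, n_shared)
  rest <- setdiff(pool_all, shared)
  uniq <- list()
  for (m in c("mown", "abandoned")) {
    n_uniq <- config$pool_size[[m]] - n_shared
    uniq[[m]] <- sample(rest, n_uniq)
    rest <- setdiff(rest, uniq[[m]])
  }
  pools <- lapply(uniq, function(u) sort(c(shared, u)))

  n_total <- sum(config$n_plots)
  plot_ids <- sprintf("plot_%02d", seq_len(n_total))
  management <- rep(c("mown", "abandoned"), config$n_plots)
  species <- sort(unique(c(exp_tip, unlist(pools))))
  comm <- matrix(0, n_total, length(species),
                 dimnames = list(plot_ids, species))
  cover <- numeric(n_total)
  richness <- integer(n_total)
  for (i in seq_len(n_total)) {
    m <- management[i]
    pool <- pools[[m]]
    c_i <- stats::runif(1, config$cover_range[[m]][1], config$cover_range[[m]][2])
    S <- max(1, round(config$richness_intercept[[m]] +
                        config$richness_slope[[m]] * c_i +
                        stats::rnorm(1, 0, config$noise_sd)))
    if (S > length(pool))
      stop("infeasible richness ", S, " exceeds pool size ", length(pool))
    w <- exp(-config$phylo_clustering[[m]] * d_exp[pool])
    chosen <- sample(pool, S, prob = w)
    if (config$expansive_monopolizes) {
      shares <- stats::rgamma(S, shape = config$dirichlet_conc)
      shares <- shares / sum(shares)
      comm[i, chosen] <- (100 - c_i) * shares
      comm[i, exp_tip] <- c_i
    } else {
      # null mode: the recorded gradient is decoupled from assembly -- the
      # expansive tip behaves as an ordinary community member, so cover,
      # management and interaction effects on diversity are all truly zero
      shares <- stats::rgamma(S + 1, shape = config$dirichlet_conc)
      shares <- shares / sum(shares)
      comm[i, c(chosen, exp_tip)] <- 100 * shares
    }
    cover[i] <- c_i
    richness[i] <- S
  }
  env <- list(
    altitude = list(mown = c(1534, 20), abandoned = c(1465, 32)),
    aspect = list(mown = c(333, 12), abandoned = c(310, 8)),
    slope = list(mown = c(5, 2), abandoned = c(10, 2)),
    litter = list(mown = c(9.7, 4.3), abandoned = c(92, 13)))
  draw_env <- function(var, lo = -Inf, hi = Inf) {
    pmin(hi, pmax(lo, stats::rnorm(
      n_total,
      vapply(management, function(m) env[[var]][[m]][1], numeric(1)),
      vapply(management, function(m) env[[var]][[m]][2], numeric(1)))))
  }
  metadata <- data.frame(
    plot_id = plot_ids, management = management, expansive_cover = cover,
    altitude = draw_env("altitude"),
    aspect = draw_env("aspect", 0, 360),
    slope = draw_env("slope", 0, 90),
    litter = draw_env("litter", 0, 100),
    stringsAsFactors = FALSE)
  structure(list(
    community = comm, metadata = metadata, tree = tree,
    ground_truth = list(
      config = unclass(config), seed = seed,
      pools = pools, expansive_tip = exp_tip,
      realized = data.frame(plot_id = plot_ids, management = management,
                            expansive_cover = cover,
                            subordinate_richness = richness))),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic grassland dataset:", nrow(x$community), "plots x",
      ncol(x$community), "species",
      sprintf("(%d mown, %d abandoned)\n",
              sum(x$metadata$management == "mown"),
              sum(x$metadata$management == "abandoned")))
  invisible(x)
}

#' Write a synthetic dataset to the pipeline's on-disk formats
#'
#' Community CSV, metadata CSV, Newick tree and a YAML ground-truth file --
#' the same formats [read_community()] and [read_metadata()] consume.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(community = file.path(dir, "community.csv"),
             metadata = file.path(dir, "metadata.csv"),
             tree = file.path(dir, "tree.nwk"),
             ground_truth = file.path(dir, "ground_truth.yml"))
  write_community(dataset$community, paths["community"])
  utils::write.csv(dataset$metadata, paths["metadata"], row.names = FALSE)
  write_newick(dataset$tree, paths["tree"])
  gt <- dataset$ground_truth
  # yaml drops names of atomic vectors; listify so mown/abandoned keys survive
  gt$config <- lapply(gt$config, function(v)
    if (!is.null(names(v))) as.list(v) else v)
  gt$realized <- lapply(as.list(gt$realized), function(col)
    if (is.numeric(col)) round(unname(col), 6) else unname(col))
  yaml::write_yaml(gt, paths["ground_truth"])
  invisible(paths)
}

#' Parameter-recovery experiment over replicate synthetic datasets
#'
#' Repeatedly simulates a dataset, computes per-plot alpha diversity
#' (taxonomic and, optionally, phylogenetic Rao Q) and fits the
#' cover x management interaction model, then summarizes coefficient signs
#' and rejection rates across replicates. The phylogeny is simulated once
#' and shared across replicates (it is a nuisance parameter here).
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicate datasets (>= 1).
#' @param seed Integer seed driving the whole experiment.
#' @param facets Responses to analyse: subset of
#'   `c("taxonomic", "phylogenetic")`.
#' @param n_tips Tips of the shared simulated tree (default: enough for
#'   the configured pools).
#' @param alpha_level Rejection threshold (default 0.05).
#' @return List of class `recovery_experiment`: `summary` (one row per
#'   facet x coefficient: mean estimate, sign-recovery proportion,
#'   rejection proportion) and `estimates` (per-replicate coefficients).
#' @export
recovery_experiment <- function(config, n_reps, seed = 1,
                                facets = c("taxonomic", "phylogenetic"),
                                n_tips = NULL, alpha_level = 0.05) {
  stopifnot(n_reps >= 1)
  facets <- match.arg(facets, several.ok = TRUE)
  if (is.null(n_tips))
    n_tips <- sum(config$pool_size) -
      round(config$pool_overlap * min(config$pool_size)) + 1
  set.seed(seed)
  tree <- simulate_tree(n_tips)
  d_phy <- scale_unit(cophenetic_distances(tree))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- list()
  for (r in seq_len(n_reps)) {
    ds <- simulate_dataset(config, tree, seed = rep_seeds[r])
    totals <- rowSums(ds$community)
    P <- ds$community / totals
    for (facet in facets) {
      d <- if (facet == "taxonomic") {
        taxonomic_dissimilarity(colnames(ds$community))
      } else {
        d_phy[colnames(ds$community), colnames(ds$community)]
      }
      alpha <- rowSums((P %*% d) * P)
      fit <- fit_interaction_model(alpha, ds$metadata$expansive_cover,
                                   ds$metadata$management)
      cf <- fit$coefficients
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, facet = facet, term = cf$term,
        estimate = cf$estimate, p_value = cf$p_value,
        stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, rows)
  est <- est[est$term != "(Intercept)", ]
  expected_sign <- c(cover = -1, managementmown = 1, `cover:managementmown` = -1)
  agg <- do.call(rbind, lapply(split(est, list(est$facet, est$term)), function(d) {
    data.frame(facet = d$facet[1], term = d$term[1],
               mean_estimate = mean(d$estimate),
               prop_negative = mean(d$estimate < 0),
               sign_recovery = mean(sign(d$estimate) ==
                                      expected_sign[[d$term[1]]]),
               rejection_rate = mean(d$p_value < alpha_level),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(summary = agg, estimates = est, n_reps = n_reps, seed = seed),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("recovery experiment:", x$n_reps, "replicates (seed", x$seed, ")\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
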
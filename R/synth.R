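#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the study design the downstream analysis assumes:
#' three successional stages (grass, mosaic, shrub) with five spatially
#' independent replicates, five soil taxonomic groups profiled per sample,
#' and a 208-variable ecosystem-function matrix.
#'
#' Community construction: each group gets a random phylogeny; a niche
#' optimum evolves on it under Brownian motion (then standardised to zero
#' mean, unit variance, preserving the tree-structured covariance); each
#' taxon gets a lognormal baseline abundance; the expected relative
#' abundance in a sample at stage environment \eqn{e} is proportional to
#' \eqn{baseline \times \exp(-s (niche - e)^2)} with selection strength
#' \eqn{s}; counts are drawn multinomially at a fixed sequencing depth.
#' `selection_strength = 0` gives stage-independent expected abundances
#' (neutral assembly); large `s` with distinct `stage_env_values` makes
#' between-stage turnover selection-dominated.
#'
#' Function matrix: per-variable stage means follow a shape profile
#' (`monotone`, `v`, `inverted_v` or `flat`) scaled by `function_effect_size`
#' plus Gaussian noise. Under the default `monotone` profile the good
#' direction improves toward the shrub stage: raw values rise for ordinary
#' variables and fall for reflect-flagged ones (for which low raw = good).
#'
#' @param n_replicates Replicates per stage (default 5).
#' @param groups Taxonomic groups to simulate (default all five).
#' @param taxa_per_group Number of taxa per group (default 60).
#' @param sequencing_depth Multinomial total per sample (default 1000).
#' @param lognormal_meanlog,lognormal_sdlog Baseline log-abundance
#'   parameters (default 0 and 2: a strongly skewed abundance distribution,
#'   so that per-sample occupancy is realistically incomplete and
#'   presence/absence turnover exists between samples).
#' @param selection_strength Non-negative selection strength `s` (default 0,
#'   neutral).
#' @param bm_sigma Brownian-motion rate for niche evolution (default 1; the
#'   trait is re-standardised, so this mainly matters relative to depth).
#' @param stage_env_values Named per-stage environmental optimum (default
#'   grass -1, mosaic 0, shrub 1, on the standardised niche scale).
#' @param function_baseline Baseline mean for every functional variable
#'   (default 10, keeps raw values positive).
#' @param function_effect_size Stage effect amplitude (default 2).
#' @param function_noise_sd Residual Gaussian sd (default 1).
#' @param function_shapes Optional character vector (length 1 or one entry
#'   per registry variable) in `c("monotone", "v", "inverted_v", "flat")`;
#'   default `"monotone"`.
#' @param registry Function registry (default shipped 208-variable registry).
#' @param seed Integer seed; every stochastic output is fully determined by it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_replicates = 5,
                         groups = TAXON_GROUPS,
                         taxa_per_group = 60,
                         sequencing_depth = 1000,
                         lognormal_meanlog = 0,
                         lognormal_sdlog = 2,
                         selection_strength = 0,
                         bm_sigma = 1,
                         stage_env_values = c(grass = -1, mosaic = 0, shrub = 1),
                         function_baseline = 10,
                         function_effect_size = 2,
                         function_noise_sd = 1,
                         function_shapes = "monotone",
                         registry = build_function_registry(),
                         seed = 1L) {
  groups <- match.arg(groups, TAXON_GROUPS, several.ok = TRUE)
  stopifnot(n_replicates >= 1, taxa_per_group >= 2, sequencing_depth >= 1,
            selection_strength >= 0, lognormal_sdlog >= 0,
            all(STAGES %in% names(stage_env_values)))
  shapes <- rep_len(function_shapes, nrow(registry))
  bad <- setdiff(unique(shapes), c("monotone", "v", "inverted_v", "flat"))
  if (length(bad)) stop("unknown function shape: ", paste(bad, collapse = ", "))
  structure(list(
    n_replicates = n_replicates, groups = groups,
    taxa_per_group = taxa_per_group, sequencing_depth = sequencing_depth,
    lognormal_meanlog = lognormal_meanlog, lognormal_sdlog = lognormal_sdlog,
    selection_strength = selection_strength, bm_sigma = bm_sigma,
    stage_env_values = stage_env_values[STAGES],
    function_baseline = function_baseline,
    function_effect_size = function_effect_size,
    function_noise_sd = function_noise_sd,
    function_shapes = shapes, registry = registry,
    seed = as.integer(seed)), class = "synth_config")
}

#' Simulate a random phylogeny
#'
#' Random coalescent tree ([ape::rcoal()]): seed-reproducible, rooted,
#' ultrametric, with exponential coalescence times. Most of the tree depth
#' sits on the deep branches, so Brownian traits evolved on it carry strong
#' deep phylogenetic signal — the regime in which nearest-taxon null models
#' are informative.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @param tip_prefix Prefix for tip labels (default `"otu"`).
#' @return An [ape::phylo] tree with `n_taxa` tips.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, tip_prefix = "otu") {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n_taxa)
  tr$tip.label <- sprintf("%s%04d", tip_prefix, seq_len(n_taxa))
  tr
}

# Brownian niche optimum standardised to mean 0, sd 1 across tips.
simulate_niche <- function(tree, sigma) {
  x <- ape::rTraitCont(tree, model = "BM", sigma = sigma)
  s <- stats::sd(x)
  if (s == 0) return(stats::setNames(rep(0, length(x)), names(x)))
  (x - mean(x)) / s
}

#' Simulate a full multitrophic dataset
#'
#' Generates, from one seed: a sample frame (3 stages x `n_replicates`), one
#' phylogeny + niche-trait vector + community table per taxonomic group, and
#' a function matrix over the registry. See [synth_config()] for the
#' generative model.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_dataset` with elements `samples`,
#'   `communities` (named list of `community_table`), `trees`, `niches`,
#'   `functions` (a `function_matrix`) and `config`.
#' @examples
#' d <- simulate_dataset(synth_config(taxa_per_group = 20, seed = 7))
#' nrow(d$samples)            # 15
#' length(d$communities)      # 5
#' @export
simulate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  samples <- default_sample_frame(config$n_replicates)
  env <- config$stage_env_values[as.character(samples$stage)]

  trees <- niches <- communities <- list()
  for (g in config$groups) {
    tr <- simulate_tree(config$taxa_per_group,
                        tip_prefix = paste0(substr(g, 1, 3), "_otu"))
    niche <- simulate_niche(tr, config$bm_sigma)
    baseline <- stats::rlnorm(config$taxa_per_group,
                              config$lognormal_meanlog, config$lognormal_sdlog)
    names(baseline) <- tr$tip.label
    counts <- matrix(0L, nrow(samples), config$taxa_per_group,
                     dimnames = list(samples$sample_id, tr$tip.label))
    for (i in seq_len(nrow(samples))) {
      w <- baseline * exp(-config$selection_strength * (niche - env[i])^2)
      counts[i, ] <- stats::rmultinom(1, config$sequencing_depth, w / sum(w))
    }
    trees[[g]] <- tr
    niches[[g]] <- niche
    communities[[g]] <- community_table(counts, g)
  }

  fm <- simulate_function_matrix(samples, config)
  structure(list(samples = samples, communities = communities, trees = trees,
                 niches = niches, functions = fm, config = config),
            class = "synth_dataset")
}

# Stage-mean multiplier for each profile shape, in grass/mosaic/shrub order.
# "monotone" is oriented so the good direction improves toward shrub: raw
# values rise unless the variable is reflect-flagged, in which case they fall
# (low raw = good for those).
shape_profile <- function(shape, reflect) {
  switch(shape,
         monotone   = if (reflect) c(1, 0.5, 0) else c(0, 0.5, 1),
         v          = c(1, 0, 1),
         inverted_v = c(0, 1, 0),
         flat       = c(0, 0, 0))
}

simulate_function_matrix <- function(samples, config) {
  reg <- config$registry
  stage_idx <- as.integer(samples$stage)
  vals <- matrix(NA_real_, nrow(samples), nrow(reg),
                 dimnames = list(samples$sample_id, reg$name))
  for (j in seq_len(nrow(reg))) {
    prof <- shape_profile(config$function_shapes[j], reg$reflect[j])
    mu <- config$function_baseline + config$function_effect_size * prof[stage_idx]
    vals[, j] <- stats::rnorm(nrow(samples), mu, config$function_noise_sd)
  }
  function_matrix(vals, reg)
}

#' Write a synthetic dataset as TSV/Newick fixtures
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_frame(dataset$samples, file.path(dir, "samples.tsv"))
  for (g in names(dataset$communities)) {
    write_community(dataset$communities[[g]],
                    file.path(dir, paste0("community_", g, ".tsv")))
    write_phylogeny(dataset$trees[[g]], file.path(dir, paste0("tree_", g, ".nwk")))
  }
  write_function_matrix(dataset$functions, file.path(dir, "functions.tsv"))
  invisible(dir)
}
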
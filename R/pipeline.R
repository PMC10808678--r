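#' Configuration for an end-to-end pipeline run
#'
#' One global seed deterministically derives every module seed, so reruns
#' with the same configuration are numerically identical.
#'
#' @param synth A [synth_config()] describing the synthetic dataset (or
#'   `NULL` when `data` is supplied to [run_pipeline()] directly).
#' @param rarity_cutoffs Named per-group cutoffs (default
#'   [default_rarity_cutoffs()]).
#' @param classifier A [classifier_config()].
#' @param mf An [mf_config()].
#' @param drivers A [driver_config()].
#' @param seed Global seed.
#' @param out_dir Optional directory; when set, stage outputs are written
#'   as TSV.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       rarity_cutoffs = default_rarity_cutoffs(),
                       classifier = classifier_config(),
                       mf = mf_config(),
                       drivers = driver_config(),
                       seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  # derive module seeds deterministically from the global seed (kept < 2^31)
  ds <- function(k) as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
  if (!is.null(synth)) synth$seed <- ds(1)
  classifier$seed <- ds(2)
  mf$seed <- ds(3)
  drivers$seed <- ds(4)
  structure(list(synth = synth, rarity_cutoffs = rarity_cutoffs,
                 classifier = classifier, mf = mf, drivers = drivers,
                 seed = seed, out_dir = out_dir), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> rarity partitioning -> assembly
#' null models on every subcommunity -> multifunctionality and trade-off
#' indices per scope with stage contrasts -> driver attribution, and
#' returns a structured report. Any stage failure aborts with the failing
#' stage named.
#'
#' @param config A [run_config()].
#' @param data Optional pre-built dataset (a `synth_dataset`-shaped list
#'   with `samples`, `communities`, `trees`, `functions`); when `NULL` the
#'   configured synthetic dataset is generated.
#' @return A list of class `shrubmf_report` with elements `samples`,
#'   `rarity` (per group: partition + subcommunity sizes), `assembly`
#'   (per group x subcommunity: process fractions and pair table),
#'   `multifunctionality` (per scope: indices + stage tests + trajectory),
#'   `tradeoff` (per scope), `drivers`, and `config`.
#' @export
run_pipeline <- function(config = run_config(), data = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(data))
    data <- stage("simulate", simulate_dataset(config$synth))
  samples <- data$samples
  stages <- samples$stage

  rarity <- assembly <- list()
  for (g in names(data$communities)) {
    tab <- data$communities[[g]]
    cutoff <- config$rarity_cutoffs[[attr(tab, "group")]]
    if (is.null(cutoff)) cutoff <- 0.001
    part <- stage("rarity", partition_rarity(tab, cutoff))
    rarity[[g]] <- list(cutoff = cutoff, partition = part)
    assembly[[g]] <- list()
    for (sub in SUBCOMMUNITIES) {
      subtab <- stage("rarity", subcommunity_table(tab, part, sub))
      if (is.null(subtab)) {
        assembly[[g]][[sub]] <- NULL
        next
      }
      assembly[[g]][[sub]] <- stage("assembly",
        assembly_analysis(subtab, data$trees[[g]], config$classifier))
    }
  }

  F_std <- stage("multifunc", standardize_functions(data$functions))
  mf_res <- to_res <- list()
  for (sc in c("aboveground", "underground", "entire")) {
    mfr <- stage("multifunc", multifunctionality(F_std, sc, config$mf))
    st <- stage("multifunc", stage_tests(mfr$averaging, stages))
    mf_res[[sc]] <- list(result = mfr, stage_tests = st,
                         trajectory = classify_trajectory(
                           st$medians, st$pairwise$p))
    reg <- attr(F_std, "registry")
    to <- stage("tradeoff", tradeoff_intensity(F_std, scope_functions(reg, sc),
                                               config = config$mf))
    st2 <- stage("tradeoff", stage_tests(to$intensity, stages))
    to_res[[sc]] <- list(result = to, stage_tests = st2,
                         trajectory = classify_trajectory(
                           st2$medians, st2$pairwise$p))
  }

  # Driver step: responses = per-scope averaging MF; candidate predictors =
  # plant species richness plus per-group entire-community OTU richness.
  Y <- cbind(aboveground = mf_res$aboveground$result$averaging,
             underground = mf_res$underground$result$averaging,
             entire = mf_res$entire$result$averaging)
  richness <- vapply(data$communities, function(tab) rowSums(unclass(tab) > 0),
                     numeric(nrow(samples)))
  colnames(richness) <- paste0(names(data$communities), "_richness")
  X <- cbind(plant_species_richness = unclass(data$functions)[, "plant_species_richness"],
             richness)
  drv <- stage("drivers", driver_analysis(Y, X, config$drivers))

  report <- structure(list(samples = samples, rarity = rarity,
                           assembly = assembly, multifunctionality = mf_res,
                           tradeoff = to_res, drivers = drv, config = config),
                      class = "shrubmf_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, data)
  report
}

write_report <- function(report, dir, data) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(data, file.path(dir, "dataset"))
  fr <- process_fraction_table(report)
  utils::write.table(fr, file.path(dir, "process_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- do.call(rbind, lapply(names(report$multifunctionality), function(sc) {
    r <- report$multifunctionality[[sc]]$result
    data.frame(scope = sc, sample_id = names(r$averaging),
               averaging_mf = unname(r$averaging), entropy_mf = unname(r$entropy),
               tradeoff_intensity = unname(report$tradeoff[[sc]]$result$intensity))
  }))
  utils::write.table(mf, file.path(dir, "multifunctionality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Long table of assembly process fractions
#'
#' @param report A `shrubmf_report`.
#' @return data.frame: group, subcommunity, process, fraction.
#' @export
process_fraction_table <- function(report) {
  rows <- list()
  for (g in names(report$assembly)) {
    for (sub in names(report$assembly[[g]])) {
      fr <- report$assembly[[g]][[sub]]$fractions
      rows[[length(rows) + 1]] <- data.frame(group = g, subcommunity = sub,
                                             process = names(fr),
                                             fraction = unname(fr))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.shrubmf_report <- function(x, ...) {
  cat("shrubmf pipeline report\n")
  cat(sprintf("  samples: %d (%s)\n", nrow(x$samples),
              paste(levels(x$samples$stage), collapse = " -> ")))
  cat(sprintf("  groups: %s\n", paste(names(x$assembly), collapse = ", ")))
  n_sub <- sum(vapply(x$assembly, length, integer(1)))
  cat(sprintf("  subcommunities analysed: %d\n", n_sub))
  for (sc in names(x$multifunctionality)) {
    st <- x$multifunctionality[[sc]]$stage_tests
    cat(sprintf("  %s MF: medians %s | KW p = %.3g | trajectory: %s\n", sc,
                paste(sprintf("%.3f", st$medians), collapse = "/"),
                st$kruskal$p, x$multifunctionality[[sc]]$trajectory))
  }
  invisible(x)
}
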
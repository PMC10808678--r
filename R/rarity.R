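#' Default abundant/rare relative-abundance cutoffs
#'
#' Per-group cutoffs (fractions, not percent) selected by multivariate
#' cutoff level analysis: archaea 0.1%, bacteria 0.05%, fungi 0.1%,
#' nematodes 0.1%, protists 0.2%.
#'
#' @return Named numeric vector of fractions.
#' @examples
#' default_rarity_cutoffs()[["protists"]]  # 0.002
#' @export
default_rarity_cutoffs <- function() {
  c(archaea = 0.001, bacteria = 0.0005, fungi = 0.001,
    nematodes = 0.001, protists = 0.002)
}

#' Multivariate cutoff level (MultiCoLA) scan
#'
#' For each candidate cutoff, taxa below it are truncated away and the
#' Bray-Curtis dissimilarity structure of the truncated table is compared to
#' that of the full table by Spearman rank correlation of the lower
#' triangles. The chosen cutoff is the largest whose correlation still meets
#' the retention threshold, i.e. the most aggressive truncation that leaves
#' the community's multivariate structure essentially intact.
#'
#' @param table A `community_table` (or count matrix) with >= 3 samples.
#' @param candidate_cutoffs Relative-abundance cutoffs in (0, 1).
#' @param retention Minimum acceptable Spearman correlation (default 0.95).
#' @param truncate_by `"mean"` drops taxa whose across-sample mean relative
#'   abundance is below the cutoff; `"per_sample"` keeps taxa reaching the
#'   cutoff in at least one sample.
#' @return A list of class `multicola_scan` with a `scan` data.frame
#'   (cutoff, n_taxa_kept, correlation — `NA` flags a degenerate truncation)
#'   and `chosen_cutoff` (`NA` if no cutoff meets the retention threshold).
#' @export
multicola_scan <- function(table, candidate_cutoffs,
                           retention = 0.95,
                           truncate_by = c("mean", "per_sample")) {
  truncate_by <- match.arg(truncate_by)
  if (nrow(table) < 3) stop("MultiCoLA needs at least 3 samples")
  if (any(candidate_cutoffs <= 0 | candidate_cutoffs >= 1))
    stop("cutoffs must lie in (0, 1)")
  rel <- relative_abundance(table)
  full_d <- vegan::vegdist(rel, method = "bray")
  scan <- data.frame(cutoff = sort(candidate_cutoffs),
                     n_taxa_kept = NA_integer_, correlation = NA_real_)
  for (i in seq_len(nrow(scan))) {
    keep <- switch(truncate_by,
                   mean = colMeans(rel) >= scan$cutoff[i],
                   per_sample = apply(rel, 2, max) >= scan$cutoff[i])
    scan$n_taxa_kept[i] <- sum(keep)
    if (!any(keep)) next  # all taxa removed: score undefined, left NA
    sub <- rel[, keep, drop = FALSE]
    if (any(rowSums(sub) == 0)) next  # a sample emptied: undefined
    trunc_d <- vegan::vegdist(sub, method = "bray")
    scan$correlation[i] <- stats::cor(as.vector(full_d), as.vector(trunc_d),
                                      method = "spearman")
  }
  ok <- which(!is.na(scan$correlation) & scan$correlation >= retention)
  chosen <- if (length(ok)) max(scan$cutoff[ok]) else NA_real_
  structure(list(scan = scan, chosen_cutoff = chosen, retention = retention,
                 truncate_by = truncate_by), class = "multicola_scan")
}

#' Partition a community into abundant and rare subcommunities
#'
#' Local partition (within each sample): among taxa present in the sample,
#' a taxon is locally abundant if its within-sample relative abundance is at
#' least `cutoff`, locally rare otherwise; absent taxa belong to neither
#' set. Regional partition (across samples): a taxon is regionally abundant
#' if its across-sample mean relative abundance is at least `cutoff`,
#' regionally rare otherwise.
#'
#' @param table A `community_table`.
#' @param cutoff Relative-abundance cutoff in (0, 1).
#' @return A list of class `rarity_partition` with `cutoff`,
#'   `locally_abundant` / `locally_rare` (named lists of taxon-id vectors,
#'   one per sample) and `regionally_abundant` / `regionally_rare`
#'   (taxon-id vectors).
#' @export
partition_rarity <- function(table, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  rel <- relative_abundance(table)
  taxa <- colnames(table)
  loc_ab <- loc_ra <- stats::setNames(vector("list", nrow(rel)), rownames(rel))
  for (s in seq_len(nrow(rel))) {
    present <- rel[s, ] > 0
    loc_ab[[s]] <- taxa[present & rel[s, ] >= cutoff]
    loc_ra[[s]] <- taxa[present & rel[s, ] < cutoff]
  }
  mean_rel <- colMeans(rel)
  structure(list(cutoff = cutoff,
                 locally_abundant = loc_ab, locally_rare = loc_ra,
                 regionally_abundant = taxa[mean_rel >= cutoff],
                 regionally_rare = taxa[mean_rel < cutoff]),
            class = "rarity_partition")
}

SUBCOMMUNITIES <- c("entire", "locally_abundant", "locally_rare",
                    "regionally_abundant", "regionally_rare")

#' Extract a subcommunity count table
#'
#' Builds the count table of one of the five subcommunities defined by a
#' rarity partition. Local subcommunities zero out the cells outside the
#' per-sample membership sets (a taxon can be locally abundant in one sample
#' and locally rare in another); regional subcommunities subset whole taxon
#' columns. All-zero taxon columns are dropped.
#'
#' @param table The full `community_table`.
#' @param partition A `rarity_partition` of that table.
#' @param which One of `"entire"`, `"locally_abundant"`, `"locally_rare"`,
#'   `"regionally_abundant"`, `"regionally_rare"`.
#' @return A `community_table`, or `NULL` (with a message) when the
#'   subcommunity is empty or has an all-zero sample, so downstream
#'   dissimilarity stages can skip it with a logged reason.
#' @export
subcommunity_table <- function(table, partition, which = SUBCOMMUNITIES) {
  which <- match.arg(which)
  if (which == "entire") return(table)
  m <- unclass(table)
  if (which %in% c("regionally_abundant", "regionally_rare")) {
    keep <- intersect(colnames(m), partition[[which]])
    m <- m[, keep, drop = FALSE]
  } else {
    sets <- partition[[which]]
    for (s in rownames(m)) m[s, !(colnames(m) %in% sets[[s]])] <- 0L
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0 || any(rowSums(m) == 0)) {
    message("subcommunity '", which, "' is empty or has an all-zero sample; skipped")
    return(NULL)
  }
  community_table(m, attr(table, "group"))
}
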
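#' Configuration for the assembly-process classifier
#'
#' @param bnti_threshold Deterministic/stochastic boundary on
#'   \eqn{|\beta NTI|} (default 2).
#' @param rc_threshold Dispersal boundary on \eqn{|RC_{bray}|} (default 0.95).
#' @param n_null Number of null-model randomisations (default 999).
#' @param abundance_weighted Weight nearest-taxon distances by relative
#'   abundance (default `TRUE`).
#' @param seed Integer seed for the null models.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(bnti_threshold = 2, rc_threshold = 0.95,
                              n_null = 999, abundance_weighted = TRUE,
                              seed = 1L) {
  stopifnot(bnti_threshold > 0, rc_threshold > 0, n_null >= 1)
  structure(list(bnti_threshold = bnti_threshold, rc_threshold = rc_threshold,
                 n_null = as.integer(n_null),
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = as.integer(seed)), class = "classifier_config")
}

PROCESS_LEVELS <- c("variable selection", "homogeneous selection",
                    "dispersal limitation", "homogenizing dispersal", "drift")

#' Beta mean nearest taxon distance between two communities
#'
#' For every taxon in one community, the patristic distance to its closest
#' relative in the other community is taken; these nearest-taxon distances
#' are averaged (weighted by relative abundance when `abundance_weighted`)
#' within each community and the two directional means are averaged. A taxon
#' shared by both communities contributes distance 0.
#'
#' @param comm_a,comm_b Named non-negative abundance vectors (taxon ids as
#'   names); zeros mark absence.
#' @param dist_matrix Patristic distance matrix covering all present taxa
#'   (dimnames = taxon ids).
#' @param abundance_weighted Weight by relative abundance (default `TRUE`).
#' @return The \eqn{\beta}MNTD value (0 for identical communities).
#' @examples
#' D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' beta_mntd(c(A = 1), c(B = 1), D)  # 3
#' @export
beta_mntd <- function(comm_a, comm_b, dist_matrix, abundance_weighted = TRUE) {
  a <- comm_a[comm_a > 0]; b <- comm_b[comm_b > 0]
  if (!length(a) || !length(b)) stop("empty community")
  taxa <- union(names(a), names(b))
  missing <- setdiff(taxa, rownames(dist_matrix))
  if (length(missing))
    stop("taxa missing from distance matrix: ", paste(missing, collapse = ", "))
  m <- matrix(0, 2, length(taxa), dimnames = list(c("a", "b"), taxa))
  m["a", names(a)] <- a; m["b", names(b)] <- b
  bmntd_pairs(m, dist_matrix[taxa, taxa, drop = FALSE], abundance_weighted)[1, 2]
}

# All-pairs bMNTD for a samples x taxa abundance matrix (C++ kernel).
bmntd_pairs <- function(abund, dist_matrix, abundance_weighted = TRUE) {
  stopifnot(identical(colnames(abund), rownames(dist_matrix)),
            identical(colnames(abund), colnames(dist_matrix)))
  out <- .bmntd_pairs_cpp(unname(as.matrix(abund)), unname(as.matrix(dist_matrix)),
                          abundance_weighted)
  dimnames(out) <- list(rownames(abund), rownames(abund))
  out
}

#' Beta nearest taxon index for all sample pairs
#'
#' z-scores the observed \eqn{\beta}MNTD of each sample pair against a null
#' distribution obtained by shuffling taxon labels across the tips of the
#' phylogeny (topology and branch lengths fixed):
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \bar{\beta MNTD}_{null}) / sd(\beta MNTD_{null})}
#' Pairs whose null distribution has zero standard deviation (e.g. identical
#' communities, or a star phylogeny where every relabelling is equivalent)
#' are flagged undefined (`NA`) and excluded from process fractions.
#'
#' @param table A `community_table` (samples x taxa).
#' @param tree Phylogeny whose tips cover the table's taxa.
#' @param config A [classifier_config()].
#' @return A list of class `bnti_result` with symmetric matrices
#'   `bmntd_obs`, `null_mean`, `null_sd` and `bnti` (`NA` diagonal;
#'   `NA` entries flag undefined pairs).
#' @export
beta_nti <- function(table, tree, config = classifier_config()) {
  check_community_tree(table, tree)
  rel <- relative_abundance(table)
  D <- stats::cophenetic(tree)[colnames(rel), colnames(rel)]
  obs <- bmntd_pairs(rel, D, config$abundance_weighted)
  nt <- ncol(rel)
  set.seed(config$seed)
  sum1 <- sum2 <- matrix(0, nrow(rel), nrow(rel))
  for (k in seq_len(config$n_null)) {
    p <- sample.int(nt)
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    nullk <- bmntd_pairs(rel, Dp, config$abundance_weighted)
    sum1 <- sum1 + nullk
    sum2 <- sum2 + nullk^2
  }
  mu <- sum1 / config$n_null
  sd2 <- sum2 / config$n_null - mu^2
  sdv <- sqrt(pmax(sd2, 0))
  bnti <- (obs - mu) / sdv
  bnti[sdv < 1e-12] <- NA_real_
  diag(bnti) <- diag(obs) <- diag(mu) <- diag(sdv) <- NA_real_
  structure(list(bmntd_obs = obs, null_mean = mu, null_sd = sdv, bnti = bnti,
                 config = config), class = "bnti_result")
}

#' Abundance-based Raup-Crick metric for all sample pairs
#'
#' Null communities preserve each observed sample's richness and total
#' abundance: richness-many taxa are drawn without replacement with
#' probability proportional to regional occupancy (number of samples
#' occupied), then the remaining individuals are distributed multinomially
#' with probability proportional to the regional mean relative abundance of
#' the drawn taxa. Observed Bray-Curtis dissimilarity is located within the
#' null distribution and rescaled to \eqn{[-1, +1]}:
#' \deqn{RC_{bray} = 2\left(\frac{n_{null < obs} + 0.5\, n_{ties}}{n_{null}}\right) - 1}
#'
#' @param table A `community_table` (integer counts).
#' @param config A [classifier_config()].
#' @param regional Optional list with elements `occupancy` and `mean_rel`
#'   (named per taxon) defining the regional pool; defaults to the table's
#'   own occupancy and mean relative abundances.
#' @return A list of class `rc_result` with the symmetric matrix `rc` in
#'   \eqn{[-1, +1]} and the observed Bray-Curtis matrix `bray_obs`.
#' @export
raup_crick_bray <- function(table, config = classifier_config(),
                            regional = NULL) {
  counts <- unclass(table)
  if (is.null(regional)) {
    regional <- list(occupancy = colSums(counts > 0),
                     mean_rel = colMeans(relative_abundance(counts)))
  }
  occ <- regional$occupancy[colnames(counts)]
  mrel <- regional$mean_rel[colnames(counts)]
  if (all(occ == 0)) stop("empty regional pool")
  S <- nrow(counts); Tn <- ncol(counts)
  obs_d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  richness <- rowSums(counts > 0)
  depth <- rowSums(counts)
  set.seed(config$seed)
  less <- ties <- matrix(0, S, S)
  nullmat <- matrix(0, S, Tn)
  for (k in seq_len(config$n_null)) {
    nullmat[] <- 0
    for (s in seq_len(S)) {
      drawn <- sample.int(Tn, richness[s], prob = occ)
      fill <- depth[s] - richness[s]
      x <- rep(1, richness[s])
      if (fill > 0) {
        pr <- mrel[drawn]
        if (sum(pr) <= 0) pr <- rep(1, length(drawn))
        x <- x + as.vector(stats::rmultinom(1, fill, pr))
      }
      nullmat[s, drawn] <- x
    }
    null_d <- as.matrix(vegan::vegdist(nullmat, method = "bray"))
    less <- less + (null_d < obs_d - 1e-10)
    ties <- ties + (abs(null_d - obs_d) <= 1e-10)
  }
  rc <- 2 * ((less + 0.5 * ties) / config$n_null) - 1
  diag(rc) <- NA_real_
  dimnames(rc) <- dimnames(obs_d)
  structure(list(rc = rc, bray_obs = obs_d, config = config),
            class = "rc_result")
}

#' Five-way assembly-process classification
#'
#' \eqn{\beta NTI > +2}: variable selection; \eqn{\beta NTI < -2}:
#' homogeneous selection; otherwise the pair is stochastic and
#' \eqn{RC_{bray} > +0.95} indicates dispersal limitation,
#' \eqn{RC_{bray} < -0.95} homogenizing dispersal, and
#' \eqn{|RC_{bray}| \le 0.95} drift. Boundary values (exactly \eqn{\pm 2} or
#' \eqn{\pm 0.95}) fall to the stochastic/drift side, matching the strict
#' inequalities of the classification rules.
#'
#' @param bnti Numeric vector (or matrix) of \eqn{\beta}NTI values; `NA`
#'   flags undefined pairs, which get no label.
#' @param rc Matching \eqn{RC_{bray}} values.
#' @param config A [classifier_config()].
#' @return Factor (same shape as `bnti`) with levels `"variable selection"`,
#'   `"homogeneous selection"`, `"dispersal limitation"`,
#'   `"homogenizing dispersal"`, `"drift"`.
#' @examples
#' classify_process(c(2.5, -2.5, 0.5, 0.5, 0.5), c(0.1, 0.1, 0.97, -0.97, 0.5))
#' @export
classify_process <- function(bnti, rc, config = classifier_config()) {
  bt <- config$bnti_threshold; rt <- config$rc_threshold
  out <- rep(NA_character_, length(bnti))
  out[!is.na(bnti) & bnti > bt] <- "variable selection"
  out[!is.na(bnti) & bnti < -bt] <- "homogeneous selection"
  sto <- !is.na(bnti) & abs(bnti) <= bt
  out[sto & !is.na(rc) & rc > rt] <- "dispersal limitation"
  out[sto & !is.na(rc) & rc < -rt] <- "homogenizing dispersal"
  out[sto & !is.na(rc) & abs(rc) <= rt] <- "drift"
  res <- factor(out, levels = PROCESS_LEVELS)
  if (is.matrix(bnti)) {
    res <- matrix(as.character(res), nrow(bnti), dimnames = dimnames(bnti))
  }
  res
}

#' Full assembly analysis of one (sub)community
#'
#' Runs [beta_nti()] and [raup_crick_bray()], classifies every sample pair,
#' and tabulates process fractions over the classified pairs.
#'
#' @param table A `community_table`.
#' @param tree Phylogeny covering the table's taxa (pruned internally).
#' @param config A [classifier_config()].
#' @return A list of class `assembly_result`: `bnti` (a `bnti_result`),
#'   `rc` (an `rc_result`), `process` (pair label matrix), `pairs` (long
#'   data.frame of the upper-triangle pairs) and `fractions` (named vector
#'   over the five processes, summing to 1 over defined pairs; `n_undefined`
#'   counts excluded pairs).
#' @export
assembly_analysis <- function(table, tree, config = classifier_config()) {
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(table)))
  check_community_tree(table, tree)
  bn <- beta_nti(table, tree, config)
  rc <- raup_crick_bray(table, config)
  proc <- classify_process(bn$bnti, rc$rc, config)
  ut <- upper.tri(bn$bnti)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(sample_a = rownames(bn$bnti)[idx[, 1]],
                      sample_b = colnames(bn$bnti)[idx[, 2]],
                      bmntd = bn$bmntd_obs[ut], bnti = bn$bnti[ut],
                      rc = rc$rc[ut], process = proc[ut])
  lab <- factor(pairs$process, levels = PROCESS_LEVELS)
  n_def <- sum(!is.na(lab))
  fractions <- if (n_def) table(lab) / n_def else table(lab) * NA_real_
  structure(list(bnti = bn, rc = rc, process = proc, pairs = pairs,
                 fractions = c(fractions), n_undefined = sum(is.na(lab))),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("assembly_result:", nrow(x$pairs), "pairs (",
      x$n_undefined, "undefined )\nprocess fractions:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Phylogenetic Mantel correlogram of a niche trait
#'
#' Tests for phylogenetic signal in tip-level niche values across classes of
#' patristic distance: patristic distances are binned (via
#' [vegan::mantel.correlog()]) and a per-class Mantel statistic between the
#' niche distance matrix and class membership is computed, with two-sided
#' permutation p-values (the direction-adaptive one-tailed probabilities are
#' doubled and capped at 1, so p is uniform under a signal-free null).
#' Positive values in the shortest classes indicate
#' that close relatives have similar niches, the premise of nearest-taxon
#' null models.
#'
#' @param niche_values Named numeric vector (one value per tip).
#' @param tree Phylogeny with matching tip labels.
#' @param n_classes Number of distance classes (default 4).
#' @param n_perm Permutations per class (default 99).
#' @param seed Optional seed.
#' @return A list of class `phylo_correlogram` with `classes` (data.frame:
#'   class midpoint, n pairs, mantel_r, p) and `undefined` (`TRUE` when the
#'   trait has zero variance, in which case `classes` is `NULL`).
#' @export
phylo_correlogram <- function(niche_values, tree, n_classes = 4,
                              n_perm = 99, seed = NULL) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  x <- niche_values[tree$tip.label]
  if (any(is.na(x))) stop("niche values missing for some tips")
  if (stats::sd(x) < 1e-12)
    return(structure(list(classes = NULL, undefined = TRUE),
                     class = "phylo_correlogram"))
  if (!is.null(seed)) set.seed(seed)
  D <- stats::cophenetic(tree)[names(x), names(x)]
  mc <- vegan::mantel.correlog(stats::dist(x), D.geo = stats::as.dist(D),
                               n.class = n_classes, nperm = n_perm,
                               cutoff = FALSE, mult = "holm")
  res <- as.data.frame(mc$mantel.res)
  classes <- data.frame(class_midpoint = res[, "class.index"],
                        n_pairs = res[, "n.dist"],
                        mantel_r = res[, "Mantel.cor"],
                        p = pmin(1, 2 * res[, "Pr(Mantel)"]))
  structure(list(classes = classes, undefined = FALSE),
            class = "phylo_correlogram")
}
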
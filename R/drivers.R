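#' Configuration for driver analysis
#'
#' @param vif_threshold Predictors with variance inflation factor at or
#'   above this are iteratively excluded (default 10).
#' @param n_perm Permutations for forward-selection admission tests
#'   (default 999).
#' @param alpha Admission significance level (default 0.05).
#' @param permute `"residual"` permutes residuals of the current model
#'   (default); `"rows"` permutes raw response rows.
#' @param seed Integer seed.
#' @return A `driver_config` list.
#' @export
driver_config <- function(vif_threshold = 10, n_perm = 999, alpha = 0.05,
                          permute = c("residual", "rows"), seed = 1L) {
  permute <- match.arg(permute)
  stopifnot(vif_threshold > 1, n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(vif_threshold = vif_threshold, n_perm = as.integer(n_perm),
                 alpha = alpha, permute = permute, seed = as.integer(seed)),
            class = "driver_config")
}

#' Stage contrasts: Kruskal-Wallis and pairwise Wilcoxon tests
#'
#' @param values Numeric vector (one observation per sample).
#' @param stages Factor/character of stage labels, same length.
#' @return A list with `kruskal` (statistic, df, p), `pairwise` (data.frame
#'   of group pairs with raw and Holm-adjusted rank-sum p-values) and
#'   `medians` (named per-stage medians).
#' @export
stage_tests <- function(values, stages) {
  stages <- droplevels(as.factor(stages))
  if (nlevels(stages) < 2) stop("need at least 2 stages")
  if (any(table(stages) < 2)) stop("every stage needs at least 2 observations")
  kw <- stats::kruskal.test(values, stages)
  lev <- levels(stages)
  cmb <- utils::combn(lev, 2)
  praw <- apply(cmb, 2, function(g)
    suppressWarnings(stats::wilcox.test(values[stages == g[1]],
                                        values[stages == g[2]])$p.value))
  pairwise <- data.frame(group_a = cmb[1, ], group_b = cmb[2, ],
                         p = praw, p_holm = stats::p.adjust(praw, "holm"))
  medians <- tapply(values, stages, stats::median)
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pairwise, medians = medians)
}

#' Classify a three-stage trajectory
#'
#' Shapes over the ordered stages grass -> mosaic -> shrub:
#' `"V"` when the mosaic median is the strict minimum and at least one
#' mosaic contrast is significant; `"inverted-V"` when it is the strict
#' maximum likewise; `"increase"`/`"decrease"` when medians are monotone
#' with a significant grass-vs-shrub contrast; `"flat"` otherwise (median
#' ties fall to flat unless a significant pairwise contrast resolves the
#' direction).
#'
#' @param medians_by_stage Numeric length-3 vector, grass/mosaic/shrub order.
#' @param pairwise_p Length-3 vector of pairwise p-values in the order
#'   grass-mosaic, grass-shrub, mosaic-shrub (the order [stage_tests()]
#'   emits for three stages).
#' @param alpha Significance level (default 0.05).
#' @return One of `"increase"`, `"decrease"`, `"V"`, `"inverted-V"`, `"flat"`.
#' @examples
#' classify_trajectory(c(1, 0.2, 1.1), c(0.01, 0.8, 0.01))  # "V"
#' @export
classify_trajectory <- function(medians_by_stage, pairwise_p, alpha = 0.05) {
  stopifnot(length(medians_by_stage) == 3, length(pairwise_p) == 3)
  m <- unname(medians_by_stage)
  p_gm <- pairwise_p[1]; p_gs <- pairwise_p[2]; p_ms <- pairwise_p[3]
  mosaic_sig <- (p_gm < alpha) || (p_ms < alpha)
  if (m[2] < m[1] && m[2] < m[3] && mosaic_sig) return("V")
  if (m[2] > m[1] && m[2] > m[3] && mosaic_sig) return("inverted-V")
  if (m[1] <= m[2] && m[2] <= m[3] && m[1] < m[3] && p_gs < alpha) return("increase")
  if (m[1] >= m[2] && m[2] >= m[3] && m[1] > m[3] && p_gs < alpha) return("decrease")
  "flat"
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} is from regressing
#' predictor j on all others; `Inf` for perfectly collinear predictors.
#'
#' @param X Numeric predictor matrix (>= 2 columns).
#' @return Named VIF vector.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' Iterative VIF screening of collinear predictors
#'
#' Repeatedly drops the predictor with the largest VIF while any VIF meets
#' the threshold. A single remaining predictor is always retained.
#'
#' @param X Numeric predictor matrix with column names.
#' @param threshold Exclusion threshold (predictors with VIF >= threshold
#'   are candidates; default 10).
#' @return A list with `retained` (column names), `dropped` (in drop order)
#'   and `vif` (final VIFs of the retained set).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs column names")
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2) break
    v <- vif(X)
    if (all(v < threshold, na.rm = TRUE)) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  list(retained = colnames(X), dropped = dropped, vif = vif(X))
}

#' Redundancy analysis (explained variance and axes)
#'
#' Least-squares projection of the (column-centred) response matrix Y on the
#' predictors X followed by eigendecomposition of the fitted values; the
#' explained fraction is the trace of the fitted covariance over the trace
#' of the total covariance (the constrained proportion of inertia).
#'
#' @param Y Numeric response matrix (samples x responses).
#' @param X Numeric predictor matrix (samples x predictors).
#' @param scale_Y Scale responses to unit variance first (default `FALSE`).
#' @return A list of class `rda_result`: `explained` (fraction in \[0, 1\]),
#'   `eig` (constrained axis eigenvalues), `site_scores`, `predictor_cor`
#'   (predictor-axis correlations).
#' @export
rda_fit <- function(Y, X, scale_Y = FALSE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same rows")
  Yc <- scale(Y, center = TRUE, scale = scale_Y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (qr(Xc)$rank < ncol(Xc))
    stop("rank-deficient predictor matrix; apply stricter VIF filtering")
  fit <- stats::lm.fit(cbind(1, Xc), Yc)
  Yhat <- Yc - fit$residuals
  tot <- sum(Yc^2)
  if (tot <= 0) stop("response matrix has zero variance")
  sv <- svd(Yhat)
  eig <- sv$d^2 / (nrow(Y) - 1)
  keep <- eig > max(eig[1], 0) * 1e-10
  site <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(site) <- rownames(Y)
  pred_cor <- suppressWarnings(stats::cor(Xc, site))
  structure(list(explained = sum(Yhat^2) / tot, eig = eig[keep],
                 site_scores = site, predictor_cor = pred_cor),
            class = "rda_result")
}

r2_of <- function(Y, X) {
  if (is.null(X) || ncol(as.matrix(X)) == 0) return(0)
  rda_fit(Y, X)$explained
}

#' Permutation forward selection of predictors
#'
#' Greedy selection maximising added explained variance (redundancy-analysis
#' \eqn{R^2}); a candidate is admitted only if its added variance is
#' significant in a permutation test (residuals of the current model
#' permuted by default), and selection stops at the first rejection. The
#' permutation reference is the maximum added variance over all remaining
#' candidates, so the test accounts for best-of-candidates selection and
#' keeps the admission rate at the nominal level under a signal-free null.
#' Ties on added variance break lexicographically, so the path is invariant
#' to predictor column order.
#'
#' @param Y Response matrix.
#' @param X Candidate predictor matrix with column names.
#' @param config A [driver_config()].
#' @return A list of class `forward_selection`: `selected` (names in
#'   order), `path` (data.frame: predictor, added_r2, cumulative_r2, p,
#'   admitted) and `r2` (final model explained variance).
#' @export
forward_select <- function(Y, X, config = driver_config()) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs column names")
  set.seed(config$seed)
  selected <- character(0)
  path <- list()
  repeat {
    candidates <- setdiff(colnames(X), selected)
    if (!length(candidates)) break
    base_r2 <- r2_of(Y, X[, selected, drop = FALSE])
    added <- vapply(candidates, function(j)
      r2_of(Y, X[, c(selected, j), drop = FALSE]) - base_r2, numeric(1))
    best <- candidates[order(-added, candidates)][1]
    obs <- added[best]
    # permutation p for the added variance of `best`
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    if (length(selected)) {
      f <- stats::lm.fit(cbind(1, scale(X[, selected, drop = FALSE])), Yc)
      fitted_part <- Yc - f$residuals
      resid_part <- f$residuals
    } else {
      fitted_part <- matrix(0, nrow(Yc), ncol(Yc))
      resid_part <- Yc
    }
    exceed <- 0L
    for (k in seq_len(config$n_perm)) {
      pi <- sample.int(nrow(Y))
      Yp <- if (config$permute == "residual") fitted_part + resid_part[pi, , drop = FALSE]
            else Y[pi, , drop = FALSE]
      base_p <- r2_of(Yp, X[, selected, drop = FALSE])
      add_p <- max(vapply(candidates, function(j)
        r2_of(Yp, X[, c(selected, j), drop = FALSE]) - base_p, numeric(1)))
      if (add_p >= obs - 1e-12) exceed <- exceed + 1L
    }
    pval <- (exceed + 1) / (config$n_perm + 1)
    admitted <- pval < config$alpha && obs > 0
    path[[length(path) + 1]] <- data.frame(predictor = best, added_r2 = obs,
                                           cumulative_r2 = base_r2 + obs,
                                           p = pval, admitted = admitted)
    if (!admitted) break
    selected <- c(selected, best)
  }
  path <- if (length(path)) do.call(rbind, path) else
    data.frame(predictor = character(0), added_r2 = numeric(0),
               cumulative_r2 = numeric(0), p = numeric(0), admitted = logical(0))
  structure(list(selected = selected, path = path,
                 r2 = r2_of(Y, X[, selected, drop = FALSE])),
            class = "forward_selection")
}

#' Hierarchical partitioning of explained variance
#'
#' All-subsets decomposition: the individual effect of predictor j is the
#' average, over hierarchy levels h = 0..p-1, of the mean gain in explained
#' variance from adding j to a size-h subset not containing it. The
#' individual effects sum exactly to the joint explained variance of the
#' full model.
#'
#' @param Y Response matrix.
#' @param X Predictor matrix with at most `max_predictors` columns.
#' @param max_predictors Exhaustive-enumeration cap (default 12).
#' @return A list of class `hier_part`: `effects` (named individual
#'   effects) and `joint_r2`.
#' @export
hierarchical_partition <- function(Y, X, max_predictors = 12) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > max_predictors)
    stop("hierarchical partitioning is exhaustive; reduce to <= ",
         max_predictors, " predictors via VIF filtering or forward selection")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  # cache R2 of every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
    r2[mask + 1] <- r2_of(Y, X[, cols, drop = FALSE])
  }
  effects <- numeric(p)
  for (j in seq_len(p)) {
    bitj <- bitwShiftL(1L, j - 1L)
    level_gain <- numeric(p)   # mean gain at each level h+1 (h = |S|)
    level_n <- numeric(p)
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bitj) > 0) next
      h <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
      gain <- r2[bitwOr(mask, bitj) + 1] - r2[mask + 1]
      level_gain[h + 1] <- level_gain[h + 1] + gain
      level_n[h + 1] <- level_n[h + 1] + 1
    }
    effects[j] <- mean(level_gain[level_n > 0] / level_n[level_n > 0])
  }
  structure(list(effects = stats::setNames(effects, colnames(X)),
                 joint_r2 = r2[2^p]), class = "hier_part")
}

#' Pairwise Pearson correlations with p-values
#'
#' @param A Numeric matrix (samples x variables).
#' @param B Optional second matrix (default `A`).
#' @return A list with matrices `r` and `p` (two-sided); zero-variance
#'   columns yield `NA` rows/columns.
#' @export
pearson_matrix <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 paired observations")
  r <- suppressWarnings(stats::cor(A, B))
  r[!is.finite(r)] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  p[is.na(r)] <- NA_real_
  list(r = r, p = p)
}

#' Driver attribution for a response matrix
#'
#' Chains the attribution steps: VIF screening of the candidate
#' predictors, redundancy analysis of the retained set, permutation forward
#' selection, and hierarchical partitioning of the selected (or retained,
#' when selection is empty) predictors.
#'
#' @param Y Response matrix (e.g. multifunctionality indices or assembly
#'   process fractions).
#' @param X Candidate predictor matrix.
#' @param config A [driver_config()].
#' @return A list of class `driver_result`: `vif`, `rda`, `forward`,
#'   `hier_part`.
#' @export
driver_analysis <- function(Y, X, config = driver_config()) {
  vf <- vif_filter(X, config$vif_threshold)
  Xr <- as.matrix(X)[, vf$retained, drop = FALSE]
  rd <- rda_fit(Y, Xr)
  fs <- forward_select(Y, Xr, config)
  hp_cols <- if (length(fs$selected)) fs$selected else
    utils::head(vf$retained, 12)
  hp <- hierarchical_partition(Y, Xr[, hp_cols, drop = FALSE])
  structure(list(vif = vf, rda = rd, forward = fs, hier_part = hp,
                 config = config), class = "driver_result")
}
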
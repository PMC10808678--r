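#' Configuration for the multifunctionality indices
#'
#' @param q Hill order for the entropy-based index (default 1, the
#'   Shannon limit).
#' @param thresholds Threshold fractions of the per-function maximum
#'   (default 0.1 to 0.9 by 0.1).
#' @param n_subset_draws Monte-Carlo draws per subset size for the
#'   MF-vs-number-of-functions curves (default 200; subsets are enumerated
#'   exhaustively whenever there are at most `exhaustive_limit` of them).
#' @param exhaustive_limit Enumerate subsets exactly when
#'   `choose(N, k)` does not exceed this (default 10000).
#' @param max_definition `"observed_max"` uses each function's across-sample
#'   maximum as the threshold reference; `"mean_top_k"` uses the mean of the
#'   `top_k` largest values.
#' @param top_k Number of top values averaged under `"mean_top_k"`
#'   (default 3).
#' @param seed Integer seed for subset draws.
#' @return An `mf_config` list.
#' @export
mf_config <- function(q = 1, thresholds = seq(0.1, 0.9, 0.1),
                      n_subset_draws = 200, exhaustive_limit = 10000,
                      max_definition = c("observed_max", "mean_top_k"),
                      top_k = 3, seed = 1L) {
  max_definition <- match.arg(max_definition)
  stopifnot(q >= 0, all(thresholds > 0 & thresholds < 1), n_subset_draws >= 1)
  structure(list(q = q, thresholds = thresholds,
                 n_subset_draws = as.integer(n_subset_draws),
                 exhaustive_limit = exhaustive_limit,
                 max_definition = max_definition, top_k = as.integer(top_k),
                 seed = as.integer(seed)), class = "mf_config")
}

#' Reflect a function so that high values mean a good state
#'
#' \eqn{r(f) = -f + \max(f)}: the observed maximum maps to 0 and the order
#' is reversed, turning "high = bad" variables (e.g. pathogen loads,
#' antibiotic resistance gene abundances, stoichiometric ratios indicating
#' nutrient limitation) into "high = good" before unit scaling.
#'
#' @param values Non-empty numeric vector.
#' @return Reflected vector (same length).
#' @examples
#' reflect(c(1, 3, 5))  # 4 2 0
#' @export
reflect <- function(values) {
  if (!length(values) || !is.numeric(values)) stop("non-empty numeric vector required")
  -values + max(values)
}

#' Scale a function to \[0, 1\] by its maximum
#'
#' @param values Numeric vector with positive maximum.
#' @return `values / max(values)`.
#' @examples
#' unit_scale(c(2, 4))  # 0.5 1.0
#' @export
unit_scale <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) stop("maximum must be positive for unit scaling")
  values / m
}

#' Standardize a function matrix for multifunctionality indices
#'
#' Applies [reflect()] to every reflect-flagged registry column, then
#' [unit_scale()] column-wise. Columns that are constant at their maximum of
#' zero after reflection (no information) are dropped with a message and
#' recorded in the `dropped` attribute.
#'
#' @param fm A `function_matrix`.
#' @return Numeric matrix in \[0, 1\] with attributes `registry` (rows of
#'   surviving columns) and `dropped` (names of removed columns).
#' @export
standardize_functions <- function(fm) {
  reg <- attr(fm, "registry")
  vals <- unclass(fm)
  for (j in which(reg$reflect)) vals[, j] <- reflect(vals[, j])
  mx <- apply(vals, 2, max)
  drop <- mx <= 0
  if (any(drop))
    message("dropping ", sum(drop), " all-zero function column(s): ",
            paste(utils::head(colnames(vals)[drop], 5), collapse = ", "))
  vals <- vals[, !drop, drop = FALSE]
  vals <- sweep(vals, 2, mx[!drop], "/")
  structure(vals, registry = reg[!drop, , drop = FALSE],
            dropped = colnames(fm)[drop])
}

#' Averaging multifunctionality
#'
#' Arithmetic mean of the standardized functions in scope, per sample.
#'
#' @param F_std Standardized matrix from [standardize_functions()] (values
#'   in \[0, 1\]), or any numeric samples x functions matrix.
#' @param cols Optional column names restricting the scope.
#' @return Named per-sample vector in \[0, 1\].
#' @export
averaging_mf <- function(F_std, cols = NULL) {
  m <- scope_matrix(F_std, cols)
  rowMeans(m)
}

#' Entropy-based (effective-number) multifunctionality
#'
#' With per-sample function shares \eqn{p_i = f_i / \sum_j f_j}, the Hill
#' number \eqn{^qD} (at \eqn{q = 1}, \eqn{\exp(-\sum p_i \ln p_i)}) measures
#' the effective number of functions delivered; the index is
#' \eqn{A \times {}^qD / N} where \eqn{A} is the averaging multifunctionality
#' and \eqn{N} the number of functions in scope. It equals \eqn{A} under
#' perfect evenness and is always \eqn{\le A}. All-zero samples return 0.
#'
#' @inheritParams averaging_mf
#' @param q Hill order (default 1).
#' @return Named per-sample vector.
#' @export
entropy_mf <- function(F_std, cols = NULL, q = 1) {
  m <- scope_matrix(F_std, cols)
  N <- ncol(m)
  vapply(seq_len(nrow(m)), function(s) {
    f <- m[s, ]
    tot <- sum(f)
    if (tot <= 0) return(0)  # degenerate sample, by convention
    p <- f[f > 0] / tot
    qd <- if (abs(q - 1) < 1e-9) exp(-sum(p * log(p)))
          else sum(p^q)^(1 / (1 - q))
    mean(f) * qd / N
  }, numeric(1)) -> out
  stats::setNames(out, rownames(m))
}

#' Threshold multifunctionality
#'
#' Number (and proportion) of scope functions for which a sample attains at
#' least a fraction `t` of the function's reference maximum \eqn{M_i}
#' (across-sample observed maximum by default, or mean of the top-k values).
#'
#' @inheritParams averaging_mf
#' @param thresholds Fractions in (0, 1).
#' @param config An [mf_config()] (controls the maximum definition).
#' @return A list with `counts` and `proportions`, each a samples x
#'   thresholds matrix.
#' @export
threshold_mf <- function(F_std, cols = NULL, thresholds = seq(0.1, 0.9, 0.1),
                         config = mf_config()) {
  m <- scope_matrix(F_std, cols)
  stopifnot(all(thresholds > 0 & thresholds < 1))
  M <- switch(config$max_definition,
              observed_max = apply(m, 2, max),
              mean_top_k = apply(m, 2, function(x)
                mean(sort(x, decreasing = TRUE)[seq_len(min(config$top_k, length(x)))])))
  counts <- sapply(thresholds, function(t) rowSums(m >= rep(t * M, each = nrow(m))))
  counts <- matrix(counts, nrow = nrow(m),
                   dimnames = list(rownames(m), paste0("t", thresholds)))
  list(counts = counts, proportions = counts / ncol(m))
}

# Draw subsets of cols: exhaustive when feasible, else Monte-Carlo.
draw_subsets <- function(n, k, n_draws, exhaustive_limit) {
  if (choose(n, k) <= exhaustive_limit) {
    subs <- utils::combn(n, k, simplify = FALSE)
  } else {
    subs <- replicate(n_draws, sample.int(n, k), simplify = FALSE)
  }
  subs
}

#' Multifunctionality versus number of functions
#'
#' Mean and sd, over random (or exhaustive, when few) k-subsets of the scope
#' functions, of the averaging and entropy indices per sample. At `k = N`
#' the single subset is the full scope, so the curve ends exactly at the
#' full-scope index with sd 0.
#'
#' @inheritParams averaging_mf
#' @param ks Subset sizes (default `1:N`).
#' @param config An [mf_config()] (draws, q, seed).
#' @return A data.frame with columns `k`, `sample_id`, `index`
#'   (`"averaging"`/`"entropy"`), `mean`, `sd`, `n_subsets`.
#' @export
mf_vs_k <- function(F_std, cols = NULL, ks = NULL, config = mf_config()) {
  m <- scope_matrix(F_std, cols)
  N <- ncol(m)
  if (is.null(ks)) ks <- seq_len(N)
  if (any(ks < 1 | ks > N)) stop("subset sizes must lie in 1..N")
  set.seed(config$seed)
  out <- list()
  for (k in ks) {
    subs <- draw_subsets(N, k, config$n_subset_draws, config$exhaustive_limit)
    av <- vapply(subs, function(j) averaging_mf(m[, j, drop = FALSE]),
                 numeric(nrow(m)))
    en <- vapply(subs, function(j) entropy_mf(m[, j, drop = FALSE], q = config$q),
                 numeric(nrow(m)))
    if (nrow(m) == 1) { av <- matrix(av, 1); en <- matrix(en, 1) }
    sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
    out[[length(out) + 1]] <- data.frame(
      k = k, sample_id = rep(rownames(m), 2),
      index = rep(c("averaging", "entropy"), each = nrow(m)),
      mean = c(rowMeans(av), rowMeans(en)),
      sd = c(apply(av, 1, sd0), apply(en, 1, sd0)),
      n_subsets = length(subs))
  }
  do.call(rbind, out)
}

#' Geometric distance of a function pair from the 1:1 line
#'
#' For standardized values \eqn{(x, y)} the perpendicular distance of the
#' point to the line \eqn{y = x} is \eqn{|x - y| / \sqrt{2}}: 0 when the two
#' functions are delivered equally, largest when one is at its maximum and
#' the other absent.
#'
#' @param x,y Standardized function values (vectors recycle).
#' @return Non-negative distance(s).
#' @examples
#' tradeoff_distance(1, 0)  # 0.7071068
#' @export
tradeoff_distance <- function(x, y) abs(x - y) / sqrt(2)

#' Per-sample functional trade-off intensity
#'
#' Mean [tradeoff_distance()] over all \eqn{C(N, 2)} pairs of scope
#' functions, per sample; optionally the mean pairwise distance within
#' random k-subsets of functions (the intensity-vs-number-of-paired-functions
#' curve).
#'
#' @inheritParams averaging_mf
#' @param ks Optional subset sizes (each >= 2) for the per-k curve.
#' @param config An [mf_config()].
#' @return A list of class `tradeoff_result` with `intensity` (named
#'   per-sample vector) and, when `ks` is given, `curve` (data.frame `k`,
#'   `sample_id`, `mean`, `sd`, `n_subsets`).
#' @export
tradeoff_intensity <- function(F_std, cols = NULL, ks = NULL,
                               config = mf_config()) {
  m <- scope_matrix(F_std, cols)
  N <- ncol(m)
  if (N < 2) stop("trade-off intensity needs at least 2 functions in scope")
  intensity <- apply(m, 1, mean_pairwise_absdiff) / sqrt(2)
  curve <- NULL
  if (!is.null(ks)) {
    if (any(ks < 2 | ks > N)) stop("subset sizes must lie in 2..N")
    set.seed(config$seed)
    rows <- list()
    for (k in ks) {
      subs <- draw_subsets(N, k, config$n_subset_draws, config$exhaustive_limit)
      vals <- vapply(subs, function(j)
        apply(m[, j, drop = FALSE], 1, mean_pairwise_absdiff) / sqrt(2),
        numeric(nrow(m)))
      if (nrow(m) == 1) vals <- matrix(vals, 1)
      sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
      rows[[length(rows) + 1]] <- data.frame(
        k = k, sample_id = rownames(m),
        mean = rowMeans(vals), sd = apply(vals, 1, sd0),
        n_subsets = length(subs))
    }
    curve <- do.call(rbind, rows)
  }
  structure(list(intensity = intensity, curve = curve),
            class = "tradeoff_result")
}

# Mean |x_i - x_j| over all unordered pairs, via the sorted-order identity
# sum_{i<j} |x_i - x_j| = sum_i (2i - n - 1) x_(i).
mean_pairwise_absdiff <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * (n - 1) / 2)
}

#' All five multifunctionality indices for one scope
#'
#' Computes, per sample: (1) averaging MF over the full scope, (2) entropy
#' MF at the maximum number of functions, (3-4) the averaging and entropy
#' MF-vs-number-of-functions curves, and (5) threshold MF counts and
#' proportions across the configured threshold grid.
#'
#' @param fm A `function_matrix` (raw values; reflection and scaling are
#'   applied internally) or a pre-standardized matrix from
#'   [standardize_functions()].
#' @param scope `"aboveground"`, `"underground"` or `"entire"`.
#' @param config An [mf_config()].
#' @param ks Subset sizes for the curves (default an even grid of at most
#'   10 sizes up to N, always including N).
#' @return A list of class `multifunctionality_result` with `scope`,
#'   `averaging`, `entropy`, `curves`, `threshold` and `n_functions`.
#' @export
multifunctionality <- function(fm, scope = c("entire", "aboveground", "underground"),
                               config = mf_config(), ks = NULL) {
  scope <- match.arg(scope)
  F_std <- if (inherits(fm, "function_matrix")) standardize_functions(fm) else fm
  reg <- attr(F_std, "registry")
  cols <- if (!is.null(reg)) scope_functions(reg, scope) else colnames(F_std)
  m <- scope_matrix(F_std, cols)
  N <- ncol(m)
  if (is.null(ks)) ks <- unique(c(round(seq(1, N, length.out = min(10, N))), N))
  structure(list(
    scope = scope, n_functions = N,
    averaging = averaging_mf(m),
    entropy = entropy_mf(m, q = config$q),
    curves = mf_vs_k(m, ks = ks, config = config),
    threshold = threshold_mf(m, thresholds = config$thresholds, config = config)),
    class = "multifunctionality_result")
}

scope_matrix <- function(F_std, cols = NULL) {
  m <- if (is.null(cols)) F_std else {
    missing <- setdiff(cols, colnames(F_std))
    if (length(missing) == length(cols)) stop("no functions in scope")
    F_std[, intersect(cols, colnames(F_std)), drop = FALSE]
  }
  if (ncol(m) == 0) stop("no functions in scope")
  unclass(m)
}
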
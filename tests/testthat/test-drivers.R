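test_that("stage tests recover exact rank-sum p-values and degenerate statistics", {
  # three identical groups -> KW statistic 0
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("grass", "mosaic", "shrub"), each = 3)
  st <- stage_tests(v, g)
  expect_equal(st$kruskal$statistic, 0)

  # fully separated groups of 5: exact rank-sum p = 2/choose(10,5) = 2/252
  v2 <- c(1:5, 11:15)
  g2 <- rep(c("grass", "shrub"), each = 5)
  st2 <- stage_tests(v2, g2)
  expect_equal(st2$pairwise$p[1], 2 / 252, tolerance = 1e-12)

  expect_error(stage_tests(c(1, 2, 3), c("grass", "grass", "shrub")),
               "at least 2 observations")
})

test_that("Kruskal-Wallis type-I error is calibrated under label permutation", {
  set.seed(42)
  v <- rnorm(15)
  stages <- rep(c("grass", "mosaic", "shrub"), each = 5)
  rej <- mean(replicate(400, {
    stage_tests(v, sample(stages))$kruskal$p < 0.05
  }))
  # binomial 99% CI half-width at n = 400, p = 0.05: ~0.028
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("trajectory classification applies the V / inverted-V / monotone rules", {
  expect_equal(classify_trajectory(c(1, 0.2, 1.1), c(0.01, 0.8, 0.01)), "V")
  expect_equal(classify_trajectory(c(0.2, 1.5, 0.3), c(0.01, 0.9, 0.02)), "inverted-V")
  expect_equal(classify_trajectory(c(1, 2, 3), c(0.5, 0.01, 0.5)), "increase")
  expect_equal(classify_trajectory(c(3, 2, 1), c(0.5, 0.01, 0.5)), "decrease")
  expect_equal(classify_trajectory(c(1, 1, 1), c(0.01, 0.01, 0.01)), "flat")
  # monotone but non-significant end-to-end contrast -> flat
  expect_equal(classify_trajectory(c(1, 2, 3), c(0.5, 0.2, 0.5)), "flat")
  # mosaic extreme but no significant mosaic contrast -> falls through
  expect_equal(classify_trajectory(c(1, 0.2, 1.1), c(0.8, 0.9, 0.6)), "flat")
  # tie at one end resolved by a significant end-to-end difference
  expect_equal(classify_trajectory(c(1, 1, 2), c(0.9, 0.01, 0.04)), "increase")
})

test_that("VIFs equal brute-force auxiliary regressions and screening drops collinear columns", {
  set.seed(5)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.9 * x1 + 0.2 * rnorm(n)
  X <- cbind(a = x1, b = x2, c = x3)
  v <- vif(X)
  for (j in 1:3) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  # orthogonal (and intercept-orthogonal) predictors all retained with VIF 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  colnames(Q) <- c("q1", "q2", "q3")
  vo <- vif_filter(Q, 10)
  expect_equal(vo$retained, c("q1", "q2", "q3"))
  expect_true(all(abs(vo$vif - 1) < 1e-8))
  # duplicated column: exactly one of the pair dropped
  Xd <- cbind(a = x1, b = x2, a2 = x1)
  vd <- vif_filter(Xd, 10)
  expect_length(vd$dropped, 1)
  expect_true(vd$dropped %in% c("a", "a2"))
  expect_length(vd$retained, 2)
})

test_that("redundancy analysis matches closed forms and vegan", {
  set.seed(7)
  n <- 30
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  B <- matrix(c(1, 0.5, -0.3, 0.8), 2)
  # exact linear response: explained fraction 1
  Y_exact <- scale(X %*% B, scale = FALSE)
  expect_equal(rda_fit(Y_exact, X)$explained, 1, tolerance = 1e-10)
  # orthogonal response: explained fraction ~ 0
  Q <- qr.Q(qr(cbind(1, X, matrix(rnorm(n * 2), n))))
  Y_orth <- Q[, 4:5]
  expect_lt(rda_fit(Y_orth, X)$explained, 1e-10)
  # univariate case: squared Pearson correlation
  y <- rnorm(n); x <- rnorm(n)
  expect_equal(rda_fit(cbind(y), cbind(x = x))$explained,
               stats::cor(y, x)^2, tolerance = 1e-10)
  # multivariate random instance: agrees with vegan's constrained proportion
  Y <- matrix(rnorm(n * 4), n)
  vg <- vegan::rda(Y ~ X)
  expect_equal(rda_fit(Y, X)$explained,
               vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-8)
  expect_error(rda_fit(Y, cbind(a = x, b = x)), "rank-deficient")
})

test_that("forward selection is calibrated, powerful and order-invariant", {
  set.seed(3)
  n <- 20
  # null calibration: pure-noise predictors rarely admitted (scaled-down reps)
  n_sel <- vapply(1:30, function(seed) {
    set.seed(seed)
    Y <- matrix(rnorm(n * 2), n)
    X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
    fs <- forward_select(Y, X, driver_config(n_perm = 99, seed = seed))
    length(fs$selected)
  }, numeric(1))
  expect_gte(mean(n_sel == 0), 0.9)

  # power: one strong predictor among noise is selected first
  hits <- vapply(1:25, function(seed) {
    set.seed(seed + 100)
    x_true <- rnorm(n)
    Y <- cbind(x_true + rnorm(n, sd = 0.3), -x_true + rnorm(n, sd = 0.3))
    X <- cbind(signal = x_true, matrix(rnorm(n * 3), n,
                                       dimnames = list(NULL, paste0("noise", 1:3))))
    fs <- forward_select(Y, X, driver_config(n_perm = 99, seed = seed))
    length(fs$selected) >= 1 && fs$selected[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # same seed -> identical path; column order does not matter
  set.seed(9)
  Y <- matrix(rnorm(n * 2), n)
  X <- cbind(a = rnorm(n), b = rnorm(n), c = Y[, 1] + rnorm(n, sd = 0.2))
  cfg <- driver_config(n_perm = 99, seed = 11)
  f1 <- forward_select(Y, X, cfg)
  f2 <- forward_select(Y, X, cfg)
  f3 <- forward_select(Y, X[, c("c", "b", "a")], cfg)
  expect_identical(f1$path, f2$path)
  expect_identical(f1$selected, f3$selected)
})

test_that("hierarchical partitioning matches closed forms and sums to the joint R2", {
  set.seed(13)
  n <- 25
  # single predictor: individual effect = its R2
  Y <- matrix(rnorm(n * 2), n)
  x <- rnorm(n)
  hp1 <- hierarchical_partition(Y, cbind(x = x))
  expect_equal(unname(hp1$effects), r2 <- rda_fit(Y, cbind(x))$explained)
  # two orthogonal predictors: effects equal marginal R2s and sum to joint R2
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))[, 2:3]
  colnames(Q) <- c("u", "v")
  hp2 <- hierarchical_partition(Y, Q)
  expect_equal(unname(hp2$effects["u"]), rda_fit(Y, Q[, "u", drop = FALSE])$explained,
               tolerance = 1e-8)
  expect_equal(unname(hp2$effects["v"]), rda_fit(Y, Q[, "v", drop = FALSE])$explained,
               tolerance = 1e-8)
  expect_equal(sum(hp2$effects), hp2$joint_r2, tolerance = 1e-8)
  # correlated predictors: brute-force all-subsets oracle
  x1 <- rnorm(n); x2 <- 0.6 * x1 + rnorm(n); x3 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  hp3 <- hierarchical_partition(Y, X)
  r2f <- function(cols) if (!length(cols)) 0 else rda_fit(Y, X[, cols, drop = FALSE])$explained
  oracle <- vapply(colnames(X), function(j) {
    others <- setdiff(colnames(X), j)
    gains_by_level <- vapply(0:2, function(h) {
      subs <- if (h == 0) list(character(0)) else
        utils::combn(others, h, simplify = FALSE)
      mean(vapply(subs, function(S) r2f(c(S, j)) - r2f(S), numeric(1)))
    }, numeric(1))
    mean(gains_by_level)
  }, numeric(1))
  expect_equal(hp3$effects, oracle, tolerance = 1e-10)
  expect_equal(sum(hp3$effects), r2f(colnames(X)), tolerance = 1e-10)
  # invariance property on random instances
  for (k in 1:5) {
    Xr <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("p", 1:4)))
    hp <- hierarchical_partition(Y, Xr)
    expect_equal(sum(hp$effects), rda_fit(Y, Xr)$explained, tolerance = 1e-8)
  }
  expect_error(hierarchical_partition(Y, matrix(rnorm(n * 13), n)), "12")
})

test_that("pearson matrices match cor.test and flag zero-variance columns", {
  set.seed(2)
  A <- matrix(rnorm(5 * 2), 5, dimnames = list(NULL, c("a", "b")))
  pm <- pearson_matrix(A)
  expect_equal(pm$r["a", "a"], 1)
  ct <- stats::cor.test(A[, "a"], A[, "b"])
  expect_equal(pm$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pm$p["a", "b"], ct$p.value, tolerance = 1e-12)
  # x vs -x
  B <- cbind(x = A[, 1], negx = -A[, 1])
  pmB <- pearson_matrix(B)
  expect_equal(pmB$r["x", "negx"], -1)
  # zero-variance column flagged
  C <- cbind(c1 = A[, 1], const = rep(1, 5))
  pmC <- pearson_matrix(C)
  expect_true(is.na(pmC$r["c1", "const"]))
  expect_error(pearson_matrix(A[1:2, ]), "at least 3")
})

test_that("driver_analysis chains screening, ordination, selection and partitioning", {
  set.seed(31)
  n <- 15
  x_true <- rnorm(n)
  Y <- cbind(mf1 = x_true + rnorm(n, sd = 0.4), mf2 = 0.8 * x_true + rnorm(n, sd = 0.4))
  X <- cbind(driver = x_true, dup = x_true + rnorm(n, sd = 1e-8),
             noise = rnorm(n))
  res <- driver_analysis(Y, X, driver_config(n_perm = 99, seed = 7))
  expect_length(res$vif$dropped, 1)            # the duplicated pair loses one
  expect_true(any(c("driver", "dup") %in% res$forward$selected))
  expect_equal(sum(res$hier_part$effects), res$hier_part$joint_r2, tolerance = 1e-8)
})
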
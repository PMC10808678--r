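test_that("beta_mntd matches hand enumeration and degenerate identities", {
  # identical communities: each taxon's nearest neighbour is itself -> 0
  D <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(beta_mntd(c(A = 2, B = 1), c(A = 2, B = 1), D), 0)
  # single-taxon communities at patristic distance d -> d
  expect_equal(beta_mntd(c(A = 5), c(B = 1), D), 3)

  # 2-vs-2 toy with a printed 4x4 distance matrix and unequal abundances
  taxa <- c("A", "B", "C", "D")
  D4 <- matrix(c(0, 2, 6, 7,
                 2, 0, 5, 6,
                 6, 5, 0, 3,
                 7, 6, 3, 0), 4, 4, dimnames = list(taxa, taxa))
  a <- c(A = 3, B = 1)   # weights 0.75, 0.25
  b <- c(C = 1, D = 4)   # weights 0.2, 0.8
  # by hand: A->min(6,7)=6, B->min(5,6)=5 ; C->min(6,5)=5, D->min(7,6)=6
  # weighted: dir_a = .75*6+.25*5 = 5.75 ; dir_b = .2*5+.8*6 = 5.8 ; mean 5.775
  expect_equal(beta_mntd(a, b, D4), 5.775)
  expect_equal(beta_mntd(a, b, D4), bmntd_oracle(a, b, D4))
  # unweighted: (5.5 + 5.5)/2
  expect_equal(beta_mntd(a, b, D4, abundance_weighted = FALSE), 5.5)
  # symmetric in the order of communities
  expect_equal(beta_mntd(b, a, D4), beta_mntd(a, b, D4))

  expect_error(beta_mntd(c(A = 0), c(B = 1), D4), "empty")
  expect_error(beta_mntd(c(A = 1), c(Z = 1), D4), "missing")
})

test_that("beta_mntd agrees with picante::comdistnt on random communities", {
  set.seed(21)
  tr <- simulate_tree(25, seed = 21)
  comm <- matrix(rpois(6 * 25, 1.2), nrow = 6,
                 dimnames = list(paste0("s", 1:6), tr$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  D <- stats::cophenetic(tr)
  rel <- comm / rowSums(comm)
  ours <- shrubmf:::bmntd_pairs(rel, D[colnames(rel), colnames(rel)], TRUE)
  theirs <- as.matrix(picante::comdistnt(comm, D, abundance.weighted = TRUE))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("beta_nti matches the exhaustive tip-relabelling z-score on small trees", {
  # 4-tip tree, disjoint single-taxon communities: null enumerable over 4! maps
  tr4 <- simulate_tree(4, seed = 13)
  taxa <- tr4$tip.label
  comm <- matrix(0L, 2, 4, dimnames = list(c("x", "y"), taxa))
  comm["x", taxa[1]] <- 10L
  comm["y", taxa[3]] <- 10L
  oracle <- bnti_exhaustive_oracle(comm["x", ], comm["y", ], tr4)
  res <- beta_nti(community_table(comm, "bacteria"), tr4,
                  classifier_config(n_null = 999, seed = 3))
  expect_equal(res$bmntd_obs["x", "y"], oracle$obs, tolerance = 1e-10)
  # permutation estimate within Monte-Carlo error of the exhaustive z-score
  se_z <- 2 / sqrt(999)  # generous bound on the z-scale
  expect_lt(abs(res$bnti["x", "y"] - oracle$z), 4 * se_z + 0.05)

  # 6-tip tree with richer communities
  tr6 <- simulate_tree(6, seed = 29)
  t6 <- tr6$tip.label
  c6 <- matrix(0L, 2, 6, dimnames = list(c("x", "y"), t6))
  c6["x", t6[c(1, 2, 5)]] <- c(4L, 1L, 2L)
  c6["y", t6[c(3, 4)]] <- c(3L, 5L)
  oracle6 <- bnti_exhaustive_oracle(c6["x", ], c6["y", ], tr6)
  res6 <- beta_nti(community_table(c6, "bacteria"), tr6,
                   classifier_config(n_null = 999, seed = 8))
  expect_equal(res6$bmntd_obs["x", "y"], oracle6$obs, tolerance = 1e-10)
  expect_lt(abs(res6$bnti["x", "y"] - oracle6$z), 4 * 2 / sqrt(999) + 0.05)
})

test_that("degenerate nulls are flagged undefined", {
  # identical communities: observed and every null bMNTD are 0
  tr <- simulate_tree(5, seed = 2)
  comm <- matrix(2L, 2, 5, dimnames = list(c("x", "y"), tr$tip.label))
  res <- beta_nti(community_table(comm, "bacteria"), tr,
                  classifier_config(n_null = 49, seed = 1))
  expect_true(is.na(res$bnti["x", "y"]))

  # star tree with equal tip branches: every relabelling is isometric
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  cm <- matrix(0L, 2, 5, dimnames = list(c("x", "y"), star$tip.label))
  cm["x", 1:2] <- 3L; cm["y", 3:5] <- 2L
  res2 <- beta_nti(community_table(cm, "bacteria"), star,
                   classifier_config(n_null = 49, seed = 1))
  expect_true(is.na(res2$bnti["x", "y"]))
})

test_that("beta_nti is invariant to sample relabelling and deterministic in the seed", {
  d <- simulate_dataset(synth_config(groups = "fungi", taxa_per_group = 15, seed = 6))
  tab <- d$communities$fungi[1:4, ]
  tab <- community_table(unclass(tab)[, colSums(tab) > 0], "fungi")
  cfg <- classifier_config(n_null = 99, seed = 17)
  r1 <- beta_nti(tab, d$trees$fungi, cfg)
  r2 <- beta_nti(tab, d$trees$fungi, cfg)
  expect_identical(r1$bnti, r2$bnti)
  expect_equal(r1$bnti, t(r1$bnti))
})

test_that("raup_crick matches a shared-seed replay oracle and stays in [-1, 1]", {
  m <- matrix(c(8L, 1L, 1L,
                1L, 8L, 1L,
                4L, 3L, 3L),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  tab <- community_table(m, "nematodes")
  cfg <- classifier_config(n_null = 49, seed = 31)
  res <- raup_crick_bray(tab, cfg)

  # independent replay of the same null draws (same RNG stream)
  counts <- unclass(m)
  occ <- colSums(counts > 0)
  mrel <- colMeans(counts / rowSums(counts))
  rich <- rowSums(counts > 0); depth <- rowSums(counts)
  obs <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) obs[i, j] <- obs[j, i] <- bray_oracle(counts[i, ], counts[j, ])
  set.seed(cfg$seed)
  less <- ties <- matrix(0, 3, 3)
  for (k in seq_len(cfg$n_null)) {
    nm <- matrix(0, 3, 3)
    for (s in 1:3) {
      drawn <- sample.int(3, rich[s], prob = occ)
      x <- rep(1, rich[s])
      fill <- depth[s] - rich[s]
      if (fill > 0) x <- x + as.vector(stats::rmultinom(1, fill, mrel[drawn]))
      nm[s, drawn] <- x
    }
    for (i in 1:2) for (j in (i + 1):3) {
      b <- bray_oracle(nm[i, ], nm[j, ])
      if (b < obs[i, j] - 1e-10) { less[i, j] <- less[i, j] + 1; less[j, i] <- less[i, j] }
      else if (abs(b - obs[i, j]) <= 1e-10) { ties[i, j] <- ties[i, j] + 1; ties[j, i] <- ties[i, j] }
    }
  }
  rc_oracle <- 2 * ((less + 0.5 * ties) / cfg$n_null) - 1
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(res$rc[i, j], rc_oracle[i, j], tolerance = 1e-12)

  expect_true(all(res$rc >= -1 & res$rc <= 1, na.rm = TRUE))
})

test_that("raup_crick formula bounds hold in forced configurations", {
  # two samples sharing no taxa, each monodominant: observed bray = 1,
  # nulls drawn from a pool where co-occurrence is possible -> rc near +1
  m <- matrix(c(20L, 0L, 5L,
                0L, 20L, 5L,
                10L, 10L, 5L),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  res <- raup_crick_bray(community_table(m, "protists"),
                         classifier_config(n_null = 199, seed = 4))
  expect_true(all(res$rc >= -1 & res$rc <= 1, na.rm = TRUE))
})

test_that("the five-way process classifier reproduces every rule", {
  cfg <- classifier_config()
  expect_equal(as.character(classify_process(2.5, 0.1, cfg)), "variable selection")
  expect_equal(as.character(classify_process(-2.5, 0.1, cfg)), "homogeneous selection")
  expect_equal(as.character(classify_process(0.5, 0.97, cfg)), "dispersal limitation")
  expect_equal(as.character(classify_process(0.5, -0.97, cfg)), "homogenizing dispersal")
  expect_equal(as.character(classify_process(0.5, 0.5, cfg)), "drift")
  expect_equal(as.character(classify_process(-1.99, -0.5, cfg)), "drift")
  # boundary convention: equality falls to the stochastic / drift side
  expect_equal(as.character(classify_process(2, 0.5, cfg)), "drift")
  expect_equal(as.character(classify_process(-2, 0.5, cfg)), "drift")
  expect_equal(as.character(classify_process(0, 0.95, cfg)), "drift")
  expect_equal(as.character(classify_process(0, -0.95, cfg)), "drift")
  # undefined bNTI -> no label
  expect_true(is.na(classify_process(NA_real_, 0.99, cfg)))
})

test_that("assembly_analysis yields symmetric matrices and unit fraction sums", {
  d <- simulate_dataset(synth_config(groups = "archaea", taxa_per_group = 20, seed = 12))
  tab <- d$communities$archaea[1:6, ]
  tab <- community_table(unclass(tab)[, colSums(tab) > 0], "archaea")
  a <- assembly_analysis(tab, d$trees$archaea, classifier_config(n_null = 99, seed = 3))
  expect_equal(a$bnti$bnti, t(a$bnti$bnti))
  expect_equal(a$rc$rc, t(a$rc$rc))
  defined <- !is.na(a$pairs$process)
  if (any(defined)) expect_equal(sum(a$fractions), 1, tolerance = 1e-9)
  expect_equal(nrow(a$pairs), choose(6, 2))
})

test_that("phylogenetic correlograms detect Brownian signal and flag degenerate traits", {
  tr <- simulate_tree(40, seed = 3)
  flat <- stats::setNames(rep(1, 40), tr$tip.label)
  expect_true(phylo_correlogram(flat, tr)$undefined)

  med_short <- stats::median(vapply(1:20, function(seed) {
    trs <- simulate_tree(40, seed = seed)
    set.seed(seed + 900)
    niche <- ape::rTraitCont(trs, sigma = 1)
    pc <- phylo_correlogram(niche, trs, n_classes = 4, n_perm = 49, seed = seed)
    pc$classes$mantel_r[1]
  }, numeric(1)))
  expect_gt(med_short, 0)
})

test_that("permuted niche values give approximately uniform correlogram p-values", {
  tr <- simulate_tree(30, seed = 77)
  set.seed(78)
  niche <- ape::rTraitCont(tr, sigma = 1)
  ps <- vapply(1:120, function(k) {
    shuffled <- stats::setNames(sample(niche), names(niche))
    pc <- phylo_correlogram(shuffled, tr, n_classes = 3, n_perm = 49, seed = k)
    pc$classes$p[1]
  }, numeric(1))
  # KS test against uniform should not reject at alpha = 0.01
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
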
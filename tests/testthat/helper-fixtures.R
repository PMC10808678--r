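# Shared fixtures and independent oracles. Everything here is deliberately
# naive (enumeration, direct formulas) so it cannot share bugs with the
# package's implementations.

toy_community <- function(group = "bacteria") {
  m <- matrix(c(50L, 30L, 15L,  5L,  0L,
                40L, 40L, 10L,  8L,  2L,
                60L, 20L, 10L,  9L,  1L,
                55L, 25L, 12L,  6L,  2L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:5)))
  community_table(m, group)
}

# all permutations of 1:n (n small), recursively
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) {
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(p, n, after = pos - 1)
  }
  out
}

# brute-force Bray-Curtis between two count/abundance vectors
bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# brute-force Spearman correlation of lower triangles of two distance matrices
spearman_lower <- function(d1, d2) {
  stats::cor(rank(as.vector(d1)), rank(as.vector(d2)))
}

# brute-force abundance-weighted bMNTD between two named abundance vectors
bmntd_oracle <- function(a, b, D, weighted = TRUE) {
  a <- a[a > 0]; b <- b[b > 0]
  term <- function(from, to) {
    w <- if (weighted) from / sum(from) else rep(1 / length(from), length(from))
    s <- 0
    for (i in seq_along(from)) {
      dmin <- min(D[names(from)[i], names(to)])
      s <- s + w[i] * dmin
    }
    s
  }
  unname((term(a, b) + term(b, a)) / 2)
}

# exhaustive taxa-label-shuffle z-score of bMNTD for small trees
bnti_exhaustive_oracle <- function(comm_a, comm_b, tree, weighted = TRUE) {
  D <- stats::cophenetic(tree)
  taxa <- tree$tip.label
  obs <- bmntd_oracle(comm_a, comm_b, D, weighted)
  nulls <- vapply(perms(length(taxa)), function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- list(taxa, taxa)
    bmntd_oracle(comm_a, comm_b, Dp, weighted)
  }, numeric(1))
  list(obs = obs, null_mean = mean(nulls), null_sd = stats::sd(nulls),
       z = (obs - mean(nulls)) / stats::sd(nulls))
}

# small standardized function matrix for multifunctionality identities
toy_fstd <- function() {
  matrix(c(1.0, 0.5, 0.2,
           0.4, 0.4, 0.4,
           0.0, 1.0, 0.6),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("s", 1:3), paste0("f", 1:3)))
}
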
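# Shared fixtures: small random correlation blocks, a dense-likelihood oracle
# and a compact genetic map used across test files.

# Random PSD matrix with unit diagonal (correlation-like), single block.
rand_corr <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  G <- tcrossprod(A) / n
  d <- 1 / sqrt(diag(G))
  G * tcrossprod(d)
}

rand_km <- function(block_sizes, seed, kind = "realized_2phi") {
  mats <- lapply(seq_along(block_sizes),
                 function(b) rand_corr(block_sizes[b], seed + b))
  N <- sum(block_sizes)
  big <- matrix(0, N, N)
  pos <- 0L
  for (b in seq_along(mats)) {
    ix <- pos + seq_len(block_sizes[b])
    big[ix, ix] <- mats[[b]]
    pos <- pos + block_sizes[b]
  }
  new_kinship_matrix(big, ids = paste0("i", seq_len(N)), kind = kind,
                     blocks = rep(seq_along(block_sizes), block_sizes))
}

# Dense multivariate normal log-likelihood without the 2*pi constant:
# the independent oracle for the eigen-scale likelihood.
dense_loglik <- function(h2, s2, G, y) {
  S <- s2 * (h2 * G + (1 - h2) * diag(nrow(G)))
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (ld + drop(crossprod(y, solve(S, y))))
}

small_map <- function() genetic_map(as.character(1:4), c(120, 90, 80, 70))

# A two-founder + one-child pedigree where everyone is analyzed.
trio_pedigree <- function() {
  f <- tempfile(fileext = ".fam")
  writeLines(c("F1 1 0 0", "F1 2 0 0", "F1 3 1 2"), f)
  build_pedigree(file = f)
}
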
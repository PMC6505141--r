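test_that("pool allele frequencies match the generating spectrum", {
  map <- small_map()
  pool <- simulate_founder_haplotypes(map, M = 400, n_haplotypes = 200,
                                      seed = 2, ld = 0.4)
  expect_true(all(pmin(pool$markers$p, 1 - pool$markers$p) >= 0.05))
  phat <- colMeans(pool$haplotypes)
  z <- abs(phat - pool$markers$p) /
    sqrt(pool$markers$p * (1 - pool$markers$p) / 200)
  expect_gt(mean(z < 4), 0.99)
  # positions inside their chromosomes, counts proportional to length
  L <- map$length_cm[match(pool$markers$chrom, map$chrom)]
  expect_true(all(pool$markers$pos_cM >= 0 & pool$markers$pos_cM <= L))
  cnt <- table(factor(pool$markers$chrom, levels = map$chrom))
  expect_true(all(abs(cnt - 400 * map$length_cm / sum(map$length_cm)) <= 1))
})

test_that("the LD parameter controls adjacent-marker correlation", {
  map <- genetic_map("1", 100)
  adj_cor <- function(ld, seed) {
    pool <- simulate_founder_haplotypes(map, M = 200, n_haplotypes = 400,
                                        seed = seed, ld = ld)
    H <- pool$haplotypes
    mean(vapply(seq_len(199), function(j) {
      suppressWarnings(r <- cor(H[, j], H[, j + 1]))
      if (is.na(r)) 0 else r
    }, numeric(1)))
  }
  expect_lt(abs(adj_cor(0, 7)), 0.02)
  expect_gt(adj_cor(0.9, 7), 0.3)
})

test_that("generator parameter validation", {
  map <- small_map()
  expect_error(simulate_founder_haplotypes(map, 10, 4, 1, maf_min = 0.5),
               "maf_min")
  expect_error(simulate_founder_haplotypes(map, 10, 4, 1, ld = 1), "ld")
})

test_that("genotype drop-down is a deterministic founder-allele lookup", {
  map <- small_map()
  ped <- trio_pedigree()  # founders analyzed too
  dr <- simulate_descent(ped, map, m = 1, seed = 11)
  pool <- simulate_founder_haplotypes(map, M = 60, n_haplotypes = 4, seed = 12)
  geno <- drop_genotypes(dr, pool)
  # founder genotype = sum of its own two pool haplotypes
  expect_equal(geno$dosage[1, ], unname(pool$haplotypes[1, ] +
                                        pool$haplotypes[2, ]))
  expect_equal(geno$dosage[2, ], unname(pool$haplotypes[3, ] +
                                        pool$haplotypes[4, ]))
  # monomorphic-in-pool marker gives identical dosages
  pool$haplotypes[, 5] <- 1L
  geno <- drop_genotypes(dr, pool)
  expect_true(all(geno$dosage[, 5] == 2L))
  # rerun is bitwise identical (no randomness in the drop)
  expect_identical(geno$dosage, drop_genotypes(dr, pool)$dosage)
})

test_that("IBD-identical regions are IBS-identical without error", {
  ped <- build_pedigree("sibpair")
  map <- genetic_map("1", 1e-6)  # one effectively single-locus chromosome
  found <- FALSE
  for (s in 1:50) {
    dr <- simulate_descent(ped, map, m = 1, seed = s)
    rk <- realized_kinship(dr)
    if (rk$matrix[1, 2] == 1) {  # sibs share both haplotypes IBD
      pool <- simulate_founder_haplotypes(map, M = 40, n_haplotypes = 4,
                                          seed = s)
      geno <- drop_genotypes(dr, pool)
      expect_equal(geno$dosage[1, ], geno$dosage[2, ])
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("classic GRM entries follow the standardized cross-product formula", {
  geno <- structure(list(dosage = matrix(c(2L, 2L), 2, 1),
                         markers = data.frame(chrom = "1", pos_cM = 1,
                                              p = 0.5),
                         ids = c("a", "b"), blocks = c(1L, 1L)),
                    class = "genotype_matrix")
  G <- classic_grm(geno)
  expect_equal(G$matrix["a", "b"], (2 - 1) * (2 - 1) / (2 * 0.5 * 0.5))
  Gc <- classic_grm(geno, constrain_diagonal = TRUE)
  expect_true(all(diag(Gc$matrix) == 1))
  expect_error(classic_grm(geno, freqs = 1), "strictly")
})

test_that("classic GRM is invariant to allele label swaps and block-sparse", {
  map <- small_map()
  ped <- build_pedigree("sibship", size = 3)
  dr <- simulate_descent(ped, map, m = 2, seed = 14)
  pool <- simulate_founder_haplotypes(map, M = 150,
                                      n_haplotypes = length(founder_labels(dr)),
                                      seed = 15)
  geno <- drop_genotypes(dr, pool)
  G <- classic_grm(geno)
  flip <- sample(150, 40)
  geno2 <- geno
  geno2$dosage[, flip] <- 2L - geno2$dosage[, flip]
  geno2$markers$p[flip] <- 1 - geno2$markers$p[flip]
  expect_equal(classic_grm(geno2)$matrix, G$matrix, tolerance = 1e-12)
  expect_true(all(G$matrix[1:3, 4:6] == 0))
})

test_that("the classic GRM is unbiased for twice realized kinship over panels", {
  ped <- build_pedigree("sibpair")
  map <- small_map()
  dr <- simulate_descent(ped, map, m = 1, seed = 20)
  target <- realized_kinship(dr)$matrix[1, 2]
  ent <- vapply(1:200, function(r) {
    pool <- simulate_founder_haplotypes(map, M = 300, n_haplotypes = 4,
                                        seed = 5000 + r, ld = 0.3)
    classic_grm(drop_genotypes(dr, pool))$matrix[1, 2]
  }, numeric(1))
  se <- sd(ent) / sqrt(length(ent))
  expect_lt(abs(mean(ent) - target), 3 * se)
})

test_that("denser panels stop helping under strong LD (variance plateau)", {
  ped <- build_pedigree("sibpair")
  map <- genetic_map(c("1", "2"), c(100, 100))
  dr <- simulate_descent(ped, map, m = 1, seed = 33)
  entvar <- function(M) {
    var(vapply(1:120, function(r) {
      pool <- simulate_founder_haplotypes(map, M = M, n_haplotypes = 4,
                                          seed = 9000 + r, ld = 0.95)
      classic_grm(drop_genotypes(dr, pool))$matrix[1, 2]
    }, numeric(1)))
  }
  v1 <- entvar(250)
  v4 <- entvar(1000)
  expect_lt(v1 / v4, 2)  # a 4x denser panel gains less than 2x in variance
})

test_that("pool / descent compatibility is enforced", {
  ped <- build_pedigree("sibship", size = 3)
  dr <- simulate_descent(ped, small_map(), m = 2, seed = 1)
  pool <- simulate_founder_haplotypes(small_map(), M = 20, n_haplotypes = 4,
                                      seed = 1)
  expect_error(drop_genotypes(dr, pool), "founder haplotype labels")
})
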
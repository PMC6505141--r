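test_that("eigen-transform preserves norms and recovers sibship eigenvalues", {
  km <- rand_km(c(5, 4, 6), seed = 1)
  set.seed(2)
  y <- rnorm(15)
  et <- eigen_transform(km, y)
  expect_equal(sum(et$ystar^2), sum(y^2), tolerance = 1e-12)
  sib <- rep_kinship(pedigree_kinship(build_pedigree("sibship", size = 14)), 3)
  lam <- sort(eigen_transform(sib)$lambda)
  expect_equal(lam, sort(c(rep(7.5, 3), rep(0.5, 39))), tolerance = 1e-12)
})

test_that("eigen-scale likelihood equals the dense MVN likelihood", {
  for (s in 1:5) {
    km <- rand_km(c(6), seed = 100 + s)
    set.seed(200 + s)
    y <- rnorm(6)
    et <- eigen_transform(km, y)
    for (h2 in c(0.1, 0.5, 0.9)) {
      expect_lt(abs(log_likelihood(h2, 1.3, et) -
                    dense_loglik(h2, 1.3, km$matrix, y)), 1e-8)
    }
  }
  # multi-block case
  km <- rand_km(c(4, 5), seed = 300)
  set.seed(301)
  y <- rnorm(9)
  et <- eigen_transform(km, y)
  expect_lt(abs(log_likelihood(0.35, 0.8, et) -
                dense_loglik(0.35, 0.8, km$matrix, y)), 1e-8)
})

test_that("likelihood is flat in h2 when all eigenvalues are 1", {
  km <- new_kinship_matrix(diag(6), paste0("i", 1:6), "pedigree_2psi",
                           rep(1L, 6))
  set.seed(4)
  y <- rnorm(6)
  et <- eigen_transform(km, y)
  expect_equal(log_likelihood(0.2, 1, et), log_likelihood(0.8, 1, et))
  # a zero eigenvalue channel makes the likelihood undefined at h2 = 1
  eig0 <- structure(list(lambda = c(0, 2), ystar = c(1, 1)),
                    class = "eigen_structure")
  expect_error(log_likelihood(1, 1, eig0), "nonpositive")
})

test_that("the profiled variance maximizes the likelihood at fixed h2", {
  km <- rand_km(c(7), seed = 9)
  set.seed(10)
  y <- rnorm(7)
  et <- eigen_transform(km, y)
  h2 <- 0.4
  v <- h2 * et$lambda + 1 - h2
  s2hat <- mean(et$ystar^2 / v)
  l0 <- log_likelihood(h2, s2hat, et)
  expect_gt(l0, log_likelihood(h2, s2hat * 1.05, et))
  expect_gt(l0, log_likelihood(h2, s2hat * 0.95, et))
})

test_that("fit_mle matches a dense-likelihood numerical maximizer", {
  for (s in 1:4) {
    sib <- rep_kinship(pedigree_kinship(build_pedigree("sibship", size = 4)),
                       3)  # N = 12
    y <- simulate_trait(sib, trait_model(0.6, 1.2), seed = 400 + s)
    fit <- fit_mle(y, sib)
    oracle <- optim(c(0.5, 0), function(par) {
      -dense_loglik(par[1], exp(par[2]), sib$matrix, y)
    }, method = "L-BFGS-B", lower = c(1e-9, -5), upper = c(1 - 1e-9, 5),
    control = list(factr = 10))
    if (oracle$par[1] > 1e-6 && oracle$par[1] < 1 - 1e-6) {
      expect_lt(abs(fit$h2 - oracle$par[1]), 1e-5)
      expect_lt(abs(fit$sigma2 - exp(oracle$par[2])), 1e-4)
    }
    expect_gte(fit$loglik + 1e-9, -oracle$value)
  }
})

test_that("identity correlation is flagged unidentifiable with sigma2 = mean(y^2)", {
  km <- new_kinship_matrix(diag(8), paste0("i", 1:8), "pedigree_2psi",
                           rep(1L, 8))
  set.seed(6)
  y <- rnorm(8)
  fit <- fit_mle(y, km)
  expect_false(fit$identifiable)
  expect_true(fit$boundary)
  expect_equal(fit$sigma2, mean(y^2))
  expect_error(fit_mle(rep(1, 8), km), "degenerate")
})

test_that("simulated traits have the model covariance", {
  # h2 = 0: iid N(0, sigma2) whatever the correlation matrix
  sib <- rep_kinship(pedigree_kinship(build_pedigree("sibpair")), 300)
  y0 <- simulate_trait(sib, trait_model(0, 2), seed = 7)
  sibcov0 <- cov(y0[seq(1, 599, 2)], y0[seq(2, 600, 2)])
  expect_lt(abs(sibcov0), 3 * 2 / sqrt(300))
  # h2 = 0.5 on one sibship block: empirical covariance near the target
  blk <- pedigree_kinship(build_pedigree("sibship", size = 6))
  set.seed(8)
  Y <- t(replicate(5000, simulate_trait(blk, trait_model(0.5, 1))))
  target <- 0.5 * blk$matrix + 0.5 * diag(6)
  emp <- cov(Y)
  # MC standard error of a covariance entry is about sqrt((1+target^2)/n)
  expect_true(all(abs(emp - target) <
                  3 * sqrt((1 + target^2) / 5000) + 0.01))
})

test_that("the MLE recovers heritability under correct specification", {
  sib <- rep_kinship(pedigree_kinship(build_pedigree("sibship", size = 8)),
                     60)
  for (h0 in c(0.2, 0.5, 0.8)) {
    h2hat <- vapply(1:50, function(r) {
      y <- simulate_trait(sib, trait_model(h0, 1),
                          seed = 10000 * h0 + r)
      fit_mle(y, sib)$h2
    }, numeric(1))
    se <- sd(h2hat) / sqrt(length(h2hat))
    expect_lt(abs(mean(h2hat) - h0), 3 * se)
  }
})

test_that("the likelihood is invariant to permuting pedigree blocks", {
  km <- rand_km(c(4, 4), seed = 50)
  set.seed(51)
  y <- rnorm(8)
  perm <- c(5:8, 1:4)
  km2 <- new_kinship_matrix(km$matrix[perm, perm], km$ids[perm],
                            km$kind, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  et1 <- eigen_transform(km, y)
  et2 <- eigen_transform(km2, y[perm])
  expect_equal(log_likelihood(0.4, 1.1, et1), log_likelihood(0.4, 1.1, et2),
               tolerance = 1e-12)
  expect_equal(fit_mle(y, km)$h2, fit_mle(y[perm], km2)$h2,
               tolerance = 1e-7)
})

test_that("dimension mismatches and non-PSD truths error", {
  km <- rand_km(c(4), seed = 60)
  expect_error(eigen_transform(km, rnorm(5)), "dimension")
  bad <- km
  bad$matrix[1, 2] <- bad$matrix[2, 1] <- 5  # breaks PSD badly
  expect_error(simulate_trait(bad, trait_model(0.5), seed = 1),
               "positive semi-definite")
})
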
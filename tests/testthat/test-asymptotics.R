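# Expected eigen-scale log-likelihood under the true distribution: only the
# channel variances a_i enter. Used as a finite-difference oracle for both
# the correct-specification ASV and the sandwich J matrix.
expected_loglik <- function(h2, s2, lambda, a) {
  v <- h2 * lambda + 1 - h2
  -0.5 * (length(lambda) * log(s2) + sum(log(v)) + sum(a / v) / s2)
}

num_hessian <- function(f, x, h = c(1e-5, 1e-5)) {
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- ej <- c(0, 0)
      ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                  f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

test_that("closed-form ASV equals the inverse expected Fisher information", {
  set.seed(1)
  lambda <- c(runif(40, 0.2, 0.9), runif(20, 1.5, 4))
  for (h2 in c(0.3, 0.6)) {
    a <- (h2 * lambda + 1 - h2) * 1.0  # correct specification, sigma2 = 1
    H <- num_hessian(function(th) expected_loglik(th[1], th[2], lambda, a),
                     c(h2, 1))
    expect_equal(asv_correct(lambda, h2), solve(-H)[1, 1], tolerance = 1e-4)
  }
})

test_that("identity eigenvalues make the heritability unidentifiable (infinite ASV)", {
  expect_warning(v <- asv_correct(rep(1, 50), 0.5), "unidentifiable")
  expect_identical(v, Inf)
})

test_that("the eigenvalue influence summand is V-shaped with minimum at 1", {
  grid <- seq(0.05, 8, by = 0.05)
  for (h2 in c(0.2, 0.5, 0.8)) {
    s <- asv_summand(grid, h2)
    expect_equal(grid[which.min(s)], 1, tolerance = 0.051)
    d <- diff(s)
    expect_true(all(d[grid[-1] <= 1] < 0))
    expect_true(all(d[grid[-length(grid)] >= 1] > 0))
  }
})

test_that("pseudo-true parameters equal the truth under correct specification", {
  for (s in 1:3) {
    km <- rand_km(c(5, 6), seed = 70 + s)
    for (h0 in c(0.25, 0.7)) {
      pt <- pseudo_true(misspec_problem(km, km, h0, 1.4))
      expect_equal(pt$h2, h0, tolerance = 1e-6)
      expect_equal(pt$sigma2, 1.4, tolerance = 1e-6)
      expect_false(pt$boundary)
    }
  }
})

test_that("sandwich reduces to the information identity when Delta = 0", {
  km <- rand_km(c(6, 5, 7), seed = 80)
  prob <- misspec_problem(km, km, 0.45, 1.1)
  sw <- sandwich_acov(prob)
  lam <- eigen_transform(km)$lambda
  expect_equal(sw$ase_h2, sqrt(asv_correct(lam, 0.45)), tolerance = 1e-6)
  expect_equal(sw$K, -sw$J, tolerance = 1e-6)
  expect_equal(unname(sw$theta1), c(0.45, 1.1), tolerance = 1e-6)
})

test_that("J matches the printed Hessian element and a finite-difference oracle", {
  ped <- build_pedigree("sibship", size = 6)
  dr <- simulate_descent(ped, small_map(), m = 8, seed = 90)
  Gt <- rep_kinship(pedigree_kinship(ped), 8)
  Gf <- realized_kinship(dr)
  prob <- misspec_problem(Gt, Gf, 0.5, 1)
  pt <- pseudo_true(prob)
  sw <- sandwich_acov(prob, pt)
  lam <- prob$lambda; a <- prob$a; N <- prob$N
  v1 <- pt$h2 * lam + 1 - pt$h2
  # the printed closed form for the (h2, h2) element of J
  J11_printed <- sum((lam - 1)^2 / v1^2 -
                     2 * (lam - 1)^2 * a / (pt$sigma2 * v1^3)) / (2 * N)
  expect_equal(sw$J[1, 1], J11_printed, tolerance = 1e-12)
  # full J against numerical differentiation of the expected log-likelihood
  Hn <- num_hessian(function(th) expected_loglik(th[1], th[2], lam, a) / N,
                    c(pt$h2, pt$sigma2))
  expect_equal(unname(sw$J), Hn, tolerance = 1e-5)
})

test_that("K matches the Monte-Carlo covariance of the score", {
  ped <- build_pedigree("sibship", size = 5)
  dr <- simulate_descent(ped, small_map(), m = 6, seed = 91)
  Gt <- realized_kinship(dr)
  Gf <- rep_kinship(pedigree_kinship(ped), 6)
  prob <- misspec_problem(Gt, Gf, 0.5, 1)
  pt <- pseudo_true(prob)
  sw <- sandwich_acov(prob, pt)
  lam <- prob$lambda
  v1 <- pt$h2 * lam + 1 - pt$h2
  et <- eigen_transform(Gf)
  model <- trait_model(0.5, 1)
  set.seed(92)
  B <- 4000
  sc <- matrix(0, B, 2)
  for (b in seq_len(B)) {
    y <- simulate_trait(Gt, model)
    ys2 <- unlist(lapply(seq_along(et$block_index), function(k) {
      crossprod(et$vectors[[k]], y[et$block_index[[k]]])[, 1]^2
    }), use.names = FALSE)
    sc[b, 1] <- -0.5 * sum((lam - 1) / v1) +
      sum(ys2 * (lam - 1) / v1^2) / (2 * pt$sigma2)
    sc[b, 2] <- -prob$N / (2 * pt$sigma2) +
      sum(ys2 / v1) / (2 * pt$sigma2^2)
  }
  Kmc <- cov(sc) / prob$N
  expect_equal(unname(sw$K), unname(Kmc), tolerance = 0.1)
  # the expected total score vanishes at the pseudo-true parameters
  expect_lt(max(abs(colMeans(sc))), 3 * max(sqrt(diag(cov(sc)) / B)))
})

test_that("fitting pedigree kinship under realized-kinship truth is consistent", {
  ped <- build_pedigree("sibship", size = 14)
  draws <- lapply(1:64, function(r) {
    dr <- simulate_descent(ped, m = 1, seed = 600 + r)
    realized_kinship(dr)
  })
  tr <- consistency_check_pedigree_fit(draws, ped, h2_0 = 0.5,
                                       m_grid = c(1, 16, 64))
  expect_lt(tr$max_abs_q[3], tr$max_abs_q[1])
  expect_lt(abs(tr$h2_pseudo_true[3] - 0.5), 0.02)
  # and with many pedigrees the sandwich ASE approaches the correct-model
  # ASV computed from the 2Psi eigenvalues
  Gt <- bind_kinship(draws)
  Gf <- rep_kinship(pedigree_kinship(ped), 64)
  sw <- sandwich_acov(misspec_problem(Gt, Gf, 0.5, 1))
  lam_psi <- eigen_transform(Gf)$lambda
  expect_equal(sw$ase_h2, sqrt(asv_correct(lam_psi, 0.5)), tolerance = 0.05)
})

test_that("fitting a broader matrix than the truth causes little bias", {
  ped <- build_pedigree("sibship", size = 14)
  dr <- simulate_descent(ped, m = 100, seed = 95)
  star <- realized_kinship(dr, "22")
  phi <- realized_kinship(dr)
  pt <- pseudo_true(misspec_problem(star, phi, 0.5, 1))
  expect_lt(abs(pt$h2 - 0.5), 0.02)
})

test_that("problem construction validates its inputs", {
  km1 <- rand_km(c(4, 4), seed = 96)
  km2 <- rand_km(c(8), seed = 97)
  expect_error(misspec_problem(km1, km2, 0.5), "block partition")
  expect_error(asv_correct(c(0.5, 2, 1), h2 = 0), "h2 > 0")
})
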
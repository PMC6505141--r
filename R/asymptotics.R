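#' Asymptotic sampling variance of the heritability MLE (correct model)
#'
#' Under a correctly specified two-component model the large-sample variance
#' of the heritability estimate is
#' `ASV(h2) = 2 / [ sum_i w_i^2 - (1/N) (sum_i w_i)^2 ]` with
#' `w_i = (lambda_i - 1) / (h2 lambda_i + 1 - h2)`, where lambda_i are the
#' eigenvalues of the genetic correlation matrix. The formula already
#' incorporates the sample size through the eigenvalue list, so its square
#' root is directly the asymptotic standard error of the estimate. When all
#' eigenvalues equal 1 the heritability is unidentifiable and the ASV is
#' infinite (returned as `Inf` with a warning).
#'
#' @param lambda eigenvalues of the correlation matrix (length N), or an
#'   [eigen_transform()] result.
#' @param h2 heritability in (0, 1) at which to evaluate.
#' @param N sample size; defaults to `length(lambda)`.
#' @return the asymptotic sampling variance of the heritability MLE.
#' @examples
#' lam <- c(rep(7.5, 100), rep(0.5, 1300))  # 100 sibships of 14
#' sqrt(asv_correct(lam, h2 = 0.5))
#' @export
asv_correct <- function(lambda, h2, N = NULL) {
  if (inherits(lambda, "eigen_structure")) lambda <- lambda$lambda
  stopifnot(h2 > 0, h2 < 1)
  N <- N %||% length(lambda)
  w <- (lambda - 1) / (h2 * lambda + 1 - h2)
  denom <- sum(w^2) - sum(w)^2 / N
  if (denom <= .Machine$double.eps * N) {
    warning("all eigenvalues equal 1: heritability unidentifiable, ASV infinite")
    return(Inf)
  }
  2 / denom
}

#' Per-eigenvalue influence on the sampling variance
#'
#' The summand `(lambda - 1)^2 / (h2 lambda + 1 - h2)^2` of the dominant term
#' of the ASV denominator. It is zero at lambda = 1 and grows for extreme
#' eigenvalues, which is why correlation matrices with more eigenvalue spread
#' (e.g. realized kinship on short genome segments) yield smaller sampling
#' variance.
#'
#' @inheritParams asv_correct
#' @return numeric vector of summand values.
#' @export
asv_summand <- function(lambda, h2) {
  (lambda - 1)^2 / (h2 * lambda + 1 - h2)^2
}

#' Mis-specification problem: true vs fitted correlation matrices
#'
#' Packages everything the mis-specification asymptotics need: the per-block
#' eigenstructure of the fitted matrix Gf, and the true covariance of the
#' transformed trait, C = T' Sigma_t T per block with
#' Sigma_t = sigma0^2 [h0^2 Gt + (1 - h0^2) I]. Its diagonal
#' a_i = (h0^2 lambda_i + 1 - h0^2) sigma0^2 + h0^2 sigma0^2 t_i' Delta t_i
#' (Delta = Gt - Gf) carries the true variance of each transformed channel.
#'
#' @param Gt,Gf true and fitted [kinship_matrix] objects over the same
#'   individuals with the same block partition.
#' @param h2_0 true heritability.
#' @param sigma2_0 true total variance.
#' @return an object of class `misspec_problem`: `lambda`, `a` (length-N
#'   vectors), `C` (list of per-block transformed true covariances),
#'   `theta0`, `N`.
#' @export
misspec_problem <- function(Gt, Gf, h2_0, sigma2_0 = 1) {
  stopifnot(inherits(Gt, "kinship_matrix"), inherits(Gf, "kinship_matrix"))
  if (!identical(dim(Gt$matrix), dim(Gf$matrix)) ||
      !identical(Gt$blocks, Gf$blocks))
    stop("Gt and Gf must share dimension and block partition")
  stopifnot(h2_0 >= 0, h2_0 <= 1, sigma2_0 > 0)
  bix <- block_indices(Gf)
  lam <- vector("list", length(bix))
  Cs <- vector("list", length(bix))
  for (b in seq_along(bix)) {
    ix <- bix[[b]]
    e <- psd_eigen(Gf$matrix[ix, ix, drop = FALSE], indefinite_ok = TRUE)
    St <- sigma2_0 * (h2_0 * Gt$matrix[ix, ix, drop = FALSE] +
                      diag(1 - h2_0, length(ix)))
    Cs[[b]] <- crossprod(e$vectors, St %*% e$vectors)
    lam[[b]] <- e$values
  }
  a <- unlist(lapply(Cs, diag), use.names = FALSE)
  if (any(a <= 0)) stop("true transformed covariance is not positive definite")
  structure(list(lambda = unlist(lam, use.names = FALSE), a = a, C = Cs,
                 theta0 = c(h2 = h2_0, sigma2 = sigma2_0),
                 N = nrow(Gf$matrix)),
            class = "misspec_problem")
}

#' @export
print.misspec_problem <- function(x, ...) {
  cat("<misspec_problem> N =", x$N, "| blocks =", length(x$C),
      "| theta0 = (", x$theta0[1L], ",", x$theta0[2L], ")\n")
  invisible(x)
}

#' Pseudo-true parameters under a mis-specified correlation matrix
#'
#' The probability limit of the MLE when the model is fitted with Gf while
#' the trait was generated under Gt: the minimizer of the Kullback-Leibler
#' objective
#' `(1/2) log(sigma2) + (1/2N) sum_i [ log(v_i) + a_i / (v_i sigma2) ]`
#' over (h2, sigma2), with v_i = h2 lambda_i + 1 - h2. sigma2 is profiled in
#' closed form, sigma2(h2) = (1/N) sum a_i / v_i, and h2 found by bounded
#' scalar search on [0, 1]. Under Gt = Gf the minimizer is the true theta0.
#'
#' @param prob a [misspec_problem()].
#' @param tol parameter tolerance of the scalar search.
#' @return an object of class `pseudo_true`: `h2`, `sigma2`, `objective`,
#'   `boundary`.
#' @export
pseudo_true <- function(prob, tol = 1e-9) {
  stopifnot(inherits(prob, "misspec_problem"))
  lam <- prob$lambda
  a <- prob$a
  negobj <- function(h2) {
    v <- h2 * lam + 1 - h2
    -0.5 * log(mean(a / v)) - 0.5 * mean(log(v))
  }
  best <- maximize_h2(negobj, tol = tol, hmax = h2_upper(lam))
  h1 <- best[1L]
  v <- h1 * lam + 1 - h1
  structure(list(h2 = h1, sigma2 = mean(a / v), objective = -best[2L],
                 boundary = (h1 < 1e-8 || h1 > 1 - 1e-8)),
            class = "pseudo_true")
}

#' @export
print.pseudo_true <- function(x, ...) {
  cat("<pseudo_true> h2 =", format(x$h2, digits = 6),
      "| sigma2 =", format(x$sigma2, digits = 6),
      if (x$boundary) "| boundary" else "", "\n")
  invisible(x)
}

#' Sandwich asymptotic covariance of the MLEs under mis-specification
#'
#' Computes the 2 x 2 matrices J (expected Hessian of the per-observation
#' log-likelihood at the pseudo-true parameters, under the true distribution)
#' and K (covariance of the per-observation score), and the asymptotic
#' covariance `Acov = J^-1 K (J^-1)' / N` of (h2-hat, sigma2-hat). Both are
#' obtained in closed form from Gaussian quadratic-form moment identities
#' (`E[y' A y] = tr(A C)`, `Cov(y' A y, y' B y) = 2 tr(A C B C)`) applied to
#' the score and Hessian of the eigen-scale log-likelihood, block by block.
#' Under correct specification K = -J and the h2 entry of Acov reduces to the
#' closed-form [asv_correct()].
#'
#' @param prob a [misspec_problem()].
#' @param theta1 optional [pseudo_true()] result (computed if missing).
#' @return an object of class `asymptotic_result`: `theta1`, `J`, `K`,
#'   `acov`, `ase_h2`, `N`.
#' @export
sandwich_acov <- function(prob, theta1 = NULL) {
  stopifnot(inherits(prob, "misspec_problem"))
  pt <- theta1 %||% pseudo_true(prob)
  h1 <- pt$h2; s1 <- pt$sigma2
  if (pt$boundary)
    warning("pseudo-true parameters on the boundary; sandwich asymptotics assume an interior optimum")
  lam <- prob$lambda; a <- prob$a; N <- prob$N
  v <- h1 * lam + 1 - h1
  d <- lam - 1
  # J: expected Hessian / N (first entry is the closed-form printed expression)
  J11 <- mean(d^2 / v^2 - 2 * d^2 * a / (s1 * v^3)) / 2
  J12 <- -sum(a * d / v^2) / (2 * s1^2 * N)
  J22 <- 1 / (2 * s1^2) - sum(a / v) / (s1^3 * N)
  J <- matrix(c(J11, J12, J12, J22), 2L, 2L,
              dimnames = list(c("h2", "sigma2"), c("h2", "sigma2")))
  # K: Var(total score) / N via per-block quadratic-form covariances
  K11 <- K12 <- K22 <- 0
  pos <- 0L
  for (Cb in prob$C) {
    nb <- nrow(Cb)
    ib <- pos + seq_len(nb)
    A <- d[ib] / v[ib]^2
    B <- 1 / v[ib]
    C2 <- Cb * Cb
    K11 <- K11 + as.numeric(crossprod(A, C2 %*% A))
    K12 <- K12 + as.numeric(crossprod(A, C2 %*% B))
    K22 <- K22 + as.numeric(crossprod(B, C2 %*% B))
    pos <- pos + nb
  }
  K <- matrix(c(K11 / (2 * s1^2), K12 / (2 * s1^3),
                K12 / (2 * s1^3), K22 / (2 * s1^4)) / N, 2L, 2L,
              dimnames = dimnames(J))
  if (kappa(J) > 1e10)
    warning("J is ill-conditioned (condition number > 1e10)")
  Jinv <- solve(J)
  acov <- Jinv %*% K %*% t(Jinv) / N
  structure(list(theta1 = c(h2 = h1, sigma2 = s1), J = J, K = K,
                 acov = acov, ase_h2 = sqrt(acov[1L, 1L]), N = N),
            class = "asymptotic_result")
}

#' @export
print.asymptotic_result <- function(x, ...) {
  cat("<asymptotic_result> theta1 = (", format(x$theta1[1L], digits = 6),
      ",", format(x$theta1[2L], digits = 6),
      ") | ASE(h2) =", format(x$ase_h2, digits = 6), "| N =", x$N, "\n")
  invisible(x)
}

#' Consistency of the pedigree-kinship fit under realized-kinship truth
#'
#' When the fitted matrix is the pedigree expectation 2 Psi and the truth is
#' realized kinship, the difference matrices Delta_b = Gt_b - 2 Psi have mean
#' zero over descent, and the mis-specification enters the asymptotics only
#' through the quadratic forms t_j' (sum_b Delta_b / m) t_j, which vanish as
#' the number of pedigrees m grows. This routine tracks that convergence:
#' for growing prefixes of a list of realized-kinship draws it reports the
#' largest |t_j' Delta-bar t_j| and the pseudo-true heritability from fitting
#' 2 Psi.
#'
#' @param Gt_list list of single-pedigree realized [kinship_matrix] draws
#'   sharing one pedigree structure.
#' @param ped the common `pedigree`.
#' @param h2_0,sigma2_0 true parameter values.
#' @param m_grid prefix sizes at which to evaluate (default: powers of 2 up
#'   to `length(Gt_list)`).
#' @return a data frame with columns `m`, `max_abs_q` and `h2_pseudo_true`.
#' @export
consistency_check_pedigree_fit <- function(Gt_list, ped, h2_0,
                                           sigma2_0 = 1, m_grid = NULL) {
  psi2 <- pedigree_kinship(ped)
  nb <- nrow(psi2$matrix)
  if (!all(vapply(Gt_list, function(g) nrow(g$matrix) == nb, logical(1))))
    stop("realized draws do not match the pedigree structure")
  e <- psd_eigen(psi2$matrix)
  m_grid <- m_grid %||% unique(pmin(2^(0:20), length(Gt_list)))
  m_grid <- sort(unique(m_grid[m_grid <= length(Gt_list)]))
  out <- lapply(m_grid, function(m) {
    Dbar <- Reduce(`+`, lapply(Gt_list[seq_len(m)],
                               function(g) g$matrix - psi2$matrix)) / m
    q <- diag(crossprod(e$vectors, Dbar %*% e$vectors))
    Gt <- bind_kinship(Gt_list[seq_len(m)])
    prob <- misspec_problem(Gt, rep_kinship(psi2, m), h2_0, sigma2_0)
    data.frame(m = m, max_abs_q = max(abs(q)),
               h2_pseudo_true = pseudo_true(prob)$h2)
  })
  do.call(rbind, out)
}

#' Concatenate single-pedigree kinship matrices into one block-diagonal sample
#' @param km_list list of `kinship_matrix` objects (one block each).
#' @export
bind_kinship <- function(km_list) {
  sizes <- vapply(km_list, function(k) nrow(k$matrix), integer(1))
  N <- sum(sizes)
  big <- matrix(0, N, N)
  ids <- character(N)
  pos <- 0L
  for (b in seq_along(km_list)) {
    ix <- pos + seq_len(sizes[b])
    big[ix, ix] <- km_list[[b]]$matrix
    ids[ix] <- paste0("P", b, "_", km_list[[b]]$ids)
    pos <- pos + sizes[b]
  }
  new_kinship_matrix(big, ids, km_list[[1L]]$kind,
                     rep(seq_along(km_list), sizes))
}
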
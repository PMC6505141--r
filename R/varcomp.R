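#' Two-component trait model
#'
#' The polygenic model y = g + e with g ~ N(0, sigma_g^2 G) and
#' e ~ N(0, sigma_e^2 I), parameterized as theta = (h2, sigma2) so that
#' y ~ N(0, sigma2 [h2 G + (1 - h2) I]), where h2 = sigma_g^2 / sigma2 is the
#' heritability and sigma2 = sigma_g^2 + sigma_e^2 the total phenotypic
#' variance.
#'
#' @param h2 heritability in [0, 1].
#' @param sigma2 total phenotypic variance (> 0).
#' @return an object of class `trait_model` with fields `h2`, `sigma2` and the
#'   derived `sigma_g2`, `sigma_e2`.
#' @export
trait_model <- function(h2, sigma2 = 1) {
  stopifnot(h2 >= 0, h2 <= 1, sigma2 > 0)
  structure(list(h2 = h2, sigma2 = sigma2,
                 sigma_g2 = h2 * sigma2, sigma_e2 = (1 - h2) * sigma2),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> h2 =", x$h2, "| sigma2 =", x$sigma2, "\n")
  invisible(x)
}

# Eigendecomposition of a block with clipping of small negative eigenvalues
# (relative tolerance 1e-10 against the largest). With indefinite_ok = FALSE
# (trait covariance side) larger negatives are an error; with TRUE (fitting
# side, e.g. a diagonal-constrained GRM) they are retained and the h2 search
# domain is restricted so all variance channels stay positive.
psd_eigen <- function(mat, tol = 1e-10, indefinite_ok = FALSE) {
  e <- eigen(mat, symmetric = TRUE)
  lo <- -tol * max(abs(e$values), 1)
  big_neg <- e$values < lo
  if (any(big_neg) && !indefinite_ok)
    stop("matrix is not positive semi-definite beyond tolerance")
  e$values[!big_neg & e$values < 0] <- 0
  e
}

# Largest h2 keeping every variance channel h2*(lambda-1) + 1 positive.
h2_upper <- function(lambda, eps = 1e-12) {
  lmin <- min(lambda)
  if (lmin >= 0) 1 - eps else min(1 - eps, (1 - 1e-9) / (1 - lmin))
}

#' Simulate trait vectors under the polygenic model
#'
#' Draws y ~ N(0, sigma2 [h2 Gt + (1 - h2) I]) block by block from the
#' eigendecomposition of each pedigree block of the true correlation matrix.
#'
#' @param Gt the true genetic correlation [kinship_matrix].
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @return numeric trait vector named by individual ids.
#' @export
simulate_trait <- function(Gt, model, seed) {
  stopifnot(inherits(Gt, "kinship_matrix"), inherits(model, "trait_model"))
  if (!missing(seed)) set.seed(as.integer(seed))
  y <- numeric(nrow(Gt$matrix))
  for (ix in block_indices(Gt)) {
    e <- psd_eigen(Gt$matrix[ix, ix, drop = FALSE])
    sdv <- sqrt(model$sigma2 * pmax(model$h2 * e$values + 1 - model$h2, 0))
    y[ix] <- e$vectors %*% (sdv * rnorm(length(ix)))
  }
  setNames(y, Gt$ids)
}

#' Per-pedigree eigen-transformation of the fitted correlation matrix
#'
#' Writes each block of Gf as T D T' and rotates the trait to y* = T' y, so
#' that under the fitted model Var(y*) = sigma2 diag(h2 lambda_i + 1 - h2).
#' The rotation is orthogonal per block, hence norm-preserving, and the
#' likelihood of the two-component model becomes a sum over independent
#' scalar channels.
#'
#' @param Gf the fitted genetic correlation [kinship_matrix].
#' @param y optional trait vector to transform.
#' @return an object of class `eigen_structure`: `values` (list per block),
#'   `vectors` (list per block), `lambda` (concatenated eigenvalues, length
#'   N), `blocks`, and `ystar` when `y` was supplied.
#' @export
eigen_transform <- function(Gf, y = NULL) {
  stopifnot(inherits(Gf, "kinship_matrix"))
  bix <- block_indices(Gf)
  es <- lapply(bix, function(ix) psd_eigen(Gf$matrix[ix, ix, drop = FALSE],
                                           indefinite_ok = TRUE))
  out <- structure(list(values = lapply(es, `[[`, "values"),
                        vectors = lapply(es, `[[`, "vectors"),
                        lambda = unlist(lapply(es, `[[`, "values"),
                                        use.names = FALSE),
                        block_index = bix,
                        blocks = Gf$blocks),
                   class = "eigen_structure")
  if (!is.null(y)) {
    if (length(y) != nrow(Gf$matrix)) stop("dimension mismatch")
    out$ystar <- unlist(lapply(seq_along(bix), function(b) {
      crossprod(es[[b]]$vectors, y[bix[[b]]])[, 1L]
    }), use.names = FALSE)
  }
  out
}

#' Log-likelihood of the two-component model on the eigen scale
#'
#' The log-likelihood without the additive constant,
#' `-(1/2) [N log(sigma2) + sum_i log(v_i) + sum_i ystar_i^2 / (v_i sigma2)]`
#' with variance channels v_i = h2 lambda_i + 1 - h2. Equals the dense
#' multivariate normal log-density of y under sigma2 [h2 Gf + (1-h2) I] up to
#' the dropped `-(N/2) log(2 pi)` term.
#'
#' @param h2,sigma2 parameter values.
#' @param eig an [eigen_transform()] result carrying `lambda`.
#' @param ystar transformed trait (defaults to `eig$ystar`).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(h2, sigma2, eig, ystar = eig$ystar) {
  v <- h2 * eig$lambda + 1 - h2
  if (any(v <= 0)) stop("nonpositive variance channel h2*lambda + 1 - h2")
  N <- length(eig$lambda)
  -0.5 * (N * log(sigma2) + sum(log(v)) + sum(ystar^2 / v) / sigma2)
}

# Brent/golden-section maximization of a scalar function of h2 on [0, hmax],
# multi-start over overlapping subintervals with the best kept, plus explicit
# endpoint comparison. Returns c(h2, value).
maximize_h2 <- function(f, tol = 1e-9, hmax = 1 - 1e-12) {
  iv <- list(c(0, 0.4), c(0.3, 0.7), c(0.6, 1), c(0, 1))
  best <- c(0, f(0))
  for (r in iv) {
    r <- pmin(r, hmax)
    if (r[2L] - r[1L] < tol) next
    o <- optimize(f, interval = r, maximum = TRUE, tol = tol)
    if (o$objective > best[2L]) best <- c(o$maximum, o$objective)
  }
  fend <- f(hmax)
  if (fend > best[2L]) best <- c(hmax, fend)
  if (f(0) >= best[2L]) best <- c(0, f(0))
  best
}

#' Maximum likelihood fit of the two-component model
#'
#' Profiles sigma2 in closed form, sigma2(h2) = (1/N) sum ystar_i^2 / v_i,
#' and maximizes the profile log-likelihood over h2 in [0, 1] by bounded
#' scalar (Brent) search with multiple starting intervals. Solutions on the
#' boundary of [0, 1] are flagged; if all eigenvalues of Gf are equal the
#' likelihood does not depend on h2 and the fit is flagged unidentifiable.
#'
#' @param y trait vector (fixed effects assumed already adjusted for).
#' @param Gf the fitted genetic correlation [kinship_matrix].
#' @param tol parameter tolerance of the scalar search.
#' @return an object of class `fit_result`: `h2`, `sigma2`, `loglik`,
#'   `boundary`, `identifiable`, `n`.
#' @export
fit_mle <- function(y, Gf, tol = 1e-9) {
  stopifnot(inherits(Gf, "kinship_matrix"))
  N <- length(y)
  if (N < 2L) stop("need at least two observations")
  if (var(y) == 0) stop("degenerate input: constant trait vector")
  eig <- eigen_transform(Gf, y)
  lam <- eig$lambda
  ys2 <- eig$ystar^2
  if (max(lam) - min(lam) < 1e-12) {
    return(structure(list(h2 = NA_real_, sigma2 = mean(ys2),
                          loglik = -0.5 * N * (log(mean(ys2)) + 1),
                          boundary = TRUE, identifiable = FALSE, n = N),
                     class = "fit_result"))
  }
  prof <- function(h2) {
    v <- h2 * lam + 1 - h2
    s2 <- mean(ys2 / v)
    -0.5 * (N * log(s2) + sum(log(v)) + N)
  }
  best <- maximize_h2(prof, tol = tol, hmax = h2_upper(lam))
  h2 <- best[1L]
  v <- h2 * lam + 1 - h2
  structure(list(h2 = h2, sigma2 = mean(ys2 / v), loglik = best[2L],
                 boundary = (h2 < 1e-8 || h2 > 1 - 1e-8),
                 identifiable = TRUE, n = N),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> h2 =", format(x$h2, digits = 6),
      "| sigma2 =", format(x$sigma2, digits = 6),
      "| logLik =", format(x$loglik, digits = 8),
      if (x$boundary) "| boundary" else "",
      if (!x$identifiable) "| unidentifiable" else "", "\n")
  invisible(x)
}

#' Read and write trait vectors
#'
#' One observation per line; either a single numeric column or two
#' whitespace-separated columns `id value`.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_trait <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) return(as.numeric(tab[[1L]]))
  setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

#' @rdname read_trait
#' @param y named or unnamed numeric trait vector.
#' @export
write_trait <- function(y, path) {
  tab <- if (is.null(names(y))) data.frame(value = y)
         else data.frame(id = names(y), value = as.numeric(y))
  write.table(tab, path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
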
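## Weighted-L1 penalized logistic regression by IRLS + coordinate descent.
## Minimizes  -loglik(alpha) + sum_j penalty_j * |alpha_j|
## where loglik is the Bernoulli log-likelihood of expit(X alpha) (no global
## intercept; any intercept structure lives in X) and penalty_j = 0 marks an
## unpenalized column. This is the glmnet-style scheme: outer quadratic
## approximation, inner cyclic coordinate descent with soft-thresholding.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

penlogit_cd <- function(X, y, penalty, start = NULL, tol = 1e-9,
                        maxit = 10000L, wmin = 1e-6) {
  p <- ncol(X)
  stopifnot(length(penalty) == p, all(penalty >= 0))
  a <- start %||% numeric(p)
  eta <- drop(X %*% a)
  xtx <- rep(NA_real_, p)
  converged <- FALSE
  for (outer in seq_len(maxit)) {
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), wmin)
    z <- eta + (y - mu) / w
    wX <- X * w
    dens <- colSums(wX * X)
    r <- z - eta                      # working residual, kept in sync
    a_outer <- a
    for (inner in seq_len(maxit)) {
      maxd <- 0
      for (j in seq_len(p)) {
        den <- dens[j]
        if (den < 1e-12) next
        num <- sum(wX[, j] * r) + den * a[j]
        new <- if (penalty[j] > 0) soft_threshold(num, penalty[j]) / den else num / den
        d <- new - a[j]
        if (d != 0) {
          r <- r - X[, j] * d
          a[j] <- new
          maxd <- max(maxd, abs(d))
        }
      }
      if (maxd < tol) break
    }
    eta <- drop(X %*% a)
    if (max(abs(a - a_outer)) < tol && outer > 1L) { converged <- TRUE; break }
    if (max(abs(a)) > 100)
      warning("very large coefficients: possible separation on unpenalized columns")
  }
  list(alpha = a, converged = converged,
       kkt = kkt_residual(X, y, a, penalty))
}

#' Karush-Kuhn-Tucker residual of a penalized logistic solution
#'
#' Returns the maximum violation of the subgradient optimality conditions of
#' the weighted-L1 penalized Bernoulli log-likelihood, scaled per observation
#' (divided by the number of pooled rows). At an exact solution the residual
#' is zero; solver output is accepted at \code{1e-6}.
#'
#' @param X design matrix, \code{y} 0/1 response, \code{alpha} coefficients,
#'   \code{penalty} per-column absolute-penalty levels (0 = unpenalized).
#' @return Nonnegative scalar.
#' @export
kkt_residual <- function(X, y, alpha, penalty) {
  mu <- expit(drop(X %*% alpha))
  grad <- drop(crossprod(X, mu - y))     # gradient of -loglik
  res <- numeric(length(alpha))
  for (j in seq_along(alpha)) {
    if (penalty[j] == 0) {
      res[j] <- abs(grad[j])
    } else if (alpha[j] != 0) {
      res[j] <- abs(grad[j] + penalty[j] * sign(alpha[j]))
    } else {
      res[j] <- max(0, abs(grad[j]) - penalty[j])
    }
  }
  max(res) / nrow(X)
}

## Bernoulli log-likelihood of the pooled logistic model.
penlogit_loglik <- function(X, y, alpha) {
  eta <- drop(X %*% alpha)
  sum(y * eta - log1p(exp(eta)))
}

## Unpenalized MLE restricted to columns `free` (others fixed at zero).
## Uses glm.fit on the submatrix.
restricted_mle <- function(X, y, free) {
  a <- numeric(ncol(X))
  if (any(free)) {
    fit <- suppressWarnings(
      stats::glm.fit(X[, free, drop = FALSE], y, family = stats::binomial())
    )
    a[free] <- fit$coefficients
    a[is.na(a)] <- 0
  }
  a
}

## Smallest lambda shrinking every penalized coefficient to zero, from the
## KKT bound at the null model (unpenalized columns at their MLE).
lambda_max_null <- function(X, y, omega, shrink) {
  a0 <- restricted_mle(X, y, !shrink)
  mu <- expit(drop(X %*% a0))
  grad <- abs(drop(crossprod(X[, shrink, drop = FALSE], y - mu)))
  max(grad / omega[shrink]) * 1.000001
}

#' Fit the outcome-adaptive LASSO coefficient path
#'
#' Solves the weighted-L1 penalized pooled logistic model over a descending
#' lambda grid with warm starts. The penalty applies only to the shrinkable
#' (covariate) columns of the pooled design, with per-coefficient adaptive
#' weights; per-time intercepts and past-treatment slots are never penalized.
#'
#' @param design a [build_pooled_design] object.
#' @param omega full-length adaptive weight vector (as from
#'   [adaptive_weights]); entries for unpenalized columns are ignored.
#' @param lambda descending grid; if \code{NULL}, \code{nlambda} log-spaced
#'   values from the smallest all-zero lambda down to
#'   \code{lambda_min_ratio} times it.
#' @param nlambda,lambda_min_ratio grid controls.
#' @param tol,maxit solver controls (coefficient max-change tolerance).
#' @return List of class \code{"loal_path"}: \code{lambda}, coefficient matrix
#'   \code{alpha} (columns = grid points), per-lambda \code{kkt} residuals and
#'   \code{loglik}.
#' @export
fit_loal_path <- function(design, omega, lambda = NULL, nlambda = 30L,
                          lambda_min_ratio = 1e-4, tol = 1e-9, maxit = 10000L) {
  stopifnot(inherits(design, "pooled_design"))
  X <- design$X; y <- design$y
  shrink <- design$shrink
  if (is.null(lambda)) {
    lmax <- lambda_max_null(X, y, omega, shrink)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  if (is.unsorted(rev(lambda))) stop("lambda grid must be descending")
  p <- ncol(X)
  alpha <- matrix(0, p, length(lambda), dimnames = list(colnames(X), NULL))
  kkt <- loglik <- numeric(length(lambda))
  start <- restricted_mle(X, y, !shrink)
  for (l in seq_along(lambda)) {
    pen <- ifelse(shrink, lambda[l] * omega, 0)
    fit <- penlogit_cd(X, y, pen, start = start, tol = tol, maxit = maxit)
    if (!fit$converged)
      stop("penalized logistic solver did not converge at lambda index ", l)
    alpha[, l] <- start <- fit$alpha
    kkt[l] <- fit$kkt
    loglik[l] <- penlogit_loglik(X, y, fit$alpha)
  }
  structure(list(lambda = lambda, alpha = alpha, kkt = kkt, loglik = loglik,
                 omega = omega, design = design),
            class = "loal_path")
}
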
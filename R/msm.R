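#' Number of treated time points in a pattern
#'
#' @param a 0/1 treatment vector or matrix (rows = patterns).
#' @return Integer count(s).
#' @export
cum_treat <- function(a) {
  if (is.matrix(a)) {
    stopifnot(all(a %in% c(0, 1)))
    rowSums(a)
  } else {
    stopifnot(all(a %in% c(0, 1)))
    sum(a)
  }
}

## Per-(subject, time) treatment probabilities implied by a fit. Accepts a
## loal / fused_loal fit (pooled model evaluated on the observed design), or
## a plain n x (T+1) probability matrix.
propensity_matrix <- function(data, fit) {
  if (is.matrix(fit)) {
    stopifnot(nrow(fit) == data$n, ncol(fit) == data$Tt + 1L)
    return(fit)
  }
  stopifnot(inherits(fit, "loal"))
  alpha <- if (inherits(fit, "fused_loal")) fit$alpha_star else fit$refit
  design <- fit$design
  m <- expit(drop(design$X %*% alpha))
  P <- matrix(NA_real_, data$n, data$Tt + 1L)
  for (r in seq_len(nrow(design$row_map)))
    P[design$row_map$subject[r], design$row_map$tau[r] + 1L] <- m[r]
  P
}

#' Cumulative stabilized inverse-probability-of-treatment weights
#'
#' \code{w_i = prod_t g_t(a_ti | L01_i) / g_t(a_ti | history_i)}: the
#' denominator comes from the fitted (pooled, selected, or fused) treatment
#' model, the stabilizing numerator from a per-time logistic regression of
#' \code{A_t} on the MSM baseline covariate \code{L01} (set
#' \code{numerator = "marginal"} for per-time frequencies, or
#' \code{"none"} for unstabilized weights). A fitted censoring model
#' multiplies the weight by inverse probabilities of remaining uncensored,
#' with marginal uncensored probabilities as numerator.
#'
#' @param data a [longdata] object.
#' @param fit a [loal]/[fuse] fit for the treatment process, or an
#'   \code{n x (T+1)} matrix of probabilities \code{P(A_t = 1 | history)}.
#' @param L01 baseline covariate name for the stabilizing numerator (default:
#'   first column of \code{L0}).
#' @param numerator \code{"L01"}, \code{"marginal"} or \code{"none"}.
#' @param censoring optional [loal] fit for the censoring process or
#'   probability matrix for \code{P(C_t = 1 | history)}.
#' @param eps positivity guard: any denominator below \code{eps} errors.
#' @return Object of class \code{"weight_set"}: \code{w} (length n; NA for
#'   censored subjects), per-time \code{numerator}/\code{denominator}
#'   matrices, and \code{diagnostics} (min, max, mean, effective sample
#'   size).
#' @export
compute_weights <- function(data, fit, L01 = NULL, numerator = c("L01", "marginal", "none"),
                            censoring = NULL, eps = 1e-12) {
  stopifnot(inherits(data, "longdata"))
  numerator <- match.arg(numerator)
  if (is.null(L01)) L01 <- colnames(data$L[[1L]])[1L]
  P <- propensity_matrix(data, fit)
  Tt <- data$Tt
  n <- data$n
  x01 <- data$L[[1L]][, L01]
  num <- den <- matrix(1, n, Tt + 1L)
  uncens <- if (is.null(data$C)) matrix(TRUE, n, Tt + 1L) else data$C == 0
  for (t in 0:Tt) {
    at <- data$A[, t + 1L]
    obs <- uncens[, t + 1L]
    g <- P[, t + 1L]
    if (any(obs & (is.na(g) | pmin(ifelse(at == 1, g, 1 - g), 1) < eps))) {
      bad <- which(obs & (is.na(g) | ifelse(at == 1, g, 1 - g) < eps))
      stop("positivity violation at time ", t, " for subject(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
    }
    den[obs, t + 1L] <- ifelse(at == 1, g, 1 - g)[obs]
    nm <- switch(numerator,
      none = rep(1, n),
      marginal = { p <- mean(at[obs]); ifelse(at == 1, p, 1 - p) },
      L01 = {
        nf <- suppressWarnings(
          stats::glm.fit(cbind(1, x01[obs]), at[obs], family = stats::binomial())
        )
        p <- expit(drop(cbind(1, x01) %*% nf$coefficients))
        ifelse(at == 1, p, 1 - p)
      })
    num[obs, t + 1L] <- nm[obs]
  }
  w <- apply(num / den, 1, prod)
  if (!is.null(censoring)) {
    Pc <- propensity_matrix(data, censoring)
    for (t in 0:Tt) {
      obs <- uncens[, t + 1L]
      gkeep <- 1 - Pc[, t + 1L]
      if (any(obs & !is.na(gkeep) & gkeep < eps))
        stop("positivity violation in censoring model at time ", t)
      pbar <- mean(obs)
      fac <- ifelse(obs & !is.na(gkeep), pbar / gkeep, 1)
      w <- w * fac
    }
  }
  complete <- uncens[, Tt + 1L]
  w[!complete] <- NA_real_
  ww <- w[complete]
  structure(
    list(w = w, numerator = num, denominator = den, L01 = L01,
         complete = complete,
         diagnostics = c(min = min(ww), max = max(ww), mean = mean(ww),
                         ess = sum(ww)^2 / sum(ww^2))),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Stabilized IPT weights: n =", length(x$w), "\n")
  print(round(x$diagnostics, 4))
  invisible(x)
}

msm_regressors <- function(data, L01, interaction) {
  x01 <- data$L[[1L]][, L01]
  cm <- cum_treat(data$A)
  X <- cbind(`(Intercept)` = 1, L01 = x01, cum = cm)
  if (interaction) X <- cbind(X, `L01:cum` = x01 * cm)
  X
}

#' IPTW estimation of marginal structural model parameters
#'
#' Weighted least squares of the observed outcome on the MSM regressors
#' \code{(1, L01, cum(abar))} — optionally plus the \code{L01 x cum}
#' interaction — using cumulative stabilized weights, with robust sandwich
#' standard errors. Censored subjects are excluded from the regression (their
#' censoring contribution lives in the weights).
#'
#' @param data a [longdata] object.
#' @param weights a [compute_weights] object (or bare numeric vector).
#' @param L01 baseline MSM covariate name (default: first column of L0, or
#'   the weight set's choice).
#' @param interaction include \code{L01 x cum}?
#' @return Object of class \code{"msm_fit"} with \code{coefficients},
#'   \code{se} (sandwich), \code{vcov}, \code{estimator = "iptw"} and weight
#'   diagnostics.
#' @export
msm_iptw <- function(data, weights, L01 = NULL, interaction = FALSE) {
  stopifnot(inherits(data, "longdata"))
  if (inherits(weights, "weight_set")) {
    L01 <- L01 %||% weights$L01
    w <- weights$w
    diag_ <- weights$diagnostics
  } else {
    w <- as.numeric(weights)
    diag_ <- NULL
  }
  if (is.null(L01)) L01 <- colnames(data$L[[1L]])[1L]
  X <- msm_regressors(data, L01, interaction)
  keep <- !is.na(w)
  df <- data.frame(y = data$Y[keep], l01 = X[keep, "L01"], cum = X[keep, "cum"],
                   w = w[keep])
  fml <- if (interaction) y ~ l01 + cum + l01:cum else y ~ l01 + cum
  fit <- stats::lm(fml, data = df, weights = w)
  if (any(is.na(stats::coef(fit)))) stop("collinear MSM design")
  V <- sandwich::vcovHC(fit, type = "HC0")
  co <- stats::coef(fit)
  names(co) <- rownames(V) <- colnames(V) <- colnames(X)
  structure(
    list(coefficients = co, vcov = V, se = sqrt(diag(V)),
         estimator = "iptw", n = sum(keep), L01 = L01,
         weight_diagnostics = diag_),
    class = "msm_fit"
  )
}

#' Sequential g-computation estimation of MSM parameters
#'
#' Stacks the time-zero counterfactual predictions \code{q_0^a} over all
#' treatment patterns and regresses them on the MSM regressors
#' \code{(1, L01, cum(a))} by least squares. Optional subject-level
#' nonparametric bootstrap (refitting the whole q recursion per resample)
#' provides standard errors.
#'
#' @param qstack a [fit_q_sequence] result.
#' @param data the matching [longdata].
#' @param L01 baseline MSM covariate name.
#' @param interaction include \code{L01 x cum}?
#' @param se \code{"none"} (default) or \code{"bootstrap"}.
#' @param B bootstrap replications.
#' @param seed seed for the bootstrap resampling.
#' @return An object of class \code{"msm_fit"} with
#'   \code{estimator = "gcomp"}.
#' @export
msm_gcomp <- function(qstack, data, L01 = NULL, interaction = FALSE,
                      se = c("none", "bootstrap"), B = 200L, seed = 1L) {
  stopifnot(inherits(qstack, "qstack"), inherits(data, "longdata"))
  se <- match.arg(se)
  if (is.null(L01)) L01 <- colnames(data$L[[1L]])[1L]
  point <- gcomp_point(qstack, data, L01, interaction)
  V <- matrix(NA_real_, length(point), length(point))
  if (se == "bootstrap") {
    set.seed(seed)
    bs <- replicate(B, {
      idx <- sample.int(data$n, replace = TRUE)
      db <- longdata(lapply(data$L, function(M) M[idx, , drop = FALSE]),
                     data$A[idx, , drop = FALSE], data$Y[idx],
                     C = if (!is.null(data$C)) data$C[idx, , drop = FALSE])
      qb <- fit_q_sequence(db, patterns = qstack$patterns,
                           q_terms = qstack$q_terms)
      gcomp_point(qb, db, L01, interaction)
    })
    V <- stats::cov(t(bs))
  }
  dimnames(V) <- list(names(point), names(point))
  structure(
    list(coefficients = point, vcov = V, se = sqrt(diag(V)),
         estimator = "gcomp", n = data$n, L01 = L01,
         weight_diagnostics = NULL),
    class = "msm_fit"
  )
}

gcomp_point <- function(qstack, data, L01, interaction) {
  npat <- nrow(qstack$patterns)
  x01 <- data$L[[1L]][, L01]
  q0 <- as.vector(qstack$q[[1L]])
  l01 <- rep(x01, npat)
  cm <- rep(cum_treat(qstack$patterns), each = data$n)
  X <- cbind(`(Intercept)` = 1, L01 = l01, cum = cm)
  if (interaction) X <- cbind(X, `L01:cum` = l01 * cm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear MSM design")
  stats::setNames(drop(qr.coef(qrX, q0)), colnames(X))
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("MSM parameter estimates (", x$estimator, "), n = ", x$n, "\n", sep = "")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.msm_fit <- function(object, ...) object$coefficients

#' @export
vcov.msm_fit <- function(object, ...) object$vcov

#' @export
summary.msm_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(
    estimate = object$coefficients, se = object$se, z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
  out <- list(table = tab, estimator = object$estimator, n = object$n,
              weight_diagnostics = object$weight_diagnostics)
  class(out) <- "summary.msm_fit"
  out
}

#' @export
print.summary.msm_fit <- function(x, ...) {
  cat("MSM fit (", x$estimator, "), n = ", x$n, "\n", sep = "")
  print(round(x$table, 4))
  if (!is.null(x$weight_diagnostics)) {
    cat("weights: ")
    print(round(x$weight_diagnostics, 3))
  }
  invisible(x)
}

#' @export
confint.msm_fit <- function(object, parm, level = 0.95, ...) {
  co <- object$coefficients
  if (missing(parm)) parm <- names(co)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = co[parm] - z * object$se[parm],
        upper = co[parm] + z * object$se[parm])
}

#' m-out-of-n bootstrap intervals for a pipeline estimator
#'
#' Draws \code{B} resamples of size \code{m} (with replacement) of subjects,
#' re-runs \code{pipeline} on each, and forms percentile intervals whose
#' deviations from the full-sample estimate are rescaled by
#' \code{sqrt(m/n)}. Designed for post-selection settings where the standard
#' bootstrap is invalid; note that coverage is not guaranteed.
#'
#' @param pipeline function taking a [longdata] and returning a numeric
#'   vector of estimates.
#' @param data a [longdata] object.
#' @param m resample size; \code{m >= n} warns and reduces to the standard
#'   bootstrap scaling.
#' @param B replications.
#' @param seed integer seed.
#' @param level confidence level.
#' @return List: \code{estimate} (full-sample), \code{lower}, \code{upper},
#'   \code{m}, \code{B}, and the raw bootstrap draws.
#' @export
m_out_of_n_bootstrap <- function(pipeline, data, m, B = 200L, seed = 1L,
                                 level = 0.95) {
  stopifnot(inherits(data, "longdata"))
  n <- data$n
  if (m >= n) {
    warning("m >= n: reduces to the standard bootstrap")
    m <- n
  }
  est <- pipeline(data)
  set.seed(seed)
  draws <- replicate(B, {
    idx <- sample.int(n, m, replace = TRUE)
    db <- longdata(lapply(data$L, function(M) M[idx, , drop = FALSE]),
                   data$A[idx, , drop = FALSE], data$Y[idx],
                   C = if (!is.null(data$C)) data$C[idx, , drop = FALSE])
    pipeline(db)
  })
  draws <- matrix(draws, nrow = length(est))
  alpha <- (1 - level) / 2
  qs <- apply(draws, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  scale <- sqrt(m / n)
  lower <- est + scale * (unname(qs)[1L, ] - est)
  upper <- est + scale * (unname(qs)[2L, ] - est)
  names(lower) <- names(upper) <- names(est)
  list(estimate = est, lower = lower, upper = upper,
       m = m, B = B, draws = draws)
}
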
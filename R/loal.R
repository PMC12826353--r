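#' Adaptive penalty weights from working-model coefficients
#'
#' Maps every shrinkable pooled-design column \code{(tau, t, k)} to
#' \code{omega_j = |beta_j|^(-gamma)}, where \code{beta_j} is the coefficient
#' of the same covariate in the time-\code{tau} working structural model.
#' Unpenalized columns (per-time intercepts, past-treatment slots) get weight
#' zero. An exactly-zero \code{beta} gets the documented cap \code{zero_cap}
#' (the coefficient is effectively excluded) with a warning, keeping the
#' objective finite.
#'
#' @param beta a [working_beta] object.
#' @param design a [build_pooled_design] object.
#' @param zero_cap weight assigned when \code{beta = 0} exactly.
#' @return Numeric weight vector, one entry per design column.
#' @export
adaptive_weights <- function(beta, design, zero_cap = 1e12) {
  stopifnot(inherits(beta, "working_beta"), inherits(design, "pooled_design"))
  m <- design$index_map
  omega <- numeric(nrow(m))
  for (j in which(design$shrink)) {
    bj <- beta_lookup(beta, m$tau[j], m$var[j])
    if (is.na(bj))
      stop("no working-model coefficient for design column ", m$col[j])
    if (bj == 0) {
      warning("working-model coefficient exactly zero for ", m$col[j],
              "; penalty weight capped at ", format(zero_cap))
      omega[j] <- zero_cap
    } else {
      omega[j] <- abs(bj)^(-beta$gamma)
    }
  }
  omega
}

## Cumulative stabilized weights at every (subject, tau) implied by pooled
## coefficients alpha. Numerator: marginal per-time frequency of the observed
## process level. Returns an n x (T+1) matrix (1 where a subject is not at
## risk). Errors on fitted probabilities numerically at 0/1.
cumulative_balance_weights <- function(design, alpha, eps = 1e-10) {
  m <- expit(drop(design$X %*% alpha))
  if (any(m < eps | m > 1 - eps))
    stop("fitted treatment probability numerically 0 or 1: positivity violation")
  n <- design$n; Tt <- design$Tt
  W <- matrix(1, n, Tt + 1L)
  for (tau in 0:Tt) {
    r <- which(design$row_map$tau == tau)
    subj <- design$row_map$subject[r]
    a <- design$y[r]
    phat <- mean(a)
    num <- ifelse(a == 1, phat, 1 - phat)
    den <- ifelse(a == 1, m[r], 1 - m[r])
    ratio <- rep(1, n)
    ratio[subj] <- num / den
    W[, tau + 1L] <- (if (tau == 0) 1 else W[, tau]) * ratio
  }
  W
}

#' Longitudinal weighted absolute mean difference balance score
#'
#' One-dimensional summary of covariate balance achieved by the
#' inverse-probability weights implied by pooled coefficients \code{alpha}:
#' for each treatment time \code{tau} and each shrinkable covariate column,
#' the absolute difference in stabilized-IPT-weighted covariate means between
#' the \code{A_tau = 1} and \code{A_tau = 0} groups, multiplied by the
#' magnitude of the covariate's working-model coefficient \code{|beta|}, and
#' summed over covariates and times (equal weight across times). Smaller is
#' better; zero is exact weighted balance on every penalizable covariate.
#'
#' This reconstruction of the longitudinal balance metric is isolated here so
#' it can be swapped for an alternative definition.
#'
#' @param design a [build_pooled_design] object (carries the data geometry).
#' @param alpha pooled coefficient vector defining the candidate weights.
#' @param beta a [working_beta] object supplying the \code{|beta|} weights.
#' @param data the [longdata] object.
#' @return Nonnegative scalar.
#' @export
balance_score <- function(design, alpha, beta, data) {
  W <- cumulative_balance_weights(design, alpha)
  m <- design$index_map
  score <- 0
  for (tau in 0:design$Tt) {
    r <- which(design$row_map$tau == tau)
    subj <- design$row_map$subject[r]
    a <- design$y[r]
    w <- W[subj, tau + 1L]
    t1 <- a == 1
    jblk <- which(design$shrink & m$tau == tau)
    for (j in jblk) {
      x <- data$L[[m$t[j] + 1L]][subj, m$k[j]]
      d1 <- sum(w[t1] * x[t1]) / sum(w[t1])
      d0 <- sum(w[!t1] * x[!t1]) / sum(w[!t1])
      bj <- beta_lookup(beta, m$tau[j], m$var[j])
      score <- score + abs(bj) * abs(d1 - d0)
    }
  }
  score
}

#' Select the regularization level by covariate balance and refit
#'
#' Evaluates the balance score at every lambda of a fitted path, selects the
#' minimizer (ties broken toward the largest lambda, i.e. the most
#' parsimonious model; a lambda whose weights violate positivity is treated
#' as infeasible), and refits the active model by unpenalized pooled-logistic
#' maximum likelihood on the selected columns plus the always-kept intercept
#' and treatment slots. When a second path is supplied (e.g. a censoring
#' process), the two grids are paired by index and the summed score is
#' minimized jointly.
#'
#' @param path a [fit_loal_path] object.
#' @param data the [longdata] object.
#' @param beta the [working_beta] object used for the penalty.
#' @param joint optional list \code{list(path =, beta =)} for a second
#'   process fit on the same data with an equal-length grid.
#' @return List: \code{lambda_index}, \code{lambda}, \code{balance} (per
#'   lambda; \code{Inf} where infeasible), \code{alpha} (path solution at the
#'   selection), \code{refit} (unpenalized MLE on the active set),
#'   \code{active} (index-map rows of selected shrinkable columns), and the
#'   same elements for the joint process when present.
#' @export
select_lambda_and_refit <- function(path, data, beta, joint = NULL) {
  stopifnot(inherits(path, "loal_path"))
  score_path <- function(pth, bt) {
    vapply(seq_along(pth$lambda), function(l) {
      tryCatch(balance_score(pth$design, pth$alpha[, l], bt, data),
               error = function(e) Inf)
    }, 0)
  }
  sc <- score_path(path, beta)
  total <- sc
  if (!is.null(joint)) {
    stopifnot(length(joint$path$lambda) == length(path$lambda))
    sc2 <- score_path(joint$path, joint$beta)
    total <- total + sc2
  }
  if (all(!is.finite(total)))
    stop("no feasible lambda: every candidate violated positivity; extend the grid")
  sel <- which.min(total)   # grid descending: first minimum = largest lambda
  finish <- function(pth) {
    a <- pth$alpha[, sel]
    active <- which(pth$design$shrink & a != 0)
    free <- !pth$design$shrink | seq_len(ncol(pth$design$X)) %in% active
    refit <- restricted_mle(pth$design$X, pth$design$y, free)
    names(refit) <- colnames(pth$design$X)
    list(alpha = a, refit = refit,
         active = pth$design$index_map[active, , drop = FALSE])
  }
  out <- c(list(lambda_index = sel, lambda = path$lambda[sel], balance = sc),
           finish(path))
  if (!is.null(joint))
    out$joint <- c(list(balance = sc2), finish(joint$path))
  out
}

#' Longitudinal outcome-adaptive LASSO for pooled treatment models
#'
#' The full first step of the two-step procedure: (1) estimate the nested
#' counterfactual regressions by sequential least squares ([fit_q_sequence]);
#' (2) estimate the stacked working structural-model coefficients beta
#' ([working_beta]); (3) build the pooled no-intercept treatment design
#' ([build_pooled_design]); (4) fit the adaptive-weight L1 path
#' ([fit_loal_path]) with \code{omega_j = |beta_j|^(-gamma)}; (5) select the
#' regularization level by the longitudinal covariate-balance metric and
#' refit the selected model by unpenalized maximum likelihood
#' ([select_lambda_and_refit]). The identical machinery applies to a
#' censoring process via \code{process = "censoring"}.
#'
#' @param data a [longdata] object.
#' @param process \code{"treatment"} or \code{"censoring"}.
#' @param gamma adaptive exponent (> 2 required by the selection theory;
#'   default 2.5).
#' @param nlambda,lambda_min_ratio lambda-grid controls; the largest grid
#'   value shrinks every penalizable coefficient to zero.
#' @param q_terms per-time q-model right-hand sides (see [fit_q_sequence]).
#' @param patterns optional restricted treatment-pattern matrix.
#' @param history covariate history entering each time model (\code{"full"}
#'   or a maximum lag).
#' @param absorbing is the process absorbing (monotone)?
#' @param beta optionally, a precomputed [working_beta] (skips steps 1-2).
#' @param lambda_rule \code{"balance"} (default) or \code{"n_power"}: the
#'   deterministic rule \code{lambda_n = n^aleph}.
#' @param aleph exponent for \code{lambda_rule = "n_power"}; must be < 0.5.
#' @return An object of class \code{"loal"}; see Details. Key elements:
#'   \code{refit} (selected-model coefficients), \code{active} (selected
#'   covariate columns), \code{path}, \code{balance}, \code{beta},
#'   \code{design}.
#' @export
loal <- function(data, process = "treatment", gamma = 2.5, nlambda = 30L,
                 lambda_min_ratio = 1e-4, q_terms = NULL, patterns = NULL,
                 history = "full", absorbing = FALSE, beta = NULL,
                 lambda_rule = c("balance", "n_power"), aleph = 0.25) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(beta)) {
    qs <- fit_q_sequence(data, patterns = patterns, q_terms = q_terms)
    beta <- working_beta(qs, data, gamma = gamma)
  } else {
    qs <- NULL
    stopifnot(inherits(beta, "working_beta"))
  }
  design <- build_pooled_design(data, process = process, history = history,
                                absorbing = absorbing)
  omega <- adaptive_weights(beta, design)
  if (lambda_rule == "n_power") {
    if (aleph >= 0.5) stop("aleph must be below 0.5")
    lam <- data$n^aleph
    path <- fit_loal_path(design, omega, lambda = lam)
    sel <- list(lambda_index = 1L, lambda = lam, balance = NA_real_)
    a <- path$alpha[, 1L]
    active <- which(design$shrink & a != 0)
    free <- !design$shrink | seq_len(ncol(design$X)) %in% active
    refit <- restricted_mle(design$X, design$y, free)
    names(refit) <- colnames(design$X)
    sel <- c(sel, list(alpha = a, refit = refit,
                       active = design$index_map[active, , drop = FALSE]))
  } else {
    path <- fit_loal_path(design, omega, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio)
    sel <- select_lambda_and_refit(path, data, beta)
  }
  structure(
    list(call = match.call(), process = process, gamma = gamma,
         qstack = qs, beta = beta, design = design, omega = omega,
         path = path, balance = sel$balance, lambda = sel$lambda,
         lambda_index = sel$lambda_index, alpha = sel$alpha,
         refit = sel$refit, active = sel$active, data = data),
    class = "loal"
  )
}

#' @export
print.loal <- function(x, ...) {
  cat("Longitudinal outcome-adaptive LASSO (", x$process, " process)\n", sep = "")
  cat("  gamma = ", x$gamma, "; selected lambda = ", signif(x$lambda, 4),
      " (index ", x$lambda_index, " of ", length(x$path$lambda), ")\n", sep = "")
  cat("  selected covariate columns:",
      if (nrow(x$active)) paste(x$active$col, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @export
coef.loal <- function(object, type = c("refit", "penalized"), ...) {
  type <- match.arg(type)
  if (type == "refit") object$refit else object$alpha
}

#' @export
summary.loal <- function(object, ...) {
  m <- object$design$index_map
  tab <- data.frame(
    time = m$tau, term = m$var, type = m$type,
    penalized = object$design$shrink,
    omega = object$omega,
    alpha_penalized = unname(object$alpha),
    alpha_refit = unname(object$refit),
    selected = unname(object$refit != 0 | !object$design$shrink)
  )
  out <- list(table = tab, lambda = object$lambda, balance = object$balance,
              lambda_grid = object$path$lambda, gamma = object$gamma,
              process = object$process)
  class(out) <- "summary.loal"
  out
}

#' @export
print.summary.loal <- function(x, ...) {
  cat("LOAL (", x$process, "), gamma = ", x$gamma,
      ", lambda_n = ", signif(x$lambda, 4), "\n\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.loal <- function(x, ...) {
  ok <- is.finite(x$balance)
  graphics::plot(log(x$path$lambda[ok]), x$balance[ok], type = "b",
                 xlab = "log(lambda)", ylab = "balance score",
                 main = "Longitudinal balance vs regularization", ...)
  graphics::abline(v = log(x$lambda), lty = 2)
  invisible(x)
}

#' Tidy coefficient table of a pooled-model fit
#'
#' @param fit a [loal] or [fuse] result.
#' @return Data frame (time, term, type, estimate).
#' @export
coef_table <- function(fit) {
  m <- fit$design$index_map
  est <- if (inherits(fit, "fused_loal")) fit$alpha_star else fit$refit
  data.frame(time = m$tau, term = m$var, type = m$type, estimate = unname(est))
}
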
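#' A term of a linear predictor
#'
#' Represents \code{coef * prod(vars^pow)} over variables generated earlier in
#' the causal ordering. An empty \code{vars} gives an intercept term.
#'
#' @param coef numeric coefficient.
#' @param vars character vector of variable names (covariates or \code{A<t>}).
#' @param pow integer powers, recycled to \code{length(vars)}.
#' @return A list of class \code{"lp_term"}.
#' @export
lp_term <- function(coef, vars = character(), pow = 1L) {
  vars <- as.character(vars)
  pow <- rep_len(as.integer(pow), length(vars))
  structure(list(coef = as.numeric(coef), vars = vars, pow = pow), class = "lp_term")
}

eval_terms <- function(terms, env, n) {
  out <- numeric(n)
  for (tm in terms) {
    v <- rep(tm$coef, n)
    for (i in seq_along(tm$vars)) {
      x <- env[[tm$vars[i]]]
      if (is.null(x)) stop("unknown variable in linear predictor: ", tm$vars[i])
      v <- v * x^tm$pow[i]
    }
    out <- out + v
  }
  out
}

#' Specification of a sequential data-generating process
#'
#' Describes a longitudinal DGP drawn in causal order: for each time
#' \code{t = 0, ..., T}, Gaussian covariates whose means are linear (or
#' polynomial, via [lp_term]) in previously generated variables, then a binary
#' treatment \code{A_t} assigned by a logistic model on the history; finally a
#' Gaussian outcome \code{Y}. Covariate roles (\code{"confounder"},
#' \code{"instrument"}, \code{"outcome_cause"}) tag the ground truth used by
#' oracle estimators and the simulation harness.
#'
#' @param Tt last treatment time (number of treatment times minus one).
#' @param covariates list of length \code{Tt + 1}; element \code{t + 1} is a
#'   list of covariate definitions, each a list with fields \code{name},
#'   \code{role}, \code{mean} (list of [lp_term]) and \code{sd} (> 0).
#' @param treatment list of length \code{Tt + 1}; element \code{tau + 1} is a
#'   list of [lp_term]s for the logit of \code{P(A_tau = 1 | history)}.
#' @param outcome list with fields \code{terms} (list of [lp_term]) and
#'   \code{sd} (> 0).
#' @param outcome_variant optional tag naming the outcome-mean family.
#' @param standardize logical; standardize realized covariates to sample mean
#'   zero and unit sample standard deviation (treatments and outcome are never
#'   standardized).
#' @return An object of class \code{"dgp_spec"}.
#' @export
dgp_spec <- function(Tt, covariates, treatment, outcome,
                     outcome_variant = NULL, standardize = TRUE) {
  Tt <- as.integer(Tt)
  stopifnot(Tt >= 0, length(covariates) == Tt + 1L, length(treatment) == Tt + 1L)
  seen <- character()
  for (t in 0:Tt) {
    for (cv in covariates[[t + 1L]]) {
      stopifnot(is.character(cv$name), cv$sd > 0)
      for (tm in cv$mean)
        if (!all(tm$vars %in% seen))
          stop("covariate ", cv$name, " refers to variables not yet generated: ",
               paste(setdiff(tm$vars, seen), collapse = ", "))
      seen <- c(seen, cv$name)
    }
    for (tm in treatment[[t + 1L]])
      if (!all(tm$vars %in% seen))
        stop("treatment A", t, " refers to variables not yet generated: ",
             paste(setdiff(tm$vars, seen), collapse = ", "))
    seen <- c(seen, paste0("A", t))
  }
  stopifnot(outcome$sd > 0)
  for (tm in outcome$terms)
    if (!all(tm$vars %in% seen))
      stop("outcome refers to unknown variables: ",
           paste(setdiff(tm$vars, seen), collapse = ", "))
  structure(
    list(Tt = Tt, covariates = covariates, treatment = treatment,
         outcome = outcome, outcome_variant = outcome_variant,
         standardize = isTRUE(standardize)),
    class = "dgp_spec"
  )
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat("Sequential DGP: T =", x$Tt, "\n")
  for (t in 0:x$Tt) {
    nm <- vapply(x$covariates[[t + 1L]], `[[`, "", "name")
    rl <- vapply(x$covariates[[t + 1L]], `[[`, "", "role")
    cat("  t = ", t, ": ", paste0(nm, " (", rl, ")", collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$outcome_variant)) cat("  outcome variant:", x$outcome_variant, "\n")
  invisible(x)
}

#' The simple two-time benchmark scenario
#'
#' A two-time-point process with one confounder and one instrument per time:
#' \code{C0, I0 ~ N(0, 1)} independently; \code{A0 ~ Bernoulli(expit(1.515 C0
#' + I0))}; \code{C1 ~ N(A0 + C0, sd)}, \code{I1 ~ N(C0, sd)};
#' \code{A1 ~ Bernoulli(expit(-0.5 + 0.5 C0 + 0.25 C1 + 0.5 A0 + I1))}. The
#' treatment coefficients are calibrated so that, after marginalizing out the
#' instruments, the coefficient of \code{C0} is 1.28 in both time-specific
#' treatment models, which is what makes the two \code{C0} coefficients
#' fusible. Instruments affect only the treatments.
#'
#' The Gaussian outcome mean is built from main terms \code{C0, A0, C1, A1}
#' plus, depending on \code{outcome_variant}, a \code{C0 * C1} covariate
#' interaction or an \code{A0 * C1^2} effect-modification term. The default
#' outcome coefficients and all noise standard deviations (1) are package
#' choices, not values taken from any external source; both can be overridden.
#'
#' @param outcome_variant one of \code{"main_terms"},
#'   \code{"covariate_interaction"}, \code{"effect_modification"}.
#' @param outcome_coefficients named numeric vector overriding any of
#'   \code{"(Intercept)", "C0", "A0", "C1", "A1", "interaction"}; the
#'   \code{"interaction"} entry is the coefficient of the variant's extra term.
#' @param noise_sds named numeric vector overriding any of \code{"C1", "I1",
#'   "Y"} (all default 1).
#' @return A [dgp_spec].
#' @export
scenario1_spec <- function(outcome_variant = c("main_terms",
                                               "covariate_interaction",
                                               "effect_modification"),
                           outcome_coefficients = NULL,
                           noise_sds = NULL) {
  outcome_variant <- match.arg(outcome_variant)
  oc <- c("(Intercept)" = 0, C0 = 0.5, A0 = 0.75, C1 = 1, A1 = 1.25,
          interaction = 0.5)
  if (!is.null(outcome_coefficients)) {
    bad <- setdiff(names(outcome_coefficients), names(oc))
    if (length(bad)) stop("unknown outcome coefficient(s): ", paste(bad, collapse = ", "))
    oc[names(outcome_coefficients)] <- outcome_coefficients
  }
  sds <- c(C1 = 1, I1 = 1, Y = 1)
  if (!is.null(noise_sds)) {
    bad <- setdiff(names(noise_sds), names(sds))
    if (length(bad)) stop("unknown noise sd(s): ", paste(bad, collapse = ", "))
    sds[names(noise_sds)] <- noise_sds
  }
  oterms <- list(
    lp_term(oc[["(Intercept)"]]),
    lp_term(oc[["C0"]], "C0"),
    lp_term(oc[["A0"]], "A0"),
    lp_term(oc[["C1"]], "C1"),
    lp_term(oc[["A1"]], "A1")
  )
  if (outcome_variant == "covariate_interaction")
    oterms <- c(oterms, list(lp_term(oc[["interaction"]], c("C0", "C1"))))
  if (outcome_variant == "effect_modification")
    oterms <- c(oterms, list(lp_term(oc[["interaction"]], c("A0", "C1"), c(1L, 2L))))
  dgp_spec(
    Tt = 1L,
    covariates = list(
      list(
        list(name = "C0", role = "confounder", mean = list(), sd = 1),
        list(name = "I0", role = "instrument", mean = list(), sd = 1)
      ),
      list(
        list(name = "C1", role = "confounder",
             mean = list(lp_term(1, "A0"), lp_term(1, "C0")), sd = sds[["C1"]]),
        list(name = "I1", role = "instrument",
             mean = list(lp_term(1, "C0")), sd = sds[["I1"]])
      )
    ),
    treatment = list(
      list(lp_term(1.515, "C0"), lp_term(1, "I0")),
      list(lp_term(-0.5), lp_term(0.5, "C0"), lp_term(0.25, "C1"),
           lp_term(0.5, "A0"), lp_term(1, "I1"))
    ),
    outcome = list(terms = oterms, sd = sds[["Y"]]),
    outcome_variant = outcome_variant
  )
}

## Draw all exogenous noise for n subjects (shared across counterfactual arms).
draw_noise <- function(spec, n) {
  eps <- list()
  for (t in 0:spec$Tt) {
    for (cv in spec$covariates[[t + 1L]])
      eps[[cv$name]] <- stats::rnorm(n, 0, cv$sd)
    eps[[paste0("U_A", t)]] <- stats::runif(n)
  }
  eps$Y <- stats::rnorm(n, 0, spec$outcome$sd)
  eps
}

## Run the structural equations forward. force_A: NULL (observational) or a
## length-(T+1) 0/1 vector forced on everyone. Returns raw (unstandardized)
## variables in one environment-like list.
run_sem <- function(spec, n, eps, force_A = NULL) {
  env <- list()
  for (t in 0:spec$Tt) {
    for (cv in spec$covariates[[t + 1L]])
      env[[cv$name]] <- eval_terms(cv$mean, env, n) + eps[[cv$name]]
    p <- expit(eval_terms(spec$treatment[[t + 1L]], env, n))
    a <- as.numeric(eps[[paste0("U_A", t)]] < p)
    if (!is.null(force_A)) a <- rep(force_A[t + 1L], n)
    env[[paste0("A", t)]] <- a
  }
  env$Y <- eval_terms(spec$outcome$terms, env, n) + eps$Y
  env
}

#' Generate a longitudinal dataset from a DGP specification
#'
#' Draws all variables in causal order, then (by default) standardizes every
#' covariate to sample mean zero and unit sample standard deviation —
#' treatments and outcome are left on their natural scale — recording the
#' constants used. Deterministic given \code{seed}.
#'
#' @param spec a [dgp_spec].
#' @param n number of subjects (at least 2).
#' @param seed integer seed.
#' @return A [longdata] object.
#' @export
sim_longdata <- function(spec, n, seed) {
  stopifnot(inherits(spec, "dgp_spec"), n >= 2)
  set.seed(seed)
  eps <- draw_noise(spec, n)
  env <- run_sem(spec, n, eps)
  std <- data.frame(variable = character(), mean = numeric(), sd = numeric())
  L <- vector("list", spec$Tt + 1L)
  for (t in 0:spec$Tt) {
    nms <- vapply(spec$covariates[[t + 1L]], `[[`, "", "name")
    M <- do.call(cbind, lapply(nms, function(v) env[[v]]))
    colnames(M) <- nms
    if (spec$standardize) {
      mu <- colMeans(M)
      sdv <- apply(M, 2, stats::sd)
      M <- scale(M, center = mu, scale = sdv)
      attr(M, "scaled:center") <- NULL
      attr(M, "scaled:scale") <- NULL
      std <- rbind(std, data.frame(variable = nms, mean = mu, sd = sdv))
    }
    L[[t + 1L]] <- M
  }
  A <- do.call(cbind, lapply(0:spec$Tt, function(t) env[[paste0("A", t)]]))
  longdata(L, A, env$Y, std = if (spec$standardize) std else NULL)
}

#' All treatment patterns for T + 1 binary time points
#'
#' @param Tt last treatment time.
#' @return A \code{2^(T+1) x (T+1)} 0/1 matrix, one row per pattern.
#' @export
treatment_patterns <- function(Tt) {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), Tt + 1L)))
  dimnames(m) <- list(NULL, paste0("a", 0:Tt))
  m
}

#' Monte-Carlo true MSM parameters of a DGP
#'
#' Simulates counterfactual outcomes under every treatment pattern by forcing
#' the treatments in the causal ordering (sharing the exogenous noise draws
#' across patterns, which is valid because a pattern only changes the forced
#' treatment values), then projects \code{E(Y^a | L01)} onto the working
#' marginal structural model \code{mu0 + mu1 L01 + mu2 cum(a)} by stacked
#' least squares.
#'
#' @param spec a [dgp_spec].
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @param L01 name of the baseline covariate entering the MSM; defaults to the
#'   first baseline covariate with role \code{"confounder"}.
#' @param patterns optional restricted pattern matrix (rows are patterns);
#'   defaults to all \code{2^(T+1)}.
#' @return Named vector \code{c(mu0, mu1, mu2)}.
#' @export
true_msm_parameters <- function(spec, n_mc = 1e6, seed = 1, L01 = NULL,
                                patterns = NULL) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (is.null(L01)) L01 <- default_L01(spec)
  if (is.null(patterns)) patterns <- treatment_patterns(spec$Tt)
  set.seed(seed)
  eps <- draw_noise(spec, n_mc)
  ## standardization constants for L01 from an observational draw of the
  ## same noise (mirrors the per-sample standardization of the generator)
  obs <- run_sem(spec, n_mc, eps)
  x01 <- obs[[L01]]
  if (spec$standardize) x01 <- (x01 - mean(x01)) / stats::sd(x01)
  ys <- l01s <- cums <- vector("list", nrow(patterns))
  for (r in seq_len(nrow(patterns))) {
    a <- patterns[r, ]
    cf <- run_sem(spec, n_mc, eps, force_A = a)
    ys[[r]] <- cf$Y
    l01s[[r]] <- x01
    cums[[r]] <- rep(sum(a), n_mc)
  }
  fit <- stats::lm.fit(
    cbind(1, unlist(l01s), unlist(cums)),
    unlist(ys)
  )
  mu <- unname(fit$coefficients)
  c(mu0 = mu[1], mu1 = mu[2], mu2 = mu[3])
}

## First baseline confounder, the default MSM baseline covariate.
default_L01 <- function(spec) {
  for (cv in spec$covariates[[1L]]) if (cv$role == "confounder") return(cv$name)
  spec$covariates[[1L]][[1L]]$name
}
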
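#' Sequentially estimate the nested counterfactual regressions
#'
#' Backwards recursion for the iterated conditional expectations
#' \code{q_t(a, Lbar_t) = E(q_{t+1} | Abar_t = abar_t, Lbar_t)}, initialized
#' at \code{q_{T+1} = Y}. At each step the regression is fit on the observed
#' data (treatments as regressors) and predictions are generated with the
#' treatment history forced to each pattern prefix. The regression is linear
#' least squares on a user-supplied term list (main terms of the full history
#' by default; interactions/polynomials may be requested per time through
#' standard formula syntax).
#'
#' @param data a [longdata] object.
#' @param patterns pattern matrix (rows are treatment patterns \code{a});
#'   defaults to all \code{2^(T+1)} patterns.
#' @param q_terms optional character vector of length \code{T + 1}; element
#'   \code{t + 1} is the right-hand side of the time-\code{t} regression
#'   formula over covariate names and \code{A0..At} (e.g.
#'   \code{"C0 + I0 + A0 + C0:A0 + I(I0^2)"}). Default: all history main
#'   terms.
#' @return Object of class \code{"qstack"}: list with \code{q} (list indexed
#'   \code{t = 0..T+1} of \code{n x npatterns} prediction matrices; the last
#'   equals the observed \code{Y} in every column), \code{patterns}, and the
#'   per-time model terms used.
#' @export
fit_q_sequence <- function(data, patterns = NULL, q_terms = NULL) {
  stopifnot(inherits(data, "longdata"))
  Tt <- data$Tt
  if (is.null(patterns)) patterns <- treatment_patterns(Tt)
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != Tt + 1L) stop("patterns must have T + 1 columns")
  df <- as_wide_df(data)
  if (is.null(q_terms)) {
    q_terms <- vapply(0:Tt, function(t) {
      covs <- unlist(lapply(0:t, function(s) colnames(data$L[[s + 1L]])))
      paste(c(covs, paste0("A", 0:t)), collapse = " + ")
    }, "")
  }
  if (length(q_terms) != Tt + 1L) stop("q_terms must have one entry per time")
  npat <- nrow(patterns)
  q <- vector("list", Tt + 2L)
  q[[Tt + 2L]] <- matrix(data$Y, data$n, npat)
  for (t in Tt:0) {
    fml <- stats::as.formula(paste("..q ~", q_terms[t + 1L]))
    qt <- matrix(NA_real_, data$n, npat)
    ## at t = T the response (Y) is pattern-free: one fit serves all patterns
    fit_ids <- if (t == Tt) rep(1L, npat) else seq_len(npat)
    fits <- vector("list", npat)
    for (r in seq_len(npat)) {
      id <- fit_ids[r]
      if (is.null(fits[[id]])) {
        df$..q <- q[[t + 2L]][, r]
        fit <- stats::lm(fml, data = df)
        if (anyNA(stats::coef(fit)))
          stop("rank-deficient q regression at time ", t, "; aliased terms: ",
               paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
        fits[[id]] <- fit
      }
      nd <- df
      for (s in 0:t) nd[[paste0("A", s)]] <- patterns[r, s + 1L]
      qt[, r] <- stats::predict(fits[[id]], newdata = nd)
    }
    q[[t + 1L]] <- qt
  }
  structure(list(q = q, patterns = patterns, q_terms = q_terms, n = data$n,
                 Tt = Tt),
            class = "qstack")
}

#' @export
print.qstack <- function(x, ...) {
  cat("q-stack: ", nrow(x$patterns), " patterns, times 0..", x$Tt,
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Serialize a q-stack to long format
#'
#' @param x a [fit_q_sequence] object.
#' @return Data frame with columns \code{subject}, \code{pattern} (collapsed
#'   \code{a} string), \code{time}, \code{q}.
#' @export
qstack_long <- function(x) {
  stopifnot(inherits(x, "qstack"))
  pat <- apply(x$patterns, 1, paste, collapse = "")
  do.call(rbind, lapply(0:(x$Tt + 1L), function(t) {
    do.call(rbind, lapply(seq_along(pat), function(r) {
      data.frame(subject = seq_len(x$n), pattern = pat[r], time = t,
                 q = x$q[[t + 1L]][, r])
    }))
  }))
}

#' Stacked working structural-model coefficients at one time
#'
#' Replicates every subject once per treatment pattern, attaches the
#' time-\code{t} prediction \code{q_t^a} as response and the pattern's
#' treatment prefix \code{a_0..a_{t-1}} as regressors alongside the observed
#' covariate history, and runs an unweighted least-squares fit of the working
#' structural model (covariate history main terms plus past-treatment main
#' terms; intercept always included). The resulting coefficients beta drive
#' the adaptive penalty: covariates with beta near zero are penalized heavily.
#'
#' @param qstack a [fit_q_sequence] result.
#' @param data the [longdata] the stack was fit on.
#' @param t model time.
#' @return Named coefficient vector (intercept \code{"(Intercept)"}, covariate
#'   names, then \code{A0..A(t-1)}), with a \code{"dropped"} attribute naming
#'   any pattern-collinear treatment columns removed.
#' @export
fit_working_beta <- function(qstack, data, t) {
  stopifnot(inherits(qstack, "qstack"), inherits(data, "longdata"))
  npat <- nrow(qstack$patterns)
  n <- data$n
  covs <- unlist(lapply(0:t, function(s) colnames(data$L[[s + 1L]])))
  Xcov <- do.call(cbind, lapply(0:t, function(s) data$L[[s + 1L]]))
  rows <- rep(seq_len(n), npat)
  X <- cbind(`(Intercept)` = 1, Xcov[rows, , drop = FALSE])
  if (t > 0) {
    Atreat <- qstack$patterns[rep(seq_len(npat), each = n), seq_len(t), drop = FALSE]
    colnames(Atreat) <- paste0("A", 0:(t - 1L))
    X <- cbind(X, Atreat)
  }
  yq <- as.vector(qstack$q[[t + 1L]])
  qr_ <- qr(X)
  dropped <- character()
  if (qr_$rank < ncol(X)) {
    keep <- qr_$pivot[seq_len(qr_$rank)]
    dropped <- colnames(X)[-keep]
    warning("pattern-collinear columns dropped from working model at t = ", t,
            ": ", paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  beta <- drop(solve(crossprod(X), crossprod(X, yq)))
  names(beta) <- colnames(X)
  attr(beta, "dropped") <- dropped
  beta
}

#' Working structural-model coefficients for all times
#'
#' Runs [fit_working_beta] at every time \code{t = 0..T} and packages the
#' results with the adaptive exponent \code{gamma}. The nonzero indicator
#' forces the intercept and past-treatment slots to one; covariate indicators
#' reflect the estimates.
#'
#' @param qstack a [fit_q_sequence] result.
#' @param data the matching [longdata].
#' @param gamma adaptive-weight exponent, must exceed 2 for the selection
#'   theory (default 2.5).
#' @return Object of class \code{"working_beta"}: list with per-time
#'   coefficient vectors \code{beta}, \code{gamma}, and a tidy \code{table}
#'   (model_time, term, estimate, type).
#' @export
working_beta <- function(qstack, data, gamma = 2.5) {
  if (gamma <= 2)
    warning("gamma <= 2 does not satisfy the adaptive-selection rate condition")
  Tt <- qstack$Tt
  beta <- lapply(0:Tt, function(t) fit_working_beta(qstack, data, t))
  names(beta) <- paste0("t", 0:Tt)
  tab <- do.call(rbind, lapply(0:Tt, function(t) {
    b <- beta[[t + 1L]]
    type <- ifelse(names(b) == "(Intercept)", "intercept",
                   ifelse(grepl("^A[0-9]+$", names(b)), "treatment", "covariate"))
    data.frame(model_time = t, term = names(b), estimate = unname(b), type = type)
  }))
  structure(list(beta = beta, gamma = gamma, table = tab), class = "working_beta")
}

#' @export
print.working_beta <- function(x, ...) {
  cat("Working structural-model coefficients (gamma =", x$gamma, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

## beta value for pooled-design coefficient (tau, var); covariate var measured
## at time t enters the time-tau working model.
beta_lookup <- function(wbeta, tau, var) {
  b <- wbeta$beta[[tau + 1L]]
  if (!var %in% names(b)) return(NA_real_)
  unname(b[var])
}
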
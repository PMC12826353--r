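#' Build the pooled treatment-model design (V-transformation)
#'
#' Stacks the time-specific treatment (or censoring) models into one
#' no-intercept logistic design. For each row, exactly one time block
#' \code{tau} is active: the block holds a per-time intercept indicator
#' \code{I(time = tau)}, covariate columns \code{I(time = tau) * L_{t,k}} for
#' every history time \code{t <= tau} allowed by \code{history}, and
#' past-process columns \code{I(time = tau) * A_s} for \code{s < tau}. The
#' shrinkable index set contains the covariate columns only: per-time
#' intercepts and past-treatment slots are never penalized.
#'
#' For an absorbing process (monotone treatment initiation, or censoring),
#' rows after absorption are dropped via the at-risk mask.
#'
#' @param data a [longdata] object.
#' @param process \code{"treatment"} models \code{A_tau}; \code{"censoring"}
#'   models \code{C_tau} (requires \code{data$C}).
#' @param history \code{"full"} (all lags) or a non-negative integer: the
#'   maximum covariate lag \code{tau - t} entering model \code{tau}.
#' @param absorbing logical; if \code{TRUE} only subjects with the process
#'   still at 0 before \code{tau} are at risk at \code{tau}. Censoring is
#'   always treated as absorbing.
#' @return An object of class \code{"pooled_design"}: list with the model
#'   matrix \code{X} (named columns), response \code{y}, \code{index_map}
#'   (data frame: \code{col}, \code{tau}, \code{t}, \code{k}, \code{var},
#'   \code{type}), logical \code{shrink} (the set of penalized columns),
#'   \code{row_map} (subject, tau) and bookkeeping fields.
#' @export
build_pooled_design <- function(data, process = c("treatment", "censoring"),
                                history = "full", absorbing = FALSE) {
  stopifnot(inherits(data, "longdata"))
  process <- match.arg(process)
  Tt <- data$Tt
  n <- data$n
  if (process == "censoring") {
    if (is.null(data$C)) stop("data has no censoring indicators")
    absorbing <- TRUE
  }
  max_lag <- if (identical(history, "full")) Tt else {
    if (!is.numeric(history) || history < 0) stop("history must be \"full\" or a non-negative lag")
    as.integer(history)
  }

  ## column layout
  cols <- list()
  for (tau in 0:Tt) {
    cols[[length(cols) + 1L]] <-
      data.frame(tau = tau, t = NA_integer_, k = NA_integer_,
                 var = sprintf("(t%d)", tau), type = "intercept")
    for (t in 0:tau) {
      if (tau - t > max_lag) next
      nm <- colnames(data$L[[t + 1L]])
      if (length(nm))
        cols[[length(cols) + 1L]] <-
          data.frame(tau = tau, t = t, k = seq_along(nm), var = nm, type = "covariate")
    }
    if (tau > 0)
      cols[[length(cols) + 1L]] <-
        data.frame(tau = tau, t = seq_len(tau) - 1L, k = NA_integer_,
                   var = paste0("A", seq_len(tau) - 1L), type = "treatment")
  }
  index_map <- do.call(rbind, cols)
  index_map$col <- paste0("tau", index_map$tau, ":", index_map$var)
  rownames(index_map) <- NULL

  ## at-risk rows
  resp <- if (process == "treatment") data$A else data$C
  at_risk <- matrix(TRUE, n, Tt + 1L)
  if (absorbing) {
    prev <- if (process == "treatment") data$A else data$C
    for (tau in seq_len(Tt))
      at_risk[, tau + 1L] <- at_risk[, tau] & prev[, tau] == 0
  }
  if (process == "treatment" && !is.null(data$C)) {
    ## censored subjects contribute only up to censoring
    for (tau in 0:Tt) at_risk[, tau + 1L] <- at_risk[, tau + 1L] & data$C[, tau + 1L] == 0
  }

  rows <- do.call(rbind, lapply(0:Tt, function(tau) {
    idx <- which(at_risk[, tau + 1L])
    data.frame(subject = idx, tau = tau)
  }))
  X <- matrix(0, nrow(rows), nrow(index_map),
              dimnames = list(NULL, index_map$col))
  y <- numeric(nrow(rows))
  for (tau in 0:Tt) {
    r <- which(rows$tau == tau)
    if (!length(r)) next
    subj <- rows$subject[r]
    jblk <- which(index_map$tau == tau)
    for (j in jblk) {
      im <- index_map[j, ]
      X[r, j] <- switch(
        im$type,
        intercept = 1,
        covariate = data$L[[im$t + 1L]][subj, im$k],
        treatment = data$A[subj, im$t + 1L]
      )
    }
    y[r] <- resp[subj, tau + 1L]
  }
  structure(
    list(X = X, y = y, index_map = index_map,
         shrink = index_map$type == "covariate",
         row_map = rows, process = process, Tt = Tt, n = n,
         history = history, absorbing = absorbing),
    class = "pooled_design"
  )
}

#' @export
print.pooled_design <- function(x, ...) {
  cat("Pooled ", x$process, " design: ", nrow(x$X), " rows (n = ", x$n,
      ", times 0..", x$Tt, "), ", ncol(x$X), " columns, ",
      sum(x$shrink), " shrinkable\n", sep = "")
  invisible(x)
}

## Locate design columns for (tau, var) pairs.
design_col <- function(design, tau, var) {
  m <- design$index_map
  i <- which(m$tau == tau & m$var == var)
  if (!length(i)) NA_integer_ else i
}
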
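#' Longitudinal observational data container
#'
#' Holds per-subject trajectories for a time-varying treatment study: covariate
#' matrices \code{L[[t+1]]} for times \code{t = 0, ..., T}, binary treatment
#' columns \code{A[, t+1]}, an optional monotone censoring indicator matrix
#' \code{C}, and a continuous end-of-study outcome \code{Y}. Covariate names
#' must be unique across all times so that a variable can be addressed by name
#' anywhere in the pipeline.
#'
#' @param L list of length \code{T + 1}; element \code{t + 1} is an
#'   \code{n x p_t} numeric matrix with column names, the covariates measured
#'   just before treatment \code{A_t}.
#' @param A \code{n x (T + 1)} matrix (or vector when \code{T = 0}) of 0/1
#'   treatments.
#' @param Y numeric outcome vector of length \code{n}.
#' @param C optional \code{n x (T + 1)} matrix of 0/1 censoring indicators;
#'   \code{C[, t + 1] = 1} means the subject is censored by time \code{t} and
#'   contributes no data from that time on.
#' @param std optional standardization record: a data frame with columns
#'   \code{variable}, \code{mean}, \code{sd} describing the location/scale
#'   applied to each covariate column.
#'
#' @return An object of class \code{"longdata"}: a list with elements
#'   \code{L}, \code{A}, \code{C}, \code{Y}, \code{Tt} (the index of the last
#'   treatment time), \code{n} and \code{std}.
#' @export
longdata <- function(L, A, Y, C = NULL, std = NULL) {
  if (!is.list(L)) L <- list(L)
  L <- lapply(L, function(x) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) stop("every covariate matrix must have column names")
    storage.mode(x) <- "double"
    x
  })
  if (is.vector(A)) A <- matrix(A, ncol = 1L)
  A <- as.matrix(A)
  Tt <- ncol(A) - 1L
  if (length(L) != Tt + 1L)
    stop("length(L) must equal ncol(A): one covariate block per treatment time")
  n <- length(Y)
  dims <- c(vapply(L, nrow, 1L), nrow(A), if (!is.null(C)) nrow(as.matrix(C)))
  if (any(dims != n)) stop("all components must describe the same n subjects")
  if (!all(A %in% c(0, 1))) stop("treatments must be binary 0/1")
  nm <- unlist(lapply(L, colnames))
  if (anyDuplicated(nm)) stop("covariate names must be unique across times")
  if (any(nm %in% paste0("A", 0:Tt)) || "Y" %in% nm)
    stop("covariate names may not clash with treatment/outcome names")
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (!all(C %in% c(0, 1))) stop("censoring indicators must be binary 0/1")
    if (any(apply(C, 1, function(r) any(diff(r) < 0))))
      stop("censoring must be monotone: once censored, always censored")
  }
  structure(
    list(L = L, A = A, C = C, Y = as.numeric(Y), Tt = Tt, n = n, std = std),
    class = "longdata"
  )
}

#' @export
print.longdata <- function(x, ...) {
  p <- vapply(x$L, ncol, 1L)
  cat("Longitudinal data: n =", x$n, ", treatment times 0..", x$Tt, "\n", sep = "")
  for (t in 0:x$Tt)
    cat("  t = ", t, ": L", t, " = {", paste(colnames(x$L[[t + 1L]]), collapse = ", "),
        "}, mean(A", t, ") = ", round(mean(x$A[, t + 1L]), 3), "\n", sep = "")
  cat("  Y: mean ", round(mean(x$Y), 3), ", sd ", round(stats::sd(x$Y), 3), "\n", sep = "")
  if (!is.null(x$C)) cat("  censoring present\n")
  invisible(x)
}

#' Flatten a longdata object to one wide data frame
#'
#' One row per subject; covariate columns keep their (globally unique) names,
#' treatments appear as \code{A0, A1, ...} and the outcome as \code{Y}.
#'
#' @param data a [longdata] object.
#' @return A data frame with \code{data$n} rows.
#' @export
as_wide_df <- function(data) {
  stopifnot(inherits(data, "longdata"))
  out <- list()
  for (t in 0:data$Tt) {
    Lt <- data$L[[t + 1L]]
    for (k in seq_len(ncol(Lt))) out[[colnames(Lt)[k]]] <- Lt[, k]
    out[[paste0("A", t)]] <- data$A[, t + 1L]
  }
  out$Y <- data$Y
  as.data.frame(out)
}

#' Write a longdata object as wide CSV plus a JSON sidecar
#'
#' The CSV has headers \code{L<t>_<name>}, \code{A<t>}, ..., \code{Y} (one row
#' per subject). The sidecar (same path with extension \code{.json}) records
#' the generating specification, when known, and the standardization record.
#'
#' @param data a [longdata] object.
#' @param path output CSV path.
#' @param spec optional [dgp_spec] stored in the sidecar for provenance.
#' @return \code{path}, invisibly.
#' @export
write_longdata <- function(data, path, spec = NULL) {
  stopifnot(inherits(data, "longdata"))
  out <- list()
  for (t in 0:data$Tt) {
    Lt <- data$L[[t + 1L]]
    for (k in seq_len(ncol(Lt)))
      out[[paste0("L", t, "_", colnames(Lt)[k])]] <- Lt[, k]
    if (!is.null(data$C)) out[[paste0("C", t)]] <- data$C[, t + 1L]
    out[[paste0("A", t)]] <- data$A[, t + 1L]
  }
  out$Y <- data$Y
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  side <- list(
    n = data$n, T = data$Tt,
    covariates = lapply(data$L, colnames),
    standardization = data$std,
    spec = spec
  )
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
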
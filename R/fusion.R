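#' Build the allowed-fusion graph over selected coefficients
#'
#' Nodes are the pooled-design coefficient indices \code{(tau, t, k)} that
#' survived the selection step. Edges connect coefficients of the same
#' underlying covariate across time-specific treatment models: a covariate
#' measured once fuses across all model times where it was selected (all
#' pairs under the \code{"clique"} family, successive times under
#' \code{"chain"}); covariates declared as repeated measurements of one
#' series (via \code{series}) fuse only at equal lag \code{tau - t}. A
#' covariate selected at a single time is an isolated node.
#'
#' @param active data frame of selected shrinkable columns (rows of the
#'   design \code{index_map}, as stored in a [loal] fit).
#' @param family \code{"clique"} or \code{"chain"}.
#' @param series optional named character vector mapping covariate names to a
#'   series identifier for time-updated variables; unlisted covariates are
#'   their own series.
#' @return Object of class \code{"fusion_graph"}: list with \code{nodes} (the
#'   \code{active} frame plus a fusion identity column) and \code{edges}
#'   (two-column matrix of row indices into \code{nodes}).
#' @export
build_fusion_graph <- function(active, family = c("clique", "chain"),
                               series = NULL) {
  family <- match.arg(family)
  if (!nrow(active)) stop("active set is empty: nothing to fuse")
  ident <- vapply(seq_len(nrow(active)), function(i) {
    v <- active$var[i]
    if (!is.null(series) && v %in% names(series))
      paste0("series:", series[[v]], ":lag", active$tau[i] - active$t[i])
    else paste0("var:", v)
  }, "")
  edges <- NULL
  for (id in unique(ident)) {
    nd <- which(ident == id)
    nd <- nd[order(active$tau[nd])]
    if (length(nd) < 2L) next
    pairs <- if (family == "clique") utils::combn(nd, 2L)
             else rbind(nd[-length(nd)], nd[-1L])
    edges <- rbind(edges, t(pairs))
  }
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  nodes <- active
  nodes$identity <- ident
  structure(list(nodes = nodes, edges = edges, family = family),
            class = "fusion_graph")
}

#' @export
print.fusion_graph <- function(x, ...) {
  cat("Fusion graph (", x$family, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges))
    for (e in seq_len(nrow(x$edges)))
      cat("  ", x$nodes$col[x$edges[e, 1L]], " -- ",
          x$nodes$col[x$edges[e, 2L]], "\n", sep = "")
  invisible(x)
}

#' Adaptive fusion weights from refitted coefficients
#'
#' Per-edge weight \code{|refit_u - refit_v|^(-gamma1)}: edges whose refitted
#' coefficients already sit close together are pushed hard toward exact
#' equality. Exactly equal refits get the documented cap (forcing fusion).
#'
#' @param refit named coefficient vector over design columns (the
#'   unpenalized refit of the selected model).
#' @param graph a [build_fusion_graph] object.
#' @param gamma1 positive exponent (default 2.5).
#' @param zero_cap weight when the refit difference is exactly zero.
#' @return Numeric vector, one weight per edge.
#' @export
fusion_weights <- function(refit, graph, gamma1 = 2.5, zero_cap = 1e12) {
  stopifnot(inherits(graph, "fusion_graph"), gamma1 > 0)
  if (!nrow(graph$edges)) return(numeric())
  vapply(seq_len(nrow(graph$edges)), function(e) {
    d <- abs(refit[graph$nodes$col[graph$edges[e, 1L]]] -
             refit[graph$nodes$col[graph$edges[e, 2L]]])
    if (d == 0) {
      warning("refit coefficients exactly equal on a fusion edge; weight capped")
      zero_cap
    } else d^(-gamma1)
  }, 0)
}

## Detect fusion groups: connected components of the edge subgraph where the
## fitted values coincide within the snap tolerance.
fusion_groups <- function(alpha_nodes, edges, tol = 1e-6) {
  member <- seq_along(alpha_nodes)
  if (nrow(edges)) repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      if (member[u] != member[v] &&
          abs(alpha_nodes[u] - alpha_nodes[v]) < tol * (1 + abs(alpha_nodes[u]))) {
        member[member == member[v]] <- member[u]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(member, unique(member))
}

## Refit the pooled logistic with fused columns summed; returns the
## full-length coefficient vector (fused groups share one value) and loglik.
snap_refit <- function(X, y, node_cols, member) {
  p <- ncol(X)
  Z <- NULL
  map <- list()
  for (gid in unique(member)) {
    cols <- node_cols[member == gid]
    Z <- cbind(Z, rowSums(X[, cols, drop = FALSE]))
    map[[length(map) + 1L]] <- cols
  }
  other <- setdiff(seq_len(p), node_cols)
  Z <- cbind(Z, X[, other, drop = FALSE])
  fit <- suppressWarnings(stats::glm.fit(Z, y, family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  alpha <- numeric(p)
  for (i in seq_along(map)) alpha[map[[i]]] <- co[i]
  alpha[other] <- co[length(map) + seq_along(other)]
  names(alpha) <- colnames(X)
  list(alpha = alpha, loglik = penlogit_loglik(X, y, alpha))
}

#' Fit the adaptive fused-LASSO path over a lambda1 grid
#'
#' For each \code{lambda1}, minimizes the pooled logistic negative
#' log-likelihood plus \code{lambda1 * sum_e w_e |alpha_u - alpha_v|} over
#' the selected-model columns (no magnitude penalty, so the zero pattern of
#' the first step is preserved). Nearly equal coefficients are snapped to a
#' discrete fusion partition (tolerance \code{1e-6 * (1 + |alpha|)}) and the
#' partition is refit exactly with the fused columns summed; BIC is computed
#' from the snapped refit, so candidates along the path are compared as
#' discrete fusion structures:
#' \code{BIC = -2 loglik + df log(N)} with \code{df} the number of distinct
#' coefficient values among graph nodes plus the number of remaining free
#' parameters, and \code{N} the pooled row count.
#'
#' @param X,y restricted pooled design (selected + unpenalized columns) and
#'   stacked response; typically taken from a [loal] fit.
#' @param graph a [build_fusion_graph] whose node \code{col} names match
#'   columns of \code{X}.
#' @param weights per-edge adaptive weights ([fusion_weights]).
#' @param lambda1 grid of fusion penalties; if \code{NULL}, \code{0} plus
#'   \code{nlambda1} log-spaced values whose upper end is doubled until the
#'   whole graph fuses.
#' @param nlambda1 grid size.
#' @param start warm-start coefficients.
#' @return Object of class \code{"fused_path"}: data frame \code{table}
#'   (lambda1, df, loglik, bic, n_groups), list \code{alphas} of snapped
#'   full-length coefficient vectors, list \code{members} of node partitions.
#' @export
fit_fused <- function(X, y, graph, weights, lambda1 = NULL, nlambda1 = 20L,
                      start = NULL) {
  node_cols <- match(graph$nodes$col, colnames(X))
  if (anyNA(node_cols)) stop("graph nodes missing from design columns")
  edges <- graph$edges
  edges_cols <- cbind(node_cols[edges[, 1L]], node_cols[edges[, 2L]])
  n_free <- ncol(X) - nrow(graph$nodes)
  N <- nrow(X)
  full_groups <- function(member) {
    ## has every connected component of the allowed graph fused?
    want <- fusion_groups(rep(0, nrow(graph$nodes)), edges, tol = Inf)
    length(unique(member)) == length(unique(want))
  }
  solve_at <- function(l1, st) {
    if (l1 == 0 || !nrow(edges)) {
      a <- restricted_mle(X, y, rep(TRUE, ncol(X)))
      names(a) <- colnames(X)
      list(alpha = a)
    } else {
      fusedlogit(X, y, edges_cols, l1 * weights, start = st)
    }
  }
  if (is.null(lambda1)) {
    upper <- 1
    st <- start
    for (i in 1:40) {
      sol <- solve_at(upper, st)
      member <- fusion_groups(sol$alpha[node_cols], edges)
      if (full_groups(member)) break
      upper <- upper * 2
      st <- sol$alpha
    }
    lambda1 <- c(0, exp(seq(log(upper * 1e-4), log(upper), length.out = nlambda1)))
  }
  lambda1 <- sort(unique(lambda1))
  alphas <- members <- vector("list", length(lambda1))
  tab <- data.frame(lambda1 = lambda1, df = NA_real_, loglik = NA_real_,
                    bic = NA_real_, n_groups = NA_integer_)
  st <- start
  cache <- list()
  for (i in seq_along(lambda1)) {
    sol <- solve_at(lambda1[i], st)
    st <- sol$alpha
    member <- fusion_groups(sol$alpha[node_cols], edges)
    key <- paste(member, collapse = ".")
    if (is.null(cache[[key]]))
      cache[[key]] <- snap_refit(X, y, node_cols, member)
    snap <- cache[[key]]
    alphas[[i]] <- snap$alpha
    members[[i]] <- member
    df <- length(unique(member)) + n_free
    tab$df[i] <- df
    tab$loglik[i] <- snap$loglik
    tab$bic[i] <- -2 * snap$loglik + df * log(N)
    tab$n_groups[i] <- length(unique(member))
  }
  structure(list(table = tab, alphas = alphas, members = members,
                 graph = graph, weights = weights, N = N),
            class = "fused_path")
}

#' Select the fusion structure by BIC
#'
#' Returns the path entry minimizing BIC; ties are broken toward the more
#' fused model (smaller degrees of freedom, then larger lambda1).
#'
#' @param paths a [fit_fused] object, or a list of them (e.g. one per
#'   \code{gamma1} value) each tagged with a \code{gamma1} attribute.
#' @return List: \code{alpha} (snapped coefficients), \code{member} (node
#'   partition), \code{lambda1}, \code{gamma1} (if tagged), \code{bic},
#'   \code{table} (the combined grid trace).
#' @export
select_by_bic <- function(paths) {
  if (inherits(paths, "fused_path")) paths <- list(paths)
  tabs <- do.call(rbind, lapply(seq_along(paths), function(i) {
    tb <- paths[[i]]$table
    tb$gamma1 <- attr(paths[[i]], "gamma1") %||% NA_real_
    tb$path_id <- i
    tb$within_id <- seq_len(nrow(tb))
    tb
  }))
  o <- order(tabs$bic, tabs$df, -tabs$lambda1)
  pick <- tabs[o[1L], ]
  pth <- paths[[pick$path_id]]
  list(alpha = pth$alphas[[pick$within_id]],
       member = pth$members[[pick$within_id]],
       lambda1 = pick$lambda1, gamma1 = pick$gamma1, bic = pick$bic,
       table = tabs)
}

#' Adaptive fused LASSO smoothing of a selected treatment model
#'
#' The second step of the two-step procedure: starting from a [loal] fit,
#' restricts the pooled design to the selected and always-kept columns,
#' builds the allowed-fusion graph, computes adaptive fusion weights
#' \code{|refit_u - refit_v|^(-gamma1)} from the unpenalized refit, fits the
#' fused path over \code{lambda1} (and a grid of \code{gamma1} values), and
#' selects the fusion structure by BIC.
#'
#' @param object a [loal] fit.
#' @param family fusion graph family: \code{"clique"} (default) or
#'   \code{"chain"}.
#' @param gamma1 vector of candidate adaptive exponents (default 2.5).
#' @param nlambda1 lambda1 grid size per gamma1.
#' @param series optional covariate-to-series map for lagged time-varying
#'   covariates (see [build_fusion_graph]).
#' @return An object of class \code{"fused_loal"} extending the [loal] fit
#'   with \code{graph}, \code{alpha_star} (full-length fused coefficients
#'   over all design columns), \code{member} (fusion partition of the graph
#'   nodes), \code{fusion} (the BIC selection record) and \code{gamma1}.
#' @export
fuse <- function(object, family = c("clique", "chain"), gamma1 = 2.5,
                 nlambda1 = 20L, series = NULL) {
  stopifnot(inherits(object, "loal"))
  family <- match.arg(family)
  design <- object$design
  keep <- !design$shrink | object$refit != 0
  X <- design$X[, keep, drop = FALSE]
  y <- design$y
  active <- object$active
  graph <- build_fusion_graph(active, family = family, series = series)
  start <- object$refit[keep]
  paths <- lapply(gamma1, function(g1) {
    w <- fusion_weights(object$refit, graph, gamma1 = g1)
    pth <- fit_fused(X, y, graph, w, nlambda1 = nlambda1, start = start)
    attr(pth, "gamma1") <- g1
    pth
  })
  sel <- select_by_bic(paths)
  alpha_star <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  alpha_star[names(sel$alpha)] <- sel$alpha
  out <- object
  out$graph <- graph
  out$alpha_star <- alpha_star
  out$member <- sel$member
  out$fusion <- sel
  out$gamma1 <- sel$gamma1
  out$call_fuse <- match.call()
  class(out) <- c("fused_loal", "loal")
  out
}

#' @export
print.fused_loal <- function(x, ...) {
  cat("Fused longitudinal outcome-adaptive LASSO (", x$process, " process)\n",
      sep = "")
  cat("  step 1: lambda_n = ", signif(x$lambda, 4), ", ", nrow(x$active),
      " covariate columns selected\n", sep = "")
  cat("  step 2: gamma1 = ", x$gamma1, ", lambda1 = ",
      signif(x$fusion$lambda1, 4), ", BIC = ", round(x$fusion$bic, 2),
      "\n", sep = "")
  nd <- x$graph$nodes
  for (gid in unique(x$member)) {
    cols <- nd$col[x$member == gid]
    if (length(cols) > 1L)
      cat("  fused: {", paste(cols, collapse = ", "), "} = ",
          signif(x$alpha_star[cols[1L]], 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fused_loal <- function(object, ...) object$alpha_star

#' Fused coefficient table with group identifiers
#'
#' @param fit a [fuse] result.
#' @return Data frame (time, term, estimate, group): non-NA \code{group}
#'   labels coefficients tied by fusion.
#' @export
fused_table <- function(fit) {
  stopifnot(inherits(fit, "fused_loal"))
  m <- fit$design$index_map
  grp <- rep(NA_integer_, nrow(m))
  grp[match(fit$graph$nodes$col, m$col)] <- fit$member
  data.frame(time = m$tau, term = m$var, type = m$type,
             estimate = unname(fit$alpha_star), group = grp)
}
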
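## Graph adaptive fused-LASSO logistic regression.
## Minimizes  -loglik(alpha) + sum_e pen_e * |alpha_u(e) - alpha_v(e)|
## with no magnitude (sparsity) penalty. Solved by an IRLS outer loop around
## an exact solver of the weighted-least-squares fused problem: coordinate
## moves over fusion groups, with merge moves when groups meet and
## enumeration-based split checks, in the spirit of the coordinate-wise
## algorithms for the generalized fused LASSO.

## 1-D exact minimizer of 0.5*a*x^2 - b*x + sum_k c_k |x - d_k| (a > 0).
min_piecewise <- function(a, b, c, d) {
  if (!length(d)) return(b / a)
  o <- order(d)
  d <- d[o]; c <- c[o]
  ## derivative: a*x - b + sum c_k sign(x - d_k)
  for (i in 0:length(d)) {
    lo <- if (i == 0) -Inf else d[i]
    hi <- if (i == length(d)) Inf else d[i + 1L]
    s <- sum(c * ifelse(seq_along(d) <= i, 1, -1))
    x <- (b - s) / a
    if (x >= lo && x <= hi) return(x)
  }
  ## otherwise a breakpoint is the minimizer: check subgradient containment
  for (i in seq_along(d)) {
    sl <- a * d[i] - b + sum(c[seq_along(d) < i]) - sum(c[seq_along(d) > i])
    if (sl - c[i] <= 1e-12 && sl + c[i] >= -1e-12) return(d[i])
  }
  d[which.min(vapply(d, function(x) 0.5 * a * x^2 - b * x + sum(c * abs(x - d)), 0))]
}

## Exact-ish solver of the quadratic fused problem:
##   0.5 alpha' H alpha - g' alpha + sum_e pen_e |alpha_u - alpha_v|
## groups: integer membership vector (same value = fused). Returns alpha and
## final membership.
fused_quadratic <- function(H, g, edges, pen, alpha, tol = 1e-10,
                            maxit = 10000L, split_cap = 16L) {
  p <- length(alpha)
  member <- seq_len(p)
  smooth_grad <- function(a) drop(H %*% a) - g
  n_edge <- nrow(edges)
  if (!n_edge || all(pen == 0))
    return(list(alpha = drop(solve(H, g)), member = member))
  for (it in seq_len(maxit)) {
    moved <- FALSE
    ## (1) coordinate moves over current groups
    for (gid in unique(member)) {
      G <- which(member == gid)
      ind <- numeric(p); ind[G] <- 1
      a_q <- drop(crossprod(ind, H %*% ind))
      if (a_q < 1e-14) next
      other <- alpha; other[G] <- 0
      b_q <- sum(ind * (g - drop(H %*% other)))
      cs <- ds <- numeric(0)
      if (n_edge) for (e in seq_len(n_edge)) {
        u <- edges[e, 1L]; v <- edges[e, 2L]
        inu <- member[u] == gid; inv <- member[v] == gid
        if (inu == inv) next
        ds <- c(ds, alpha[if (inu) v else u]); cs <- c(cs, pen[e])
      }
      x <- min_piecewise(a_q, b_q, cs, ds)
      if (abs(x - alpha[G][1L]) > tol) {
        alpha[G] <- x
        moved <- TRUE
      }
    }
    ## (2) merge groups that meet across an allowed edge
    if (n_edge) for (e in seq_len(n_edge)) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      if (member[u] != member[v] && abs(alpha[u] - alpha[v]) < 1e-9) {
        member[member == member[v]] <- member[u]
        alpha[member == member[u]] <- alpha[u]
        moved <- TRUE
      }
    }
    if (!moved) {
      ## (3) split check by subset enumeration on each fused group
      improved <- FALSE
      sg <- smooth_grad(alpha)
      for (gid in unique(member)) {
        G <- which(member == gid)
        if (length(G) < 2L) next
        if (length(G) > split_cap) {
          warning("fusion group larger than split enumeration cap; ",
                  "split optimality not verified for this group")
          next
        }
        nG <- length(G)
        best <- NULL
        for (mask in 1:(2^nG - 2L)) {
          S <- G[bitwAnd(mask, 2^(seq_len(nG) - 1L)) > 0]
          dpen_pos <- dpen_neg <- 0
          if (n_edge) for (e in seq_len(n_edge)) {
            u <- edges[e, 1L]; v <- edges[e, 2L]
            inS <- c(u %in% S, v %in% S)
            if (all(inS) || !any(inS)) next
            out_node <- if (inS[1L]) v else u
            if (out_node %in% G) {           # internal edge cut by the split
              dpen_pos <- dpen_pos + pen[e]; dpen_neg <- dpen_neg + pen[e]
            } else {
              dv <- alpha[S[1L]] - alpha[out_node]
              if (abs(dv) < 1e-12) { dpen_pos <- dpen_pos + pen[e]; dpen_neg <- dpen_neg + pen[e] }
              else { dpen_pos <- dpen_pos + pen[e] * sign(dv); dpen_neg <- dpen_neg - pen[e] * sign(dv) }
            }
          }
          gS <- sum(sg[S])
          if (gS + dpen_pos < -1e-9 || -gS + dpen_neg < -1e-9) { best <- S; break }
        }
        if (!is.null(best)) {
          newid <- max(member) + 1L
          member[best] <- newid
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(alpha = alpha, member = member)
}

fused_objective <- function(X, y, alpha, edges, pen) {
  obj <- -penlogit_loglik(X, y, alpha)
  if (nrow(edges))
    obj <- obj + sum(pen * abs(alpha[edges[, 1L]] - alpha[edges[, 2L]]))
  obj
}

## IRLS driver for the fused logistic problem.
fusedlogit <- function(X, y, edges, pen, start = NULL, tol = 1e-8,
                       maxit = 200L, wmin = 1e-6) {
  p <- ncol(X)
  edges <- matrix(as.integer(edges), ncol = 2L)
  alpha <- start %||% numeric(p)
  member <- seq_len(p)
  converged <- FALSE
  for (outer in seq_len(maxit)) {
    eta <- drop(X %*% alpha)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), wmin)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w)
    g <- drop(crossprod(X, w * z))
    sol <- fused_quadratic(H, g, edges, pen, alpha)
    if (max(abs(sol$alpha - alpha)) < tol && outer > 1L) {
      alpha <- sol$alpha; member <- sol$member; converged <- TRUE; break
    }
    alpha <- sol$alpha; member <- sol$member
  }
  if (!converged) stop("fused logistic solver did not converge")
  list(alpha = alpha, member = member,
       objective = fused_objective(X, y, alpha, edges, pen))
}
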
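# Fixtures and independent oracles shared across the suite.

# Small deterministic two-time dataset with exactly linear outcome
# Y = 1 + 2*C0 + 3*C1 + 1.5*A0 + 0.5*A1 (no noise), for exact-recovery checks.
linear_fixture <- function(n = 60, seed = 101) {
  set.seed(seed)
  C0 <- rnorm(n); I0 <- rnorm(n)
  A0 <- rbinom(n, 1, plogis(0.5 * C0))
  C1 <- rnorm(n, C0 + A0); I1 <- rnorm(n, C0)
  A1 <- rbinom(n, 1, plogis(0.3 * C0 + 0.4 * C1 + 0.2 * A0))
  Y <- 1 + 2 * C0 + 3 * C1 + 1.5 * A0 + 0.5 * A1
  longdata(
    L = list(cbind(C0 = C0, I0 = I0), cbind(C1 = C1, I1 = I1)),
    A = cbind(A0, A1), Y = Y
  )
}

# Single-time dataset with a binary covariate, for saturated-model identities.
discrete_fixture <- function(n = 120, seed = 7) {
  set.seed(seed)
  Z <- rbinom(n, 1, 0.5)
  A0 <- rbinom(n, 1, plogis(-0.3 + 0.9 * Z))
  Y <- 1 + Z + 2 * A0 - 0.8 * Z * A0 + rnorm(n, 0, 0.5)
  longdata(L = list(cbind(Z = Z)), A = cbind(A0 = A0), Y = Y)
}

# Standard scenario-based pooled-design fixture for path/selection tests.
make_path_fixture <- function(n = 200, seed = 17) {
  d <- sim_longdata(scenario1_spec("main_terms"), n, seed)
  qs <- fit_q_sequence(d)
  wb <- working_beta(qs, d)
  des <- build_pooled_design(d)
  list(data = d, design = des, beta = wb,
       omega = adaptive_weights(wb, des))
}

# Brute-force minimizer of the weighted-L1 penalized logistic objective:
# coarse lattice over all coefficients, polished by Nelder-Mead restarts.
# Returns the best objective value found; independent of the package solver.
bf_penlogit_objective <- function(X, y, penalty, lattice = seq(-3, 3, by = 0.75)) {
  obj <- function(a) {
    eta <- drop(X %*% a)
    -sum(y * eta - log1p(exp(eta))) + sum(penalty * abs(a))
  }
  p <- ncol(X)
  grid <- as.matrix(expand.grid(rep(list(lattice), p)))
  vals <- apply(grid, 1, obj)
  starts <- list(grid[which.min(vals), ], numeric(p))
  best <- Inf
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# Brute-force minimizer of the fused logistic objective (edge penalties).
bf_fused_objective <- function(X, y, edges, pen, lattice = seq(-2, 2, by = 0.5)) {
  obj <- function(a) {
    eta <- drop(X %*% a)
    v <- -sum(y * eta - log1p(exp(eta)))
    if (nrow(edges)) v <- v + sum(pen * abs(a[edges[, 1]] - a[edges[, 2]]))
    v
  }
  p <- ncol(X)
  grid <- as.matrix(expand.grid(rep(list(lattice), p)))
  vals <- apply(grid, 1, obj)
  starts <- list(grid[which.min(vals), ], numeric(p))
  best <- Inf
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    o <- optim(o$par, obj, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# Independent hand-coded forward simulator of the simple two-time scenario
# (main-terms outcome), bypassing the package's structural-equation engine.
# Used as the counterfactual-mean oracle.
hand_scenario1_counterfactual_mu <- function(oc, n, seed) {
  set.seed(seed)
  C0 <- rnorm(n); I0 <- rnorm(n)
  eC1 <- rnorm(n); eI1 <- rnorm(n); eY <- rnorm(n)
  U0 <- runif(n); U1 <- runif(n)
  l01 <- NULL; ys <- NULL; cums <- NULL
  obsC0 <- (C0 - mean(C0)) / sd(C0)
  for (a0 in 0:1) for (a1 in 0:1) {
    C1 <- a0 + C0 + eC1
    Y <- oc[["(Intercept)"]] + oc[["C0"]] * C0 + oc[["A0"]] * a0 +
      oc[["C1"]] * C1 + oc[["A1"]] * a1 + eY
    ys <- c(ys, Y); l01 <- c(l01, obsC0); cums <- c(cums, rep(a0 + a1, n))
  }
  unname(lm(ys ~ l01 + cums)$coefficients)
}

# Oracle-selected restricted pooled design plus refit, for fusion tests.
fused_instance <- function(n = 500, seed = 13) {
  d <- sim_longdata(scenario1_spec("main_terms"), n, seed)
  des <- build_pooled_design(d)
  m <- des$index_map
  oracle_cols <- c("tau0:C0", "tau1:C0", "tau1:C1")
  keep <- !des$shrink | (m$col %in% oracle_cols)
  X <- des$X[, keep, drop = FALSE]
  refit <- loalfuse:::restricted_mle(X, des$y, rep(TRUE, ncol(X)))
  names(refit) <- colnames(X)
  graph <- build_fusion_graph(m[m$col %in% oracle_cols, ], "clique")
  list(X = X, y = des$y, graph = graph, refit = refit)
}

# Oracle-weighted fusion of the two baseline-confounder coefficients on a
# freshly simulated treatment process; returns TRUE if they fused.
oracle_fusion_once <- function(spec, n, seed, gamma1 = 2.5) {
  d <- sim_longdata(spec, n, seed)
  des <- build_pooled_design(d)
  m <- des$index_map
  oracle_cols <- c("tau0:C0", "tau1:C0", "tau1:C1")
  keep <- !des$shrink | (m$col %in% oracle_cols)
  X <- des$X[, keep, drop = FALSE]
  refit <- loalfuse:::restricted_mle(X, des$y, rep(TRUE, ncol(X)))
  names(refit) <- colnames(X)
  graph <- build_fusion_graph(m[m$col %in% oracle_cols, ], "clique")
  w <- fusion_weights(refit, graph, gamma1 = gamma1)
  sel <- select_by_bic(fit_fused(X, des$y, graph, w, start = refit))
  i <- which(graph$nodes$col %in% c("tau0:C0", "tau1:C0"))
  length(unique(sel$member[i])) == 1L
}
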
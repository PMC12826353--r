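active_frame <- function(tau, t, var) {
  data.frame(tau = tau, t = t, k = 1L, var = var, type = "covariate",
             col = paste0("tau", tau, ":", var))
}

test_that("fusion graphs follow the clique, chain, and lag rules", {
  # baseline covariate selected at two times: a single edge
  a2 <- active_frame(c(0, 1), c(0, 0), c("C0", "C0"))
  g <- build_fusion_graph(a2, "clique")
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$nodes$col[g$edges[1, ]], c("tau0:C0", "tau1:C0"))
  # baseline covariate at three times: chain connects successive times only
  a3 <- active_frame(0:2, c(0, 0, 0), rep("B", 3))
  gch <- build_fusion_graph(a3, "chain")
  expect_equal(nrow(gch$edges), 2)
  gcl <- build_fusion_graph(a3, "clique")
  expect_equal(nrow(gcl$edges), 3)
  # lag-1 time-varying coefficients across tau = 3, 4, 5 fuse together
  alag <- active_frame(c(3, 4, 5), c(2, 3, 4), c("D2", "D3", "D4"))
  glag <- build_fusion_graph(alag, "clique",
                             series = c(D2 = "D", D3 = "D", D4 = "D"))
  expect_equal(nrow(glag$edges), 3)
  # an isolated selection is a node without edges, not an error
  giso <- build_fusion_graph(active_frame(1, 1, "C1"), "clique")
  expect_equal(nrow(giso$edges), 0)
  expect_error(build_fusion_graph(a2[0, ], "clique"), "empty")
})

test_that("fusion weights follow the closed form |diff|^(-gamma1)", {
  a2 <- active_frame(c(0, 1), c(0, 0), c("C0", "C0"))
  g <- build_fusion_graph(a2, "clique")
  refit <- c(`tau0:C0` = 1.3, `tau1:C0` = 2.3)
  expect_equal(unname(fusion_weights(refit, g, 2.5)), 1)
  refit2 <- c(`tau0:C0` = 1.0, `tau1:C0` = 1.5)
  expect_equal(unname(fusion_weights(refit2, g, 2.5)), 2^2.5, tolerance = 1e-9)
  refit3 <- c(`tau0:C0` = 0, `tau1:C0` = 2)
  expect_equal(unname(fusion_weights(refit3, g, 1)), 0.5)
  expect_warning(w <- fusion_weights(c(`tau0:C0` = 1, `tau1:C0` = 1), g, 2.5),
                 "capped")
  expect_equal(unname(w), 1e12)
})

test_that("lambda1 limits: unpenalized MLE at zero, shared MLE at infinity", {
  fx <- fused_instance()
  w <- fusion_weights(fx$refit, fx$graph, 2.5)
  pth <- fit_fused(fx$X, fx$y, fx$graph, w, lambda1 = c(0, 1e5),
                   start = fx$refit)
  expect_equal(unname(pth$alphas[[1]]), unname(fx$refit), tolerance = 1e-7)
  # at the fusion limit the two C0 columns share the summed-column MLE
  i <- match(c("tau0:C0", "tau1:C0"), colnames(fx$X))
  Xs <- cbind(rowSums(fx$X[, i]), fx$X[, -i])
  shared <- suppressWarnings(glm.fit(Xs, fx$y, family = binomial()))$coefficients
  a_inf <- pth$alphas[[2]]
  expect_equal(unname(a_inf[i]), rep(unname(shared[1]), 2), tolerance = 1e-7)
})

test_that("fused path solutions match brute force on a tiny instance", {
  set.seed(8)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.7 * x1 + 0.4 * x2))
  X <- cbind(int = 1, x1 = x1, x2 = x2)
  edges <- matrix(c(2L, 3L), 1)
  for (l1 in c(0.4, 2, 8)) {
    f <- loalfuse:::fusedlogit(X, y, edges, pen = l1)
    oracle <- bf_fused_objective(X, y, edges, l1)
    expect_lt(abs(f$objective - oracle), 1e-6)
  }
})

test_that("BIC selection prefers fewer degrees of freedom on ties", {
  fake_path <- structure(list(
    table = data.frame(lambda1 = c(0, 1), df = c(6, 5),
                       loglik = c(-100, -100),
                       bic = c(200 + 6 * log(50), 200 + 5 * log(50)),
                       n_groups = c(2, 1)),
    alphas = list(c(a = 1), c(a = 2)),
    members = list(c(1, 2), c(1, 1))
  ), class = "fused_path")
  sel <- select_by_bic(fake_path)
  expect_equal(sel$lambda1, 1)
  # exact BIC tie: the more fused candidate wins
  fake_path$table$bic <- c(200, 200)
  sel2 <- select_by_bic(fake_path)
  expect_equal(sel2$member, c(1, 1))
})

test_that("fusion preserves the first-step zero pattern (no extra sparsity)", {
  d <- sim_longdata(scenario1_spec("main_terms"), 600, 44)
  fit <- loal(d)
  ff <- fuse(fit)
  shrink <- ff$design$shrink
  cols <- ff$design$index_map$col
  expect_setequal(cols[shrink][ff$alpha_star[shrink] != 0], fit$active$col)
  # fused estimate is nonzero on every selected and protected column
  expect_true(all(ff$alpha_star[!shrink] != 0))
  # degrees of freedom shrink weakly along increasing lambda1 on this fixture
  tab <- ff$fusion$table[ff$fusion$table$gamma1 == ff$gamma1, ]
  tab <- tab[order(tab$lambda1), ]
  expect_true(all(diff(tab$n_groups) <= 0))
})

test_that("covariate relabeling permutes the fused solution accordingly", {
  d <- sim_longdata(scenario1_spec("main_terms"), 400, 55)
  swap <- d
  swap$L[[2]] <- swap$L[[2]][, c(2, 1)]
  f1 <- fuse(loal(d))
  f2 <- fuse(loal(swap))
  expect_equal(f1$alpha_star[sort(names(f1$alpha_star))],
               f2$alpha_star[sort(names(f2$alpha_star))], tolerance = 1e-7)
})
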
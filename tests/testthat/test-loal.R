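# A hand-built working_beta object over a single-time design with two
# covariates, for closed-form weight checks.
toy_beta <- function(b, gamma = 2.5) {
  structure(list(
    beta = list(t0 = c(`(Intercept)` = 0.1, X1 = b[1], X2 = b[2])),
    gamma = gamma,
    table = NULL
  ), class = "working_beta")
}

toy_design <- function(n = 6, X1 = NULL, X2 = NULL, A = NULL) {
  X1 <- X1 %||% c(1, 2, 3, 4, 5, 6)
  X2 <- X2 %||% c(0, 1, 0, 1, 0, 1)
  A <- A %||% c(1, 1, 1, 0, 0, 0)
  d <- longdata(L = list(cbind(X1 = X1, X2 = X2)), A = cbind(A0 = A),
                Y = rnorm(length(X1)))
  list(data = d, design = build_pooled_design(d))
}

test_that("adaptive weights follow the closed form |beta|^(-gamma)", {
  fx <- toy_design()
  w <- adaptive_weights(toy_beta(c(1, 0.5)), fx$design)
  expect_equal(unname(w), c(0, 1, 2^2.5))
  w2 <- adaptive_weights(toy_beta(c(-2, 0.5)), fx$design)
  expect_equal(unname(w2[2]), 2^(-2.5))   # sign is ignored
  expect_equal(unname(w2[2]), 0.1767767, tolerance = 1e-6)
  expect_equal(unname(w[3]), 5.6568542, tolerance = 1e-6)
})

test_that("an exactly-zero working coefficient is capped, not infinite", {
  fx <- toy_design()
  expect_warning(w <- adaptive_weights(toy_beta(c(1, 0)), fx$design),
                 "capped")
  expect_equal(unname(w[3]), 1e12)
})

test_that("balance score equals the hand-computed weighted mean difference", {
  fx <- toy_design()
  # alpha = 0 gives fitted probability 0.5 everywhere; the marginal numerator
  # is also 0.5 (three treated of six), so all weights are exactly one
  alpha <- numeric(3)
  W <- loalfuse:::cumulative_balance_weights(fx$design, alpha)
  expect_equal(unname(W[, 1]), rep(1, 6))
  b <- toy_beta(c(2, 0.5))
  sc <- balance_score(fx$design, alpha, b, fx$data)
  hand <- 2 * abs(mean(c(1, 2, 3)) - mean(c(4, 5, 6))) +
    0.5 * abs(mean(c(0, 1, 0)) - mean(c(1, 0, 1)))
  expect_equal(sc, hand, tolerance = 1e-12)
  # linearity: doubling all |beta| weights doubles the score
  sc2 <- balance_score(fx$design, alpha, toy_beta(c(4, 1)), fx$data)
  expect_equal(sc2, 2 * sc, tolerance = 1e-12)
})

test_that("degenerate fitted probabilities raise a positivity error", {
  fx <- toy_design()
  expect_error(balance_score(fx$design, c(0, 50, 0), toy_beta(c(1, 1)), fx$data),
               "positivity")
})

test_that("ties in the balance score resolve to the largest lambda", {
  fx <- make_path_fixture(n = 150, seed = 23)
  base <- fit_loal_path(fx$design, fx$omega, lambda = 1)
  # duplicate the identical solution at two grid points: an exact score tie
  path <- base
  path$lambda <- c(2, 1)
  path$alpha <- cbind(base$alpha[, 1], base$alpha[, 1])
  path$kkt <- rep(base$kkt, 2)
  path$loglik <- rep(base$loglik, 2)
  sel <- select_lambda_and_refit(path, fx$data, fx$beta)
  expect_identical(sel$lambda_index, 1L)
  expect_equal(sel$balance[1], sel$balance[2])
})

test_that("the refit is nonzero only on the active and protected slots", {
  fit <- loal(sim_longdata(scenario1_spec("main_terms"), 400, 9))
  shrink <- fit$design$shrink
  sel_cols <- fit$design$index_map$col[shrink][fit$refit[shrink] != 0]
  expect_setequal(sel_cols, fit$active$col)
  # selected model retains both confounders' columns
  expect_true(all(c("tau0:C0", "tau1:C1") %in% fit$active$col))
  # refit agrees with glm on the reduced design
  keep <- !shrink | fit$design$index_map$col %in% fit$active$col
  g <- suppressWarnings(glm.fit(fit$design$X[, keep], fit$design$y,
                                family = binomial()))
  expect_equal(unname(fit$refit[keep]), unname(g$coefficients),
               tolerance = 1e-7)
})

test_that("the deterministic n-power tuning rule is available", {
  d <- sim_longdata(scenario1_spec("main_terms"), 300, 12)
  fit <- loal(d, lambda_rule = "n_power", aleph = 0.25)
  expect_equal(fit$lambda, 300^0.25)
  expect_error(loal(d, lambda_rule = "n_power", aleph = 0.7), "below 0.5")
})

test_that("loal on a censoring process reuses the treatment machinery", {
  set.seed(77)
  n <- 300
  Z0 <- rnorm(n); Z1 <- rnorm(n, Z0)
  A0 <- rbinom(n, 1, plogis(0.5 * Z0))
  A1 <- pmax(A0, rbinom(n, 1, plogis(0.2 + 0.4 * Z1)))
  Y <- Z0 + Z1 + A0 + A1 + rnorm(n)
  d_tr <- longdata(L = list(cbind(Z0 = Z0), cbind(Z1 = Z1)),
                   A = cbind(A0, A1), Y = Y)
  d_ce <- longdata(L = list(cbind(Z0 = Z0), cbind(Z1 = Z1)),
                   A = cbind(A0 = rep(0, n), A1 = rep(0, n)),
                   C = cbind(A0, A1), Y = Y)
  qs <- fit_q_sequence(d_tr)
  wb <- working_beta(qs, d_tr)
  f_tr <- loal(d_tr, beta = wb, absorbing = TRUE)
  f_ce <- loal(d_ce, process = "censoring", beta = wb)
  expect_equal(f_tr$refit[f_tr$design$index_map$type != "treatment"],
               f_ce$refit[f_ce$design$index_map$type != "treatment"],
               tolerance = 1e-8)
  expect_identical(f_tr$lambda_index, f_ce$lambda_index)
})

test_that("joint selection minimizes the summed balance metric", {
  fx <- make_path_fixture(n = 250, seed = 33)
  path <- fit_loal_path(fx$design, fx$omega, nlambda = 6)
  solo <- select_lambda_and_refit(path, fx$data, fx$beta)
  both <- select_lambda_and_refit(path, fx$data, fx$beta,
                                  joint = list(path = path, beta = fx$beta))
  # identical processes: the summed criterion selects the same index
  expect_identical(both$lambda_index, solo$lambda_index)
  expect_equal(both$joint$balance, both$balance)
})
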
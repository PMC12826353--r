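test_that("cum counts treated time points", {
  expect_equal(cum_treat(c(0, 0)), 0)
  expect_equal(cum_treat(c(0, 1, 1, 1, 1)), 4)
  expect_equal(cum_treat(c(1, 1)), 2)
  expect_equal(cum_treat(rbind(c(0, 1), c(1, 1))), c(1, 2))
  expect_error(cum_treat(c(0, 2)))
})

test_that("numerator equal to denominator gives unit weights and OLS", {
  d <- discrete_fixture()
  # denominator model A0 ~ L01 is exactly the stabilizing numerator model
  g <- glm(d$A[, 1] ~ d$L[[1]][, "Z"], family = binomial)
  P <- matrix(fitted(g), ncol = 1)
  w <- compute_weights(d, P, L01 = "Z", numerator = "L01")
  expect_equal(unname(w$w), rep(1, d$n), tolerance = 1e-9)
  m_iptw <- msm_iptw(d, w, L01 = "Z")
  ols <- lm(d$Y ~ d$L[[1]][, "Z"] + d$A[, 1])
  expect_equal(unname(coef(m_iptw)), unname(coef(ols)), tolerance = 1e-9)
})

test_that("a hand-computed two-time weight product is reproduced", {
  d <- longdata(L = list(cbind(Z0 = c(0, 0)), cbind(Z1 = c(0, 0))),
                A = rbind(c(1, 1), c(0, 0)), Y = c(1, 2))
  P <- rbind(c(0.5, 0.25), c(0.5, 0.75))
  w <- compute_weights(d, P, numerator = "marginal")
  # numerators 0.5 * 0.5; denominators 0.5 * 0.25 -> weight 2
  expect_equal(unname(w$w[1]), 2)
  expect_equal(unname(w$w[2]), (0.5 * 0.5) / (0.5 * 0.25))
  # uniform rescaling of weights leaves the estimate unchanged
  m1 <- msm_iptw(discrete_fixture(), rep(1, 120), L01 = "Z")
  m2 <- msm_iptw(discrete_fixture(), rep(2, 120), L01 = "Z")
  expect_equal(coef(m1), coef(m2), tolerance = 1e-12)
})

test_that("true-probability stabilized weights average to one", {
  spec <- scenario1_spec("main_terms")
  spec$standardize <- FALSE
  d <- sim_longdata(spec, 20000, 19)
  C0 <- d$L[[1]][, "C0"]; I0 <- d$L[[1]][, "I0"]
  C1 <- d$L[[2]][, "C1"]; I1 <- d$L[[2]][, "I1"]
  P <- cbind(plogis(1.515 * C0 + I0),
             plogis(-0.5 + 0.5 * C0 + 0.25 * C1 + 0.5 * d$A[, 1] + I1))
  w <- compute_weights(d, P, numerator = "marginal")
  mc_sd <- sd(w$w) / sqrt(d$n)
  expect_lt(abs(mean(w$w) - 1), 3 * mc_sd)
  expect_error(compute_weights(d, P * 0 + 1e-15), "positivity")
})

test_that("g-computation recovers an exactly linear counterfactual mean", {
  d <- discrete_fixture(n = 60)
  pat <- treatment_patterns(0)
  qs <- structure(list(
    q = list(matrix(rep(2 * pat[, 1], each = 60), 60),
             matrix(d$Y, 60, 2)),
    patterns = pat, q_terms = "Z", n = 60, Tt = 0
  ), class = "qstack")
  fit <- msm_gcomp(qs, d, L01 = "Z")
  expect_equal(unname(coef(fit)), c(0, 0, 2), tolerance = 1e-10)
})

test_that("saturated models make G-comp, IPTW, and plug-in coincide", {
  d <- discrete_fixture(n = 160, seed = 12)
  Z <- d$L[[1]][, "Z"]; A <- d$A[, 1]; Y <- d$Y
  # saturated q model and saturated treatment model
  qs <- fit_q_sequence(d, q_terms = "Z * A0")
  gc <- msm_gcomp(qs, d, L01 = "Z", interaction = TRUE)
  g <- glm(A ~ Z, family = binomial)  # saturated in binary Z
  w <- compute_weights(d, matrix(fitted(g), ncol = 1), L01 = "Z",
                       numerator = "marginal")
  ipw <- msm_iptw(d, w, L01 = "Z", interaction = TRUE)
  # plug-in nonparametric estimate: cell means determine the saturated MSM
  cell <- function(z, a) mean(Y[Z == z & A == a])
  plug <- c(cell(0, 0), cell(1, 0) - cell(0, 0), cell(0, 1) - cell(0, 0),
            cell(1, 1) - cell(1, 0) - cell(0, 1) + cell(0, 0))
  expect_equal(unname(coef(gc)), plug, tolerance = 1e-9)
  expect_equal(unname(coef(ipw)), plug, tolerance = 1e-9)
})

test_that("sandwich standard errors calibrate against Monte-Carlo spread", {
  spec <- scenario1_spec("main_terms")
  spec$standardize <- FALSE
  R <- 300
  est <- se <- numeric(R)
  for (r in seq_len(R)) {
    d <- sim_longdata(spec, 800, 4000 + r)
    C0 <- d$L[[1]][, "C0"]; I0 <- d$L[[1]][, "I0"]
    C1 <- d$L[[2]][, "C1"]; I1 <- d$L[[2]][, "I1"]
    P <- cbind(plogis(1.515 * C0 + I0),
               plogis(-0.5 + 0.5 * C0 + 0.25 * C1 + 0.5 * d$A[, 1] + I1))
    fit <- msm_iptw(d, compute_weights(d, P))
    est[r] <- coef(fit)["cum"]
    se[r] <- fit$se["cum"]
  }
  expect_lt(abs(sd(est) / mean(se) - 1), 0.15)
})

test_that("g-computation bootstrap and m-out-of-n behave as documented", {
  d <- discrete_fixture(n = 80)
  qs <- fit_q_sequence(d, q_terms = "Z + A0")
  f1 <- msm_gcomp(qs, d, L01 = "Z", se = "bootstrap", B = 30, seed = 2)
  f2 <- msm_gcomp(qs, d, L01 = "Z", se = "bootstrap", B = 30, seed = 2)
  expect_equal(f1$se, f2$se)
  expect_true(all(f1$se > 0))
  # m-out-of-n on the sample mean: fixed seed reproducibility and B = 1
  pipeline <- function(dd) mean(dd$Y)
  set.seed(1); big <- longdata(L = list(cbind(Z = rnorm(2000))),
                               A = cbind(A0 = rbinom(2000, 1, 0.5)),
                               Y = rnorm(2000))
  b1 <- m_out_of_n_bootstrap(pipeline, big, m = 500, B = 400, seed = 3)
  b2 <- m_out_of_n_bootstrap(pipeline, big, m = 500, B = 400, seed = 3)
  expect_equal(b1$lower, b2$lower)
  b3 <- m_out_of_n_bootstrap(pipeline, big, m = 500, B = 1, seed = 4)
  expect_equal(b3$lower, b3$upper, tolerance = 1e-12)
  # closed-form Gaussian case: the rescaled interval width matches
  # 2 * 1.96 * sigma / sqrt(n) within 10%
  width <- b1$upper - b1$lower
  expect_lt(abs(width / (2 * qnorm(0.975) * sd(big$Y) / sqrt(2000)) - 1), 0.1)
  expect_warning(m_out_of_n_bootstrap(pipeline, big, m = 2000, B = 2, seed = 1),
                 "standard bootstrap")
})
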
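test_that("the benchmark scenario encodes the printed treatment process", {
  spec <- scenario1_spec("main_terms")
  tr0 <- spec$treatment[[1]]
  co <- vapply(tr0, `[[`, 0, "coef")
  vars <- lapply(tr0, `[[`, "vars")
  expect_equal(co[vapply(vars, identical, TRUE, "C0")], 1.515)
  expect_equal(co[vapply(vars, identical, TRUE, "I0")], 1)
  tr1 <- spec$treatment[[2]]
  co1 <- vapply(tr1, `[[`, 0, "coef")
  vars1 <- vapply(tr1, function(tm) paste(tm$vars, collapse = ""), "")
  expect_equal(unname(co1[match(c("", "C0", "C1", "A0", "I1"), vars1)]),
               c(-0.5, 0.5, 0.25, 0.5, 1))
  # covariate transitions: C1 mean A0 + C0, I1 mean C0
  c1 <- spec$covariates[[2]][[1]]
  expect_setequal(unlist(lapply(c1$mean, `[[`, "vars")), c("A0", "C0"))
  i1 <- spec$covariates[[2]][[2]]
  expect_equal(unlist(lapply(i1$mean, `[[`, "vars")), "C0")
})

test_that("variant handling: null outcome, effect modification, bad input", {
  null_spec <- scenario1_spec("main_terms",
                              outcome_coefficients = c(C0 = 0, A0 = 0, C1 = 0, A1 = 0))
  expect_s3_class(null_spec, "dgp_spec")
  em <- scenario1_spec("effect_modification")
  pows <- lapply(em$outcome$terms, function(tm)
    if (setequal(tm$vars, c("A0", "C1"))) sort(tm$pow) else NULL)
  expect_true(any(vapply(pows, identical, TRUE, c(1L, 2L))))
  expect_error(scenario1_spec("quadratic"), "arg")
  expect_error(scenario1_spec("main_terms", outcome_coefficients = c(X9 = 1)),
               "unknown outcome coefficient")
  expect_error(dgp_spec(0, list(list(list(name = "B", role = "confounder",
                                          mean = list(lp_term(1, "Zmissing")),
                                          sd = 1))),
                        list(list(lp_term(0))),
                        list(terms = list(lp_term(0)), sd = 1)),
               "not yet generated")
})

test_that("generation is deterministic and standardizes covariates exactly", {
  spec <- scenario1_spec("main_terms")
  d1 <- sim_longdata(spec, 500, 99)
  d2 <- sim_longdata(spec, 500, 99)
  expect_identical(d1, d2)
  d3 <- sim_longdata(spec, 500, 100)
  expect_false(identical(d1$Y, d3$Y))
  for (t in 0:1) {
    M <- d1$L[[t + 1]]
    expect_lt(max(abs(colMeans(M))), 1e-8)
    expect_lt(max(abs(apply(M, 2, sd) - 1)), 1e-8)
  }
  expect_true(all(d1$A %in% c(0, 1)))
  # standardization record allows recovering the raw scale
  expect_setequal(d1$std$variable, c("C0", "I0", "C1", "I1"))
})

test_that("the first-time treatment is balanced on average", {
  # the A0 linear predictor 1.515*C0 + I0 is symmetric about zero
  d <- sim_longdata(scenario1_spec("main_terms"), 2e5, 3)
  mc_sd <- sqrt(0.25 / 2e5)
  expect_lt(abs(mean(d$A[, 1]) - 0.5), 3 * mc_sd)
})

test_that("true MSM parameters: null and exactly linear cases", {
  null_spec <- scenario1_spec("main_terms",
                              outcome_coefficients = c(`(Intercept)` = 0, C0 = 0,
                                                       A0 = 0, C1 = 0, A1 = 0))
  mu <- true_msm_parameters(null_spec, n_mc = 5000, seed = 1)
  expect_lt(max(abs(mu)), 0.1)
  # outcome mean exactly 2*cum(a): mu2 = 2 to machine precision
  lin <- scenario1_spec("main_terms",
                        outcome_coefficients = c(`(Intercept)` = 0, C0 = 0,
                                                 A0 = 2, C1 = 0, A1 = 2))
  mu2 <- true_msm_parameters(lin, n_mc = 4000, seed = 2)
  expect_equal(unname(mu2["mu2"]), 2, tolerance = 1e-10)
})

test_that("counterfactual means agree with an independent forward simulator", {
  spec <- scenario1_spec("main_terms")
  mu_pkg <- true_msm_parameters(spec, n_mc = 2e5, seed = 11)
  oc <- c(`(Intercept)` = 0, C0 = 0.5, A0 = 0.75, C1 = 1, A1 = 1.25)
  mu_hand <- hand_scenario1_counterfactual_mu(oc, 2e5, seed = 202)
  # both are Monte-Carlo estimates of the same projection
  expect_equal(unname(mu_pkg), mu_hand, tolerance = 0.03)
})

test_that("forcing the observed treatments reproduces the factual outcome", {
  spec <- scenario1_spec("covariate_interaction")
  set.seed(5)
  eps <- loalfuse:::draw_noise(spec, 200)
  obs <- loalfuse:::run_sem(spec, 200, eps)
  for (a0 in 0:1) for (a1 in 0:1) {
    cf <- loalfuse:::run_sem(spec, 200, eps, force_A = c(a0, a1))
    match_rows <- obs$A0 == a0 & obs$A1 == a1
    expect_identical(cf$Y[match_rows], obs$Y[match_rows])
  }
})

test_that("wide CSV writer round-trips the data with a JSON sidecar", {
  d <- sim_longdata(scenario1_spec("main_terms"), 25, 1)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, sub("csv$", "json", path))))
  write_longdata(d, path)
  back <- read.csv(path)
  expect_named(back, c("L0_C0", "L0_I0", "A0", "L1_C1", "L1_I1", "A1", "Y"))
  expect_equal(back$L0_C0, unname(d$L[[1]][, "C0"]))
  expect_equal(back$Y, d$Y)
  side <- jsonlite::read_json(sub("csv$", "json", path))
  expect_equal(side$n, 25)
})
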
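## Role lookup from a dgp_spec: covariate name -> role, and measurement time.
spec_roles <- function(spec) {
  out <- list()
  for (t in 0:spec$Tt)
    for (cv in spec$covariates[[t + 1L]])
      out[[cv$name]] <- list(role = cv$role, t = t)
  out
}

## Pooled-design MLE keeping only the given covariate variables (plus the
## always-kept intercept and treatment slots); optionally fusing baseline
## variables' coefficients across model times. Returns the n x (T+1)
## propensity matrix.
reduced_propensity <- function(data, keep_vars, fuse_baseline = FALSE,
                               baseline_vars = character()) {
  design <- build_pooled_design(data)
  m <- design$index_map
  keep <- !design$shrink | m$var %in% keep_vars
  X <- design$X[, keep, drop = FALSE]
  mk <- m[keep, , drop = FALSE]
  if (fuse_baseline && length(baseline_vars)) {
    node_cols <- which(mk$type == "covariate" & mk$var %in% baseline_vars)
    member <- match(mk$var[node_cols], unique(mk$var[node_cols]))
    alpha <- snap_refit(X, design$y, node_cols, member)$alpha
  } else {
    alpha <- restricted_mle(X, design$y, rep(TRUE, ncol(X)))
  }
  eta <- drop(X %*% alpha)
  P <- matrix(NA_real_, data$n, data$Tt + 1L)
  mm <- expit(eta)
  for (r in seq_len(nrow(design$row_map)))
    P[design$row_map$subject[r], design$row_map$tau[r] + 1L] <- mm[r]
  P
}

#' Oracle (truth-informed) IPTW estimators
#'
#' Fits the variable-selection oracle pooled treatment model — confounders
#' only, instruments excluded, no selection step — and its correctly fused
#' variant in which each baseline confounder carries one shared coefficient
#' across all model times, then estimates the MSM by stabilized-weight IPTW.
#' Available only in simulation, where the generating roles are known.
#'
#' @param data a [longdata] object.
#' @param spec the generating [dgp_spec] (identifies confounders and
#'   fusible baseline variables).
#' @param L01 MSM baseline covariate; defaults to the first baseline
#'   confounder.
#' @return List with [msm_iptw] fits \code{oracle_select} and
#'   \code{oracle_select_fuse}.
#' @export
oracle_estimators <- function(data, spec, L01 = NULL) {
  roles <- spec_roles(spec)
  if (is.null(L01)) L01 <- default_L01(spec)
  conf <- names(roles)[vapply(roles, function(r) r$role == "confounder", TRUE)]
  base_conf <- conf[vapply(conf, function(v) roles[[v]]$t == 0L, TRUE)]
  P1 <- reduced_propensity(data, conf)
  P2 <- reduced_propensity(data, conf, fuse_baseline = TRUE,
                           baseline_vars = base_conf)
  list(
    oracle_select = msm_iptw(data, compute_weights(data, P1, L01 = L01)),
    oracle_select_fuse = msm_iptw(data, compute_weights(data, P2, L01 = L01))
  )
}

#' Configuration of a replicated simulation experiment
#'
#' @param spec generating [dgp_spec].
#' @param n vector of sample sizes.
#' @param reps replications per sample size.
#' @param estimators subset of \code{"gcomp_main_terms"}, \code{"iptw_full"},
#'   \code{"iptw_oracle_select"}, \code{"iptw_oracle_select_fuse"},
#'   \code{"loal"}, \code{"fused_loal"}.
#' @param q_terms per-time q-model right-hand sides passed to the estimators
#'   that fit outcome models (deliberate misspecifications welcome); NULL =
#'   main terms.
#' @param base_seed integer; replication seeds derive from it.
#' @param gamma,nlambda LOAL settings.
#' @param gamma1 fusion exponent(s).
#' @param n_mc,mc_seed Monte-Carlo size and seed for the true MSM parameters.
#' @param L01 MSM baseline covariate (default: first baseline confounder).
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(spec, n = c(200L, 500L, 1000L), reps = 200L,
                       estimators = c("gcomp_main_terms", "iptw_full",
                                      "iptw_oracle_select",
                                      "iptw_oracle_select_fuse",
                                      "loal", "fused_loal"),
                       q_terms = NULL, base_seed = 1L, gamma = 2.5,
                       nlambda = 30L, gamma1 = 2.5, n_mc = 2e5,
                       mc_seed = 1234L, L01 = NULL) {
  known <- c("gcomp_main_terms", "iptw_full", "iptw_oracle_select",
             "iptw_oracle_select_fuse", "loal", "fused_loal")
  estimators <- match.arg(estimators, known, several.ok = TRUE)
  stopifnot(inherits(spec, "dgp_spec"), reps >= 1)
  structure(
    list(spec = spec, n = as.integer(n), reps = as.integer(reps),
         estimators = estimators, q_terms = q_terms,
         base_seed = as.integer(base_seed), gamma = gamma,
         nlambda = as.integer(nlambda), gamma1 = gamma1,
         n_mc = n_mc, mc_seed = mc_seed,
         L01 = L01 %||% default_L01(spec)),
    class = "sim_config"
  )
}

run_one <- function(est, data, cfg, roles) {
  out <- list(mu = NULL, selected = NULL, fused = NULL)
  L01 <- cfg$L01
  if (est == "gcomp_main_terms") {
    qs <- fit_q_sequence(data, q_terms = cfg$q_terms)
    out$mu <- coef(msm_gcomp(qs, data, L01 = L01))
  } else if (est == "iptw_full") {
    P <- reduced_propensity(data, names(roles))
    out$mu <- coef(msm_iptw(data, compute_weights(data, P, L01 = L01)))
  } else if (est == "iptw_oracle_select") {
    conf <- names(roles)[vapply(roles, function(r) r$role == "confounder", TRUE)]
    P <- reduced_propensity(data, conf)
    out$mu <- coef(msm_iptw(data, compute_weights(data, P, L01 = L01)))
  } else if (est == "iptw_oracle_select_fuse") {
    conf <- names(roles)[vapply(roles, function(r) r$role == "confounder", TRUE)]
    bc <- conf[vapply(conf, function(v) roles[[v]]$t == 0L, TRUE)]
    P <- reduced_propensity(data, conf, fuse_baseline = TRUE, baseline_vars = bc)
    out$mu <- coef(msm_iptw(data, compute_weights(data, P, L01 = L01)))
  } else if (est %in% c("loal", "fused_loal")) {
    fit <- loal(data, gamma = cfg$gamma, nlambda = cfg$nlambda,
                q_terms = cfg$q_terms)
    m <- fit$design$index_map
    sel <- paste0("tau", m$tau, ":", m$var)[fit$design$shrink]
    out$selected <- stats::setNames(
      m$col[fit$design$shrink] %in% fit$active$col, sel)
    if (est == "fused_loal") {
      ff <- fuse(fit, gamma1 = cfg$gamma1)
      nd <- ff$graph$nodes
      fusable <- unique(nd$identity[duplicated(nd$identity)])
      out$fused <- stats::setNames(
        vapply(fusable, function(id) {
          i <- which(nd$identity == id)
          length(unique(ff$member[i])) == 1L
        }, TRUE), sub("^var:", "", fusable))
      out$mu <- coef(msm_iptw(data, compute_weights(data, ff, L01 = L01)))
    } else {
      out$mu <- coef(msm_iptw(data, compute_weights(data, fit, L01 = L01)))
    }
  }
  out
}

#' Run a replicated estimator-comparison experiment
#'
#' For each sample size and replication: generate data from the configured
#' process, run every configured estimator, record MSM estimates and (for the
#' adaptive methods) selection and fusion indicators; aggregate into
#' scaled-bias/scaled-MSE and proportion tables with Monte-Carlo standard
#' errors. An estimator failure inside a replication is recorded and
#' excluded from aggregation, not raised. Deterministic given the
#' configuration (replication seeds derive from \code{base_seed}).
#'
#' @param config a [sim_config].
#' @return Object of class \code{"results_table"}: \code{estimates} (long,
#'   one row per rep x estimator), \code{performance} (per estimator x n x
#'   coefficient: \code{n_abs_bias} = n |mean bias|, \code{n_mean_abs_bias} =
#'   n mean |bias|, \code{n_mse}, with MC standard errors), \code{selection}
#'   and \code{fusion} proportion tables, \code{true_mu}, \code{failures}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roles <- spec_roles(config$spec)
  true_mu <- true_msm_parameters(config$spec, n_mc = config$n_mc,
                                 seed = config$mc_seed, L01 = config$L01)
  rows <- list(); selrows <- list(); fuserows <- list(); failures <- list()
  for (n in config$n) {
    seeds <- derive_seeds(config$base_seed + n, config$reps)
    for (r in seq_len(config$reps)) {
      data <- sim_longdata(config$spec, n, seeds[r])
      for (est in config$estimators) {
        res <- tryCatch(run_one(est, data, config, roles),
                        error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(n = n, rep = r, estimator = est,
                       message = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1L]] <-
          data.frame(n = n, rep = r, estimator = est,
                     mu0 = res$mu[[1L]], mu1 = res$mu[[2L]], mu2 = res$mu[[3L]])
        if (!is.null(res$selected))
          selrows[[length(selrows) + 1L]] <-
            data.frame(n = n, rep = r, estimator = est,
                       term = names(res$selected),
                       selected = unname(res$selected))
        if (!is.null(res$fused))
          fuserows[[length(fuserows) + 1L]] <-
            data.frame(n = n, rep = r, estimator = est,
                       covariate = names(res$fused), fused = unname(res$fused))
      }
    }
  }
  estimates <- do.call(rbind, rows)
  perf <- do.call(rbind, lapply(split(
    estimates, list(estimates$estimator, estimates$n), drop = TRUE),
    function(d) {
      do.call(rbind, lapply(1:3, function(k) {
        err <- d[[paste0("mu", k - 1L)]] - true_mu[k]
        n <- d$n[1L]; R <- nrow(d)
        data.frame(estimator = d$estimator[1L], n = n,
                   coefficient = paste0("mu", k - 1L),
                   n_abs_bias = n * abs(mean(err)),
                   n_mean_abs_bias = n * mean(abs(err)),
                   n_mse = n * mean(err^2),
                   mc_se_bias = n * stats::sd(err) / sqrt(R),
                   mc_se_mse = n * stats::sd(err^2) / sqrt(R),
                   reps = R)
      }))
    }))
  rownames(perf) <- NULL
  agg_prop <- function(lst, key, val) {
    if (!length(lst)) return(NULL)
    d <- do.call(rbind, lst)
    out <- do.call(rbind, lapply(
      split(d, list(d$estimator, d$n, d[[key]]), drop = TRUE),
      function(s) {
        p <- mean(s[[val]])
        data.frame(estimator = s$estimator[1L], n = s$n[1L],
                   term = s[[key]][1L], proportion = p,
                   mc_se = sqrt(p * (1 - p) / nrow(s)), reps = nrow(s))
      }))
    rownames(out) <- NULL
    out
  }
  structure(
    list(estimates = estimates,
         performance = perf,
         selection = agg_prop(selrows, "term", "selected"),
         fusion = agg_prop(fuserows, "covariate", "fused"),
         true_mu = true_mu,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         config = config),
    class = "results_table"
  )
}

#' @export
print.results_table <- function(x, ...) {
  cat("Simulation results (true mu =",
      paste(round(x$true_mu, 3), collapse = ", "), ")\n\n")
  cat("Performance (n x |bias|, n x MSE):\n")
  print(x$performance, row.names = FALSE, digits = 3)
  if (!is.null(x$selection)) {
    cat("\nSelection proportions:\n")
    print(x$selection, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$fusion)) {
    cat("\nFusion proportions:\n")
    print(x$fusion, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$failures))
    cat("\nFailed replications:", nrow(x$failures), "\n")
  invisible(x)
}
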
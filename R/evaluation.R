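#' @name design_evaluation
#' @title Evaluating sparse sampling designs
#'
#' @description
#' Two complementary routes quantify how precisely a windowed sparse design
#' can estimate the structural PK parameters: the expected first-order (FO)
#' population Fisher information matrix, whose inverse bounds the estimator
#' covariance, and empirical simulation/re-estimation with the pooled
#' estimator.  Both work on the log-parameter scale, so a diagonal element of
#' the inverse information is directly the squared relative standard error
#' and `%RSE = 100 * sqrt(diag(FIM^-1))`.
NULL

default_estimated <- function() c("cl", "clm1", "v2", "clm", "v4", "ka")

# prediction of log concentrations for one subject: adult-referenced theta,
# allometric tying by weight, single oral dose, both analytes at the
# requested times; returns list(log_pred, keep) where keep marks rows with a
# positive prediction (pre-lag samples carry no information)
subject_logpred <- function(theta, weight, amt, times, cmt,
                            allometric = TRUE, floor = 1e-12,
                            grid = NULL, idx = NULL) {
  p <- unclass(theta)
  if (allometric) p <- scale_plist(p, weight)
  if (is.null(grid)) {
    grid <- sort(unique(times))
    idx <- match(times, grid)
  }
  cc <- solve_conc(p, amt, grid)
  conc <- cc$can[idx]
  sp <- cmt == 2
  conc[sp] <- cc$spir[idx[sp]]
  keep <- conc > floor
  list(log_pred = log(pmax(conc, floor)), keep = keep)
}

perturb_params <- function(params, name, factor) {
  p <- unclass(params)
  p[[name]] <- p[[name]] * factor
  p
}

# central finite-difference derivatives of log-prediction w.r.t. the log of
# each named parameter (multiplicative perturbation), rows = observations
logpred_jacobian <- function(params, names, weight, amt, times, cmt,
                             allometric = TRUE, h = 1e-4) {
  sapply(names, function(nm) {
    up <- subject_logpred(perturb_params(params, nm, exp(h)), weight, amt,
                          times, cmt, allometric)$log_pred
    dn <- subject_logpred(perturb_params(params, nm, exp(-h)), weight, amt,
                          times, cmt, allometric)$log_pred
    (up - dn) / (2 * h)
  })
}

omega_matrix <- function(spec) {
  nm <- names(spec$omega2)
  om <- diag(spec$omega2, nrow = length(nm))
  dimnames(om) <- list(nm, nm)
  if (all(c("cl", "v2") %in% nm)) {
    om["cl", "v2"] <- om["v2", "cl"] <- spec$cov_cl_v2
  }
  om
}

#' Expected %RSE of a sparse design by FO population Fisher information
#'
#' For each subject the model is linearized around zero random effects: on
#' the log-concentration scale the observation covariance is
#' `V = G Omega G' + diag(eps)` with `G` the sensitivities to the
#' between-subject effects and `eps` the analyte residual variance, and the
#' fixed-effect information contribution is `J' V^-1 J` with `J` the
#' sensitivities to the estimated log-parameters.  Subjects are independent
#' so contributions add; `%RSE = 100 * sqrt(diag(FIM^-1))`.
#'
#' @param design a design list: one element per subject with fields `weight`
#'   (kg), `amt` (mg) and `times` (h), e.g. from [design_from_schemes()].
#' @param typical adult-referenced typical `pk_params`.
#' @param spec a [variability_spec()].
#' @param estimated names of the estimated structural parameters.
#' @param allometric tie subjects to the adult scale by weight?
#' @return A `design_evaluation` list: `rse` (named %RSE vector), `fim`,
#'   `method = "FIM"`, `n_subjects`, `n_obs`.
#' @export
expected_rse_fim <- function(design, typical = adult_params(),
                             spec = variability_spec(),
                             estimated = default_estimated(),
                             allometric = TRUE) {
  om <- omega_matrix(spec)
  bsv_names <- names(spec$omega2)
  np <- length(estimated)
  fim <- matrix(0, np, np, dimnames = list(estimated, estimated))
  n_obs <- 0L
  for (s in design) {
    times <- rep(s$times, 2)
    cmt <- rep(c(2L, 4L), each = length(s$times))
    base <- subject_logpred(typical, s$weight, s$amt, times, cmt, allometric)
    keep <- base$keep
    if (!any(keep)) next
    jac <- logpred_jacobian(typical, estimated, s$weight, s$amt, times, cmt,
                            allometric)[keep, , drop = FALSE]
    # eta sensitivities act on the subject-level (scaled) parameters
    p_i <- if (allometric) scale_parameters(typical, s$weight) else typical
    g <- logpred_jacobian(p_i, bsv_names, s$weight, s$amt, times, cmt,
                          allometric = FALSE)[keep, , drop = FALSE]
    eps <- ifelse(cmt[keep] == 2, spec$eps1, spec$eps2)
    v <- g %*% om %*% t(g) + diag(eps, nrow = sum(keep))
    fim <- fim + t(jac) %*% solve(v, jac)
    n_obs <- n_obs + sum(keep)
  }
  if (n_obs < np) stop("design has fewer informative observations (",
                       n_obs, ") than estimated parameters (", np, ")")
  ev <- eigen(fim, symmetric = TRUE)
  if (min(ev$values) < max(ev$values) * 1e-10) {
    dir <- estimated[which.max(abs(ev$vectors[, np]))]
    stop("singular information matrix; weakest direction involves '", dir,
         "' (eigenvalue ratio ", format(min(ev$values) / max(ev$values)), ")")
  }
  rse <- 100 * sqrt(diag(solve(fim)))
  structure(list(rse = rse, fim = fim, method = "FIM",
                 n_subjects = length(design), n_obs = n_obs),
            class = "design_evaluation")
}

#' Materialize a subject-level design from sampling schemes
#'
#' Assigns each cohort subject to its age group, randomizes 1:1 to the two
#' subgroups, and draws one sampling time per window.
#'
#' @param cohort subjects from [build_cohort()] or [design_cohort()].
#' @param dose_mg_per_kg dose, mg/kg.
#' @param schemes scheme list (default [builtin_schemes()]).
#' @return A design list usable by [expected_rse_fim()].
#' @export
design_from_schemes <- function(cohort, dose_mg_per_kg = 0.5,
                                schemes = builtin_schemes()) {
  groups <- vapply(cohort, function(s) age_to_group(s$age), integer(1))
  sub <- character(length(cohort))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    perm <- sample(idx)
    half <- ceiling(length(perm) / 2)
    sub[perm[seq_len(half)]] <- paste0(g, ".1")
    sub[perm[-seq_len(half)]] <- paste0(g, ".2")
  }
  lapply(seq_along(cohort), function(i) {
    list(weight = cohort[[i]]$weight,
         amt = dose_mg_per_kg * cohort[[i]]$weight,
         times = draw_sampling_times(schemes[[sub[i]]]))
  })
}

#' Pooled estimation of structural parameters from a PK dataset
#'
#' Weight-aware pooled nonlinear least squares on log concentrations: all
#' subjects are tied to adult-referenced parameters through fixed-exponent
#' allometry (disable with `allometric = FALSE` for adult data, where weight
#' is not a model covariate), and the estimated parameters are optimized on
#' the log scale.  Between-subject variability is absorbed as additional
#' log-scale variance inflation: each observation is weighted by the inverse
#' of `eps + g' Omega g` with `g` the eta-sensitivities at the initial
#' estimate (a first-order approximation, not a mixed-effects fit).
#' Non-convergence triggers up to 3 restarts from multiplicatively perturbed
#' initials (CV 20%).
#'
#' @param dataset an `nm_dataset` (single oral dose per subject).
#' @param init initial/typical `pk_params` (also supplies the fixed
#'   parameters).
#' @param estimated names of estimated parameters.
#' @param spec a [variability_spec()] used for the weighting; `NULL` for
#'   unweighted.
#' @param truth optional `pk_params` for %bias reporting.
#' @param allometric tie subjects by weight (WT column)?
#' @return A `pooled_fit` list: `estimates` (a `pk_params`), `table`
#'   (parameter, init, estimate, pct_rse, pct_bias), `converged`,
#'   `n_obs`, `objective`.
#' @export
fit_pooled <- function(dataset, init = adult_params(),
                       estimated = default_estimated(),
                       spec = variability_spec(), truth = NULL,
                       allometric = TRUE) {
  subj <- split(as.data.frame(dataset), dataset$ID)
  data_list <- lapply(subj, function(d) {
    dose <- d[d$EVID == 1, ][1, ]
    obs <- d[d$EVID == 0 & !is.na(d$DV) & d$DV > 0, ]
    times <- obs$TIME - dose$TIME
    grid <- sort(unique(times))
    list(weight = if ("WT" %in% names(d)) dose$WT else 70,
         amt = dose$AMT, t0 = dose$TIME,
         times = times, cmt = obs$CMT, dv = obs$DV,
         grid = grid, idx = match(times, grid), log_dv = log(obs$DV))
  })
  data_list <- Filter(function(s) length(s$times) > 0, data_list)

  # FO whitening: each subject's log-scale covariance V = G Omega G' +
  # diag(eps) (all observations of a subject share one eta draw, so V has
  # off-diagonal structure); residuals are premultiplied by inv(chol(V))'
  # computed once at the initial estimate
  whiteners <- lapply(data_list, function(s) {
    n <- length(s$times)
    if (is.null(spec)) return(diag(n))
    p_i <- if (allometric) scale_plist(unclass(init), s$weight) else
      unclass(init)
    g <- logpred_jacobian(p_i, names(spec$omega2), s$weight, s$amt,
                          s$times, s$cmt, allometric = FALSE)
    om <- omega_matrix(spec)
    eps <- ifelse(s$cmt == 2, spec$eps1, spec$eps2)
    v <- g %*% om %*% t(g) + diag(eps + 1e-8, nrow = n)  # ridge keeps chol
    chol(v)   # upper-triangular U with V = U'U           # well-posed at eps=0
  })

  # second-order mean correction: with eta ~ N(0, Omega) the marginal mean
  # of log f is approximately log f(0) + tr(Omega H)/2 (H the eta-Hessian of
  # log f), and E log(1 + eps) is approximately -eps/2; both frozen at the
  # initial estimate.  Without this the pooled fit is biased for parameters
  # with large BSV curvature (notably v2 and ka).
  corrections <- lapply(data_list, function(s) {
    n <- length(s$times)
    if (is.null(spec)) return(numeric(n))
    p_i <- if (allometric) scale_plist(unclass(init), s$weight) else
      unclass(init)
    lp <- function(p) subject_logpred(p, s$weight, s$amt, s$times, s$cmt,
                                      allometric = FALSE, grid = s$grid,
                                      idx = s$idx)$log_pred
    h <- 1e-3
    base <- lp(p_i)
    tr <- numeric(n)
    for (k in names(spec$omega2)) {
      if (spec$omega2[[k]] == 0) next
      hkk <- (lp(perturb_params(p_i, k, exp(h))) - 2 * base +
                lp(perturb_params(p_i, k, exp(-h)))) / h^2
      tr <- tr + spec$omega2[[k]] * hkk
    }
    if (spec$cov_cl_v2 != 0) {
      pp <- function(f1, f2) perturb_params(perturb_params(p_i, "cl", f1),
                                            "v2", f2)
      hx <- (lp(pp(exp(h), exp(h))) - lp(pp(exp(h), exp(-h))) -
               lp(pp(exp(-h), exp(h))) + lp(pp(exp(-h), exp(-h)))) / (4 * h^2)
      tr <- tr + 2 * spec$cov_cl_v2 * hx
    }
    eps <- ifelse(s$cmt == 2, spec$eps1, spec$eps2)
    tr / 2 - eps / 2
  })

  resid_vec <- function(logtheta, params0) {
    theta <- unclass(params0)
    theta[estimated] <- as.list(exp(logtheta))
    unlist(lapply(seq_along(data_list), function(i) {
      s <- data_list[[i]]
      lp <- subject_logpred(theta, s$weight, s$amt, s$times, s$cmt,
                            allometric, grid = s$grid, idx = s$idx)
      r <- s$log_dv - (lp$log_pred + corrections[[i]])
      r[!lp$keep] <- 0
      backsolve(whiteners[[i]], r, transpose = TRUE)
    }))
  }
  start <- log(unlist(unclass(init)[estimated]))
  run_lm <- function(s0) {
    ft <- minpack.lm::nls.lm(par = s0, fn = resid_vec, params0 = init,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-10, ptol = 1e-8))
    list(par = ft$par, objective = ft$deviance,
         converged = ft$info %in% 1:3)
  }
  fit <- run_lm(start)
  tries <- 0
  while (!fit$converged && tries < 3) {
    tries <- tries + 1
    start2 <- start + stats::rnorm(length(start), 0, 0.2)
    fit2 <- run_lm(start2)
    if (fit2$converged || fit2$objective < fit$objective) fit <- fit2
  }

  est_log <- fit$par
  p <- unclass(init)
  p[estimated] <- as.list(exp(est_log))
  est <- do.call(pk_params, p)

  # asymptotic covariance on the log scale from the weighted Jacobian
  h <- 1e-4
  r0 <- resid_vec(est_log, init)
  jac <- sapply(seq_along(est_log), function(k) {
    up <- est_log; up[k] <- up[k] + h
    dn <- est_log; dn[k] <- dn[k] - h
    (resid_vec(up, init) - resid_vec(dn, init)) / (2 * h)
  })
  n_obs <- length(r0)
  dof <- max(n_obs - length(est_log), 1)
  sigma2 <- sum(r0^2) / dof
  xtx <- crossprod(jac)
  cv <- tryCatch(sigma2 * solve(xtx), error = function(e) NULL)
  pct_rse <- if (is.null(cv)) rep(NA_real_, length(est_log)) else
    100 * sqrt(pmax(diag(cv), 0))

  tab <- data.frame(
    parameter = estimated,
    init = unlist(unclass(init)[estimated]),
    estimate = exp(est_log),
    pct_rse = pct_rse)
  if (!is.null(truth)) {
    tv <- unlist(unclass(truth)[estimated])
    tab$truth <- tv
    tab$pct_bias <- 100 * (tab$estimate - tv) / tv
  }
  rownames(tab) <- NULL
  structure(list(estimates = est, table = tab,
                 converged = fit$converged, n_obs = n_obs,
                 objective = fit$objective),
            class = "pooled_fit")
}

#' Empirical design evaluation by simulation and re-estimation
#'
#' Repeatedly simulates the sparse study (fresh cohort, sampling times and
#' residual noise each replicate), refits the pooled estimator, and reports
#' the empirical `%RSE = 100 * sd(estimate) / truth` per parameter along
#' with median %bias and the convergence fraction.
#'
#' @param n_replicates number of simulate/fit replicates (>= 20).
#' @param typical adult-referenced truth `pk_params`.
#' @param spec a [variability_spec()].
#' @param estimated estimated parameter names.
#' @param n_per_group subjects per age group.
#' @param dose_mg_per_kg dose, mg/kg.
#' @param schemes scheme list.
#' @return A `design_evaluation` list: `rse`, `median_bias`, `estimates`
#'   (replicate x parameter matrix), `convergence_fraction`,
#'   `method = "sim-reestimation"`.
#' @export
evaluate_design <- function(n_replicates = 100, typical = adult_params(),
                            spec = variability_spec(),
                            estimated = default_estimated(),
                            n_per_group = 6, dose_mg_per_kg = 0.5,
                            schemes = builtin_schemes()) {
  if (n_replicates < 20 && !(spec$eps1 == 0 && spec$eps2 == 0)) {
    stop("n_replicates must be >= 20")
  }
  truth <- unlist(unclass(typical)[estimated])
  est <- matrix(NA_real_, n_replicates, length(estimated),
                dimnames = list(NULL, estimated))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cohort <- design_cohort(n_per_group, spec = spec)
    ds <- simulate_sparse_study(cohort, dose_mg_per_kg, schemes, spec)
    ft <- fit_pooled(ds, init = typical, estimated = estimated, spec = spec)
    est[r, ] <- ft$table$estimate
    conv[r] <- ft$converged
  }
  if (mean(conv) < 0.5) {
    stop("more than half the replicates failed to converge (",
         sum(!conv), "/", n_replicates, ")")
  }
  ok <- conv
  rse <- 100 * apply(est[ok, , drop = FALSE], 2, stats::sd) / truth
  bias <- 100 * (apply(est[ok, , drop = FALSE], 2, stats::median) - truth) /
    truth
  structure(list(rse = rse, median_bias = bias, estimates = est,
                 convergence_fraction = mean(conv),
                 method = "sim-reestimation",
                 n_subjects = 3 * n_per_group, n_replicates = n_replicates),
            class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, ...) {
  cat("Design evaluation (", x$method, "), ", x$n_subjects, " subjects\n",
      sep = "")
  print(round(x$rse, 2))
  invisible(x)
}
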
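#' Specification of a synthetic adult phase-I study
#'
#' Describes the single-dose adult studies used to build the model: arms of
#' richly sampled healthy adults at 25 or 100 mg of the oral suspension, with
#' body weights drawn from the pooled demographic moments (mean 64.1 kg, SD
#' 6.4 kg, truncated above 40 kg).  The default arms (14 at 25 mg + 78 at
#' 100 mg, fasted) reproduce the 92 analyzed subjects.  The rich sampling
#' grid spans absorption through the metabolite terminal phase.
#'
#' @param arms data.frame with columns `n`, `dose_mg`, `fed`.
#' @param times rich sampling times, h.
#' @param weight_mean,weight_sd,weight_min weight distribution, kg.
#' @return A `study_spec` list.
#' @export
study_spec <- function(arms = data.frame(n = c(14, 78), dose_mg = c(25, 100),
                                         fed = c(FALSE, FALSE)),
                       times = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12,
                                 24, 48, 72, 96, 120),
                       weight_mean = 64.1, weight_sd = 6.4,
                       weight_min = 40) {
  if (any(arms$n <= 0)) stop("arm sizes must be > 0")
  if (any(diff(times) <= 0)) stop("sampling times must be increasing")
  structure(list(arms = arms, times = times, weight_mean = weight_mean,
                 weight_sd = weight_sd, weight_min = weight_min),
            class = "study_spec")
}

draw_weights <- function(n, spec) {
  w <- numeric(0)
  while (length(w) < n) {
    cand <- stats::rnorm(n, spec$weight_mean, spec$weight_sd)
    w <- c(w, cand[cand > spec$weight_min])
  }
  w[seq_len(n)]
}

adult_subject_rows <- function(id, wt, dose_mg, params, times, vspec,
                               t_offset = 0, fed = FALSE) {
  prof <- solve_profile(params, dose_events(0, dose_mg), times)
  obs <- apply_residual(prof, vspec)
  dose_row <- data.frame(ID = id, TIME = t_offset, AMT = dose_mg,
                         DV = NA_real_, CMT = 1L, EVID = 1L, MDV = 1L,
                         WT = wt, FED = as.integer(fed))
  obs_rows <- data.frame(ID = id, TIME = t_offset + rep(times, 2),
                         AMT = NA_real_, DV = c(obs$spir, obs$can),
                         CMT = rep(c(2L, 4L), each = length(times)),
                         EVID = 0L, MDV = 0L, WT = wt, FED = as.integer(fed))
  obs_rows <- obs_rows[order(obs_rows$TIME, obs_rows$CMT), ]
  rbind(dose_row, obs_rows)
}

generate_adult_study_full <- function(spec = study_spec(),
                                      typical = adult_params(),
                                      vspec = variability_spec()) {
  n_total <- sum(spec$arms$n)
  wt <- draw_weights(n_total, spec)
  eta <- sample_eta(n_total, vspec)
  rows <- list()
  id <- 0L
  subjects <- list()
  for (a in seq_len(nrow(spec$arms))) {
    scen <- scenario_spec(fed = isTRUE(spec$arms$fed[a]))
    for (k in seq_len(spec$arms$n[a])) {
      id <- id + 1L
      indiv <- apply_eta(typical, eta[id, ])
      p <- apply_scenario(indiv, scen)
      rows[[id]] <- adult_subject_rows(id, wt[id], spec$arms$dose_mg[a], p,
                                       spec$times, vspec,
                                       fed = isTRUE(spec$arms$fed[a]))
      subjects[[id]] <- list(id = id, weight = wt[id],
                             dose_mg = spec$arms$dose_mg[a], params = indiv)
    }
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  ds <- structure(ds, class = c("nm_dataset", "data.frame"))
  validate_nm_dataset(ds)
  list(dataset = ds, eta = eta, subjects = subjects, typical = typical,
       vspec = vspec)
}

#' Generate a synthetic adult single-dose study
#'
#' Stand-in for the (proprietary) adult phase-I concentration data: each
#' subject receives one oral dose, individual parameters are drawn from the
#' log-normal BSV distribution, profiles are solved at the rich grid, and
#' proportional residual error is added per analyte.  The adult model carries
#' no weight covariate; weights are drawn only as realistic covariate
#' columns.
#'
#' @param spec a [study_spec()].
#' @param typical typical adult `pk_params`.
#' @param vspec a [variability_spec()].
#' @return An `nm_dataset` with columns `ID, TIME, AMT, DV, CMT, EVID, MDV,
#'   WT, FED`.
#' @export
generate_adult_study <- function(spec = study_spec(),
                                 typical = adult_params(),
                                 vspec = variability_spec()) {
  generate_adult_study_full(spec, typical, vspec)$dataset
}

#' Generate a synthetic crossover food-effect arm
#'
#' Paired fasted/fed periods for `n` subjects at one dose: each subject keeps
#' the same between-subject random effects in both periods, and the fed
#' period applies the food-effect modifiers (slowed absorption, doubled
#' bioavailability, reduced fraction metabolized).  The fed period is offset
#' by a washout so times remain non-decreasing within subject.
#'
#' @param n number of completing subjects (default 23).
#' @param dose_mg dose per period, mg.
#' @param typical typical adult `pk_params`.
#' @param vspec a [variability_spec()].
#' @param spec a [study_spec()] (for times and weights).
#' @param washout_h gap between period doses, h.
#' @return An `nm_dataset` with a `FED` period indicator.
#' @export
generate_fed_arm <- function(n = 23, dose_mg = 100,
                             typical = adult_params(),
                             vspec = variability_spec(),
                             spec = study_spec(), washout_h = 336) {
  wt <- draw_weights(n, spec)
  eta <- sample_eta(n, vspec)
  fed_scen <- scenario_spec(fed = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    indiv <- apply_eta(typical, eta[i, ])
    fasted <- adult_subject_rows(i, wt[i], dose_mg, indiv, spec$times, vspec)
    fedp <- apply_scenario(indiv, fed_scen)
    fed <- adult_subject_rows(i, wt[i], dose_mg, fedp, spec$times, vspec,
                              t_offset = washout_h, fed = TRUE)
    rbind(fasted, fed)
  })
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  ds <- structure(ds, class = c("nm_dataset", "data.frame"))
  validate_nm_dataset(ds)
  ds
}

#' Synthetic study with exposed ground truth
#'
#' Same generator as [generate_adult_study()] but returning the latent values
#' that produced the data, for parameter-recovery experiments.
#'
#' @inheritParams generate_adult_study
#' @return A list: `dataset`, `typical` (generating `pk_params`), `eta`
#'   (subject x parameter matrix of log-scale random effects), `subjects`
#'   (per-subject weight, dose and individual parameters).
#' @export
truth_bundle <- function(spec = study_spec(), typical = adult_params(),
                         vspec = variability_spec()) {
  full <- generate_adult_study_full(spec, typical, vspec)
  full[c("dataset", "typical", "eta", "subjects")]
}
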
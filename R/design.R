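#' Built-in windowed sparse sampling schemes
#'
#' The six age-group/subgroup schemes of the proposed pediatric PK study.
#' Three age groups (1: 12 to <17 y, 2: 6 to <12 y, 3: 2 to <6 y); within
#' each group subjects are randomized 1:1 to one of two interleaved day-1
#' window sets, and every subject contributes one additional sample in each
#' of the late windows 46-50 h and 166-170 h.  Group 1 takes 4 day-1 samples
#' (6 total per subject); groups 2 and 3 take 3 (5 total).
#'
#' @return A named list of `sampling_scheme` objects (`"1.1"`, `"1.2"`,
#'   `"2.1"`, `"2.2"`, `"3.1"`, `"3.2"`), each with fields `group`,
#'   `subgroup`, `day1_windows` (2-column matrix, h), `late_windows`,
#'   `n_samples`.
#' @export
builtin_schemes <- function() {
  win <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                              dimnames = list(NULL, c("start", "end")))
  late <- win(46, 50, 166, 170)
  day1 <- list(
    "1.1" = win(0.08, 0.5, 1, 1.5, 2, 3, 4, 6),
    "1.2" = win(0.5, 1, 1.5, 2, 3, 4, 6, 8),
    "2.1" = win(0.08, 0.75, 1.5, 2.5, 3.5, 6),
    "2.2" = win(0.75, 1.5, 2.5, 3.5, 6, 8),
    "3.1" = win(0.08, 0.75, 1.5, 2.5, 3.5, 6),
    "3.2" = win(0.75, 1.5, 2.5, 3.5, 6, 8))
  out <- lapply(names(day1), function(id) {
    grp <- as.integer(substr(id, 1, 1))
    sc <- structure(list(group = grp, subgroup = id,
                         day1_windows = day1[[id]], late_windows = late,
                         n_samples = nrow(day1[[id]]) + nrow(late)),
                    class = "sampling_scheme")
    validate_scheme(sc)
    sc
  })
  names(out) <- names(day1)
  out
}

validate_scheme <- function(sc) {
  w <- rbind(sc$day1_windows, sc$late_windows)
  if (any(w[, 2] <= w[, 1])) stop("sampling windows must have end > start")
  if (any(diff(as.vector(t(w))) < 0)) {
    stop("sampling windows must be non-overlapping and increasing")
  }
  expected <- if (sc$group == 1) 4L else 3L
  if (nrow(sc$day1_windows) != expected) {
    stop("group ", sc$group, " must have ", expected, " day-1 windows")
  }
  invisible(sc)
}

age_to_group <- function(age) {
  if (age >= 12 && age <= 17) 1L
  else if (age >= 6) 2L
  else if (age >= 2) 3L
  else stop("age ", age, " outside the 2 to <17 year study range")
}

#' Draw one sampling time per window
#'
#' One uniform draw inside each window of the scheme (day-1 windows then late
#' windows), returned sorted.
#'
#' @param scheme a `sampling_scheme` from [builtin_schemes()].
#' @return Numeric vector of sampling times, h.
#' @export
draw_sampling_times <- function(scheme) {
  w <- rbind(scheme$day1_windows, scheme$late_windows)
  sort(stats::runif(nrow(w), w[, 1], w[, 2]))
}

#' Simulate a sparse windowed pediatric PK study
#'
#' Each cohort subject is assigned to an age group by age, block-randomized
#' 1:1 to one of the group's two sampling subgroups, dosed at `dose_mg_per_kg
#' * weight` mg, sampled at one uniformly drawn time per window, and both
#' analytes are observed at every drawn time with proportional residual
#' error.
#'
#' @param cohort subjects from [build_cohort()].
#' @param dose_mg_per_kg single oral dose, mg/kg.
#' @param schemes scheme list (default [builtin_schemes()]).
#' @param spec a [variability_spec()] supplying the residual variances
#'   (BSV is already in the cohort's individual parameters).
#' @param scenario optional [scenario_spec()] applied to each subject.
#' @return An `nm_dataset` data.frame (see [read_nm_dataset()]): columns
#'   `ID, TIME, AMT, DV, CMT, EVID, MDV, WT, AGE, SEX, SUBGROUP`.  `CMT` is
#'   1 for the depot dose record, 2 for SPIR and 4 for CAN observations.
#' @export
simulate_sparse_study <- function(cohort, dose_mg_per_kg = 0.5,
                                  schemes = builtin_schemes(),
                                  spec = variability_spec(),
                                  scenario = scenario_spec()) {
  groups <- vapply(cohort, function(s) age_to_group(s$age), integer(1))
  subgroup <- character(length(cohort))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    # block 1:1 randomization within group (permute, alternate halves)
    perm <- sample(idx)
    half <- ceiling(length(perm) / 2)
    subgroup[perm[seq_len(half)]] <- paste0(g, ".1")
    subgroup[perm[-seq_len(half)]] <- paste0(g, ".2")
  }

  rows <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    sc <- schemes[[subgroup[i]]]
    amt <- dose_mg_per_kg * s$weight
    tt <- draw_sampling_times(sc)
    p <- apply_scenario(s$params, scenario)
    prof <- solve_profile(p, dose_events(0, amt), tt)
    obs <- apply_residual(prof, spec)
    sexn <- if (s$sex == "F") 2L else 1L
    dose_row <- data.frame(ID = s$id, TIME = 0, AMT = amt, DV = NA_real_,
                           CMT = 1L, EVID = 1L, MDV = 1L, WT = s$weight,
                           AGE = s$age, SEX = sexn, SUBGROUP = subgroup[i])
    obs_rows <- data.frame(
      ID = s$id, TIME = rep(tt, 2), AMT = NA_real_,
      DV = c(obs$spir, obs$can), CMT = rep(c(2L, 4L), each = length(tt)),
      EVID = 0L, MDV = 0L, WT = s$weight, AGE = s$age, SEX = sexn,
      SUBGROUP = subgroup[i])
    obs_rows <- obs_rows[order(obs_rows$TIME, obs_rows$CMT), ]
    rbind(dose_row, obs_rows)
  })
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  validate_nm_dataset(ds)
  structure(ds, class = c("nm_dataset", "data.frame"))
}

#' Default cohort for the sparse-design study
#'
#' Three age groups of `n_per_group` subjects each (balanced sexes) at the
#' reference ages 12, 6 and 2 years for groups 1-3, using the default median
#' weights and adult variability.
#'
#' @param n_per_group subjects per age group (default 6, the proposed study
#'   size).
#' @param spec a [variability_spec()].
#' @return A cohort list (see [build_cohort()]).
#' @export
design_cohort <- function(n_per_group = 6, spec = variability_spec()) {
  if (n_per_group %% 2 != 0) stop("n_per_group must be even for 1:1 blocks")
  build_cohort(n_per_group / 2, ages = c(2, 6, 12), spec = spec)
}
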
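#' Noncompartmental analysis of a single concentration-time course
#'
#' Linear-up/log-down trapezoidal `AUC_last`; terminal slope `lambda_z` by
#' log-linear regression over the candidate terminal window (>= 3 positive
#' points after and excluding Cmax) that maximizes adjusted R-squared;
#' `AUC_inf = AUC_last + C_last / lambda_z`.  When no acceptable terminal fit
#' exists (fewer than 3 positive terminal points, or a non-negative slope),
#' `lambda_z` and `auc_inf` are `NA`.
#'
#' @param time sampling times, h (strictly increasing).
#' @param conc concentrations, mg/L (>= 0).
#' @return A one-row data.frame: `auc_last`, `auc_inf`, `cmax`, `tmax`,
#'   `lambda_z`.
#' @export
nca <- function(time, conc) {
  if (length(time) != length(conc)) stop("time/conc length mismatch")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  n <- length(time)
  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- time[imax]

  auc_last <- 0
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      dt <- time[i + 1] - time[i]
      c1 <- conc[i]; c2 <- conc[i + 1]
      auc_last <- auc_last +
        if (c2 < c1 && c2 > 0) dt * (c1 - c2) / log(c1 / c2)  # log-down
        else dt * (c1 + c2) / 2                               # linear
    }
  }

  lz <- nca_lambda_z(time, conc, imax)
  auc_inf <- NA_real_
  if (!is.na(lz)) {
    clast <- conc[max(which(conc > 0))]
    auc_inf <- auc_last + clast / lz
  }
  data.frame(auc_last = auc_last, auc_inf = auc_inf, cmax = cmax,
             tmax = tmax, lambda_z = lz)
}

# best-adjusted-R2 terminal regression over suffix windows of the positive
# tail, excluding Cmax itself; windows all end at the last point and contain
# 3 to max_window points
nca_lambda_z <- function(time, conc, imax, max_window = 30L) {
  idx <- which(seq_along(conc) > imax & conc > 0)
  if (length(idx) < 3) return(NA_real_)
  starts <- seq.int(max(1L, length(idx) - max_window + 1L), length(idx) - 2L)
  best <- NULL
  for (start in starts) {
    i <- idx[start:length(idx)]
    x <- time[i]; y <- log(conc[i]); n <- length(i)
    sxx <- sum((x - mean(x))^2)
    if (sxx <= 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (!is.finite(b) || b >= 0) next
    res <- y - mean(y) - b * (x - mean(x))
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy > 0) 1 - sum(res^2) / syy else 1
    ar2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || ar2 > best$ar2 + 1e-10) best <- list(ar2 = ar2, lz = -b)
  }
  if (is.null(best)) NA_real_ else best$lz
}

#' Per-subject exposure metrics for a cohort
#'
#' Simulates each subject's profile under a dose and scenario and computes
#' NCA metrics for both analytes.  The scenario is applied to each subject's
#' individual parameters; residual error is not added (exposure metrics are
#' computed on model-predicted profiles, as in simulation-based dose
#' selection).
#'
#' @param cohort a list of subjects from [build_cohort()].
#' @param dose_mg_per_kg dose in mg/kg (`NULL` to use `dose_mg` instead).
#' @param dose_mg absolute dose in mg (for adult reference arms).
#' @param scenario a [scenario_spec()].
#' @param times simulation grid, h.
#' @return A data.frame with one row per subject x analyte: `id`, `age`,
#'   `sex`, `weight`, `dose_mg`, `analyte` plus the [nca()] columns.
#' @export
exposure_table <- function(cohort, dose_mg_per_kg = NULL, dose_mg = NULL,
                           scenario = scenario_spec(),
                           times = default_nca_grid()) {
  if (is.null(dose_mg_per_kg) == is.null(dose_mg)) {
    stop("give exactly one of dose_mg_per_kg or dose_mg")
  }
  rows <- lapply(cohort, function(s) {
    amt <- if (is.null(dose_mg)) dose_mg_per_kg * s$weight else dose_mg
    p <- apply_scenario(s$params, scenario)
    prof <- solve_profile(p, dose_events(0, amt), times)
    do.call(rbind, lapply(c("spir", "can"), function(an) {
      cbind(data.frame(id = s$id, age = s$age, sex = s$sex,
                       weight = s$weight, dose_mg = amt,
                       analyte = toupper(an)),
            nca(prof$time, prof[[an]]))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# grid spanning absorption through the CAN terminal phase (t1/2 ~ 30 h)
default_nca_grid <- function() {
  unique(c(seq(0, 1, 0.1), seq(1.25, 8, 0.25), seq(9, 24, 1),
           seq(28, 72, 4), seq(80, 240, 8)))
}

#' Summarize an exposure metric over grouping cells
#'
#' @param records an [exposure_table()] data.frame.
#' @param metric column to summarize (default `"auc_inf"`).
#' @param by character vector of grouping columns (default `c("age",
#'   "analyte")`).
#' @return A data.frame per cell: grouping columns, `n`, `mean`, `sd`, `p5`,
#'   `p95` (percentiles by linear interpolation, quantile type 7).
#' @export
summarize_exposure <- function(records, metric = "auc_inf",
                               by = c("age", "analyte")) {
  x <- records[[metric]]
  if (any(is.na(x))) {
    warning(sum(is.na(x)), " records with missing ", metric, " dropped")
    records <- records[!is.na(x), , drop = FALSE]
    x <- records[[metric]]
  }
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(x), key), function(i) {
    if (length(i) < 1) stop("empty summary cell")
    cell <- records[i[1], by, drop = FALSE]
    q <- stats::quantile(x[i], c(0.05, 0.95), names = FALSE, type = 7)
    cbind(cell, data.frame(n = length(i), mean = mean(x[i]),
                           sd = stats::sd(x[i]), p5 = q[1], p95 = q[2]))
  }))
  rownames(out) <- NULL
  out
}

#' Compare pediatric exposure cells against an adult reference band
#'
#' Flags, per pediatric cell, whether the mean exposure falls inside the
#' adult mean +/- SD band and inside the adult 5th-95th prediction interval
#' (the similarity rule used for dose selection).
#'
#' @param ped pediatric summary rows (from [summarize_exposure()], grouped at
#'   least by `analyte`).
#' @param adult_ref adult summary rows with an `analyte` column.
#' @return `ped` with extra columns `ref_mean`, `ref_p5`, `ref_p95`,
#'   `inside_sd_band`, `inside_pi`.
#' @export
compare_to_reference <- function(ped, adult_ref) {
  if (!all(c("analyte", "mean") %in% names(ped)) ||
      !all(c("analyte", "mean", "sd", "p5", "p95") %in% names(adult_ref))) {
    stop("summaries must carry analyte/mean/sd/p5/p95 columns")
  }
  i <- match(ped$analyte, adult_ref$analyte)
  if (any(is.na(i))) stop("analyte mismatch between pediatric and reference")
  ref <- adult_ref[i, ]
  ped$ref_mean <- ref$mean
  ped$ref_p5 <- ref$p5
  ped$ref_p95 <- ref$p95
  ped$inside_sd_band <- ped$mean >= ref$mean - ref$sd &
    ped$mean <= ref$mean + ref$sd
  ped$inside_pi <- ped$mean >= ref$p5 & ped$mean <= ref$p95
  ped
}

#' Sweep pediatric doses against adult reference exposures
#'
#' Simulates pediatric cohorts at each dose (mg/kg) and compares each
#' age x analyte exposure cell against adult reference bands at the given
#' reference doses (mg), all under one clinical scenario.  Adult references
#' are simulated cohorts of the same size per cell at the reference weight.
#'
#' @param doses_mg_per_kg pediatric doses to sweep, mg/kg.
#' @param ages reference ages, years.
#' @param n_per_sex pediatric subjects per age/sex cell (adult reference uses
#'   `2 * n_per_sex` to match the cell size).
#' @param scenario a [scenario_spec()].
#' @param adult_ref_doses_mg adult reference doses, mg.
#' @param spec a [variability_spec()].
#' @param metric exposure metric column.
#' @return A tidy data.frame: one row per dose x age x analyte x reference
#'   dose with summary statistics and the band flags.
#' @export
dose_sweep <- function(doses_mg_per_kg = c(0.25, 0.5, 1, 1.5, 2),
                       ages = c(2, 6, 12, 17), n_per_sex = 100,
                       scenario = scenario_spec(),
                       adult_ref_doses_mg = c(25, 100),
                       spec = variability_spec(), metric = "auc_inf") {
  refs <- lapply(adult_ref_doses_mg, function(dmg) {
    # both sexes together give 2 * n_per_sex reference adults, matching the
    # size of one pediatric age cell
    ad <- build_cohort(n_per_sex, ages = 30, spec = spec, adult = TRUE)
    summarize_exposure(
      exposure_table(ad, dose_mg = dmg, scenario = scenario),
      metric = metric, by = "analyte")
  })
  names(refs) <- as.character(adult_ref_doses_mg)

  out <- list()
  for (d in doses_mg_per_kg) {
    ped <- build_cohort(n_per_sex, ages = ages, spec = spec)
    tab <- exposure_table(ped, dose_mg_per_kg = d, scenario = scenario)
    summ <- summarize_exposure(tab, metric = metric, by = c("age", "analyte"))
    for (rd in names(refs)) {
      cmpd <- compare_to_reference(summ, refs[[rd]])
      cmpd$dose_mg_per_kg <- d
      cmpd$ref_dose_mg <- as.numeric(rd)
      cmpd$scenario <- scenario_label(scenario)
      out[[length(out) + 1L]] <- cmpd
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
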
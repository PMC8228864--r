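#' Between-subject and residual variability specification
#'
#' Log-normal between-subject variability (BSV): individual parameters are
#' `P_i = P_typical * exp(eta_i)` with `eta ~ N(0, omega2)`; `(eta_cl,
#' eta_v2)` are drawn jointly with the stated covariance and all other
#' effects independently.  Residual error is proportional per analyte:
#' `obs = pred * (1 + eps)` with `eps ~ N(0, eps1)` for SPIR and
#' `N(0, eps2)` for CAN (`eps1`/`eps2` are variances, following the NONMEM
#' SIGMA convention).  Defaults are the adult estimates, which are carried
#' unchanged to pediatrics.
#'
#' @param omega2 named numeric vector of log-scale variances; names among
#'   `ka, cl, v2, q, clm1, clm, v4, q1, v5`.
#' @param cov_cl_v2 covariance of the `cl` and `v2` random effects.
#' @param eps1,eps2 proportional residual variances for SPIR and CAN.
#' @return A `variability_spec` list.
#' @export
variability_spec <- function(omega2 = c(ka = 0.9, cl = 0.166, v2 = 0.118,
                                        q = 0.08, clm1 = 0.18, clm = 0.08,
                                        v4 = 0.03, q1 = 0.07, v5 = 0.09),
                             cov_cl_v2 = 0.112, eps1 = 0.08, eps2 = 0.017) {
  allowed <- c("ka", "cl", "v2", "q", "clm1", "clm", "v4", "q1", "v5")
  if (length(omega2) && !all(names(omega2) %in% allowed)) {
    stop("omega2 names must be among: ", paste(allowed, collapse = ", "))
  }
  if (any(omega2 < 0) || eps1 < 0 || eps2 < 0) {
    stop("variances must be >= 0")
  }
  ocl <- if ("cl" %in% names(omega2)) omega2[["cl"]] else 0
  ov2 <- if ("v2" %in% names(omega2)) omega2[["v2"]] else 0
  if (cov_cl_v2^2 > ocl * ov2 + 1e-12) {
    stop("(cl, v2) covariance block is not positive semidefinite")
  }
  structure(list(omega2 = omega2, cov_cl_v2 = cov_cl_v2,
                 eps1 = eps1, eps2 = eps2),
            class = "variability_spec")
}

#' Variability with everything switched off
#' @return A `variability_spec` with all variances zero.
#' @export
zero_variability <- function() {
  variability_spec(omega2 = c(ka = 0, cl = 0, v2 = 0, q = 0, clm1 = 0,
                              clm = 0, v4 = 0, q1 = 0, v5 = 0),
                   cov_cl_v2 = 0, eps1 = 0, eps2 = 0)
}

# draw an n x k matrix of log-scale random effects; columns named after the
# omega2 entries; the (cl, v2) pair is drawn jointly via Cholesky of its block
sample_eta <- function(n, spec) {
  nm <- names(spec$omega2)
  eta <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  joint <- c("cl", "v2") %in% nm
  if (all(joint) && spec$cov_cl_v2 != 0) {
    sig <- matrix(c(spec$omega2[["cl"]], spec$cov_cl_v2,
                    spec$cov_cl_v2, spec$omega2[["v2"]]), 2, 2)
    ch <- tryCatch(chol(sig), error = function(e) {
      warning("near-singular (cl, v2) block; jittering diagonal")
      chol(sig + diag(1e-12, 2))
    })
    z <- matrix(stats::rnorm(2 * n), n, 2)
    eta[, c("cl", "v2")] <- z %*% ch
    rest <- setdiff(nm, c("cl", "v2"))
  } else {
    rest <- nm
  }
  for (k in rest) {
    if (spec$omega2[[k]] > 0) {
      eta[, k] <- stats::rnorm(n, 0, sqrt(spec$omega2[[k]]))
    }
  }
  eta
}

apply_eta <- function(typical, eta_row) {
  p <- unclass(typical)
  for (k in names(eta_row)) p[[k]] <- p[[k]] * exp(eta_row[[k]])
  do.call(pk_params, p)
}

#' Sample an individual parameter set
#'
#' @param typical typical-value `pk_params`.
#' @param spec a [variability_spec()].
#' @param n number of individuals.
#' @return For `n = 1` a `pk_params`; otherwise a list of them.  Parameters
#'   without a variance term (`alag1`, `fm`, `v3`) stay at the typical value.
#' @export
sample_individual <- function(typical, spec = variability_spec(), n = 1) {
  validate_pk_params(typical)
  eta <- sample_eta(n, spec)
  out <- lapply(seq_len(n), function(i) apply_eta(typical, eta[i, ]))
  if (n == 1) out[[1]] else out
}

#' Apply proportional residual error to a predicted profile
#'
#' `obs = pred * (1 + eps)` with analyte-specific variances; draws that would
#' be negative are floored at zero and the count recorded in the
#' `"n_floored"` attribute.
#'
#' @param profile a `conc_profile`.
#' @param spec a [variability_spec()].
#' @return A `conc_profile` of observed concentrations.
#' @export
apply_residual <- function(profile, spec = variability_spec()) {
  n <- nrow(profile)
  obs <- profile
  obs$spir <- profile$spir * (1 + stats::rnorm(n, 0, sqrt(spec$eps1)))
  obs$can  <- profile$can  * (1 + stats::rnorm(n, 0, sqrt(spec$eps2)))
  floored <- sum(obs$spir < 0) + sum(obs$can < 0)
  obs$spir <- pmax(obs$spir, 0)
  obs$can <- pmax(obs$can, 0)
  attr(obs, "n_floored") <- floored
  obs
}

#' Build a virtual pediatric (or adult) cohort
#'
#' For each requested age, `n_per_sex` subjects per sex are created at the
#' weight given by the weight table, the adult typical parameters are scaled
#' allometrically to that weight, and individual parameters are sampled from
#' the BSV distribution.  Ages must lie in \[2, 17) for pediatric use; pass
#' `adult = TRUE` to build a 70 kg adult reference cohort instead (no
#' scaling, no age/weight lookup).
#'
#' @param n_per_sex subjects per age/sex cell.
#' @param ages numeric vector of ages, years.
#' @param adult_typical adult `pk_params`.
#' @param spec a [variability_spec()].
#' @param weights weight table (default [default_weight_table()]).
#' @param rule an [allometric_rule()].
#' @param adult build an adult reference cohort at the rule's reference
#'   weight instead of a pediatric one.
#' @return A list of `virtual_subject` lists with fields `id`, `age`, `sex`,
#'   `weight` and `params`.
#' @export
build_cohort <- function(n_per_sex, ages = c(2, 6, 12, 17),
                         adult_typical = adult_params(),
                         spec = variability_spec(),
                         weights = default_weight_table(),
                         rule = allometric_rule(), adult = FALSE) {
  if (n_per_sex <= 0) stop("n_per_sex must be > 0")
  # the study range is 2 to <17 years; age 17 is accepted as the reference
  # age for the upper edge of the oldest group
  if (!adult && (any(ages < 2) | any(ages > 17))) {
    stop("pediatric ages must be within 2 to 17 years")
  }
  subjects <- list()
  id <- 0L
  for (age in ages) {
    for (sex in c("F", "M")) {
      wt <- if (adult) rule$reference_weight else lookup_weight(weights, age, sex)
      typ <- if (adult) adult_typical else scale_parameters(adult_typical, wt, rule)
      indiv <- sample_individual(typ, spec, n = n_per_sex)
      if (n_per_sex == 1) indiv <- list(indiv)
      for (j in seq_len(n_per_sex)) {
        id <- id + 1L
        subjects[[id]] <- structure(
          list(id = id, age = age, sex = sex, weight = wt,
               params = indiv[[j]]),
          class = "virtual_subject")
      }
    }
  }
  subjects
}
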
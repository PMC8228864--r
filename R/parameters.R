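#' Structural parameter set for the parent-metabolite model
#'
#' Constructs and validates the set of apparent (bioavailability-conditioned)
#' structural constants of the spironolactone (SPIR) / canrenone (CAN) model:
#' a first-order absorption depot with lag feeding a two-compartment parent,
#' a fixed fraction of parent clearance routed to metabolite formation, and a
#' two-compartment metabolite.  All clearances are L/h, volumes L, `ka` 1/h,
#' `alag1` h.  `fm` is the fraction of parent elimination that forms CAN.
#' `dose_scale` is a relative-bioavailability multiplier applied to every dose
#' amount entering the depot; because all parameters are apparent, a
#' bioavailability change is algebraically identical to scaling the dose.
#'
#' @param cl SPIR apparent clearance not routed to CAN, L/h.
#' @param clm1 SPIR to CAN apparent metabolic clearance, L/h.
#' @param v2 SPIR central volume, L.
#' @param q SPIR intercompartmental clearance, L/h.
#' @param v3 SPIR peripheral volume, L.
#' @param ka first-order absorption rate constant, 1/h.
#' @param alag1 absorption lag time, h.
#' @param fm fraction of parent clearance forming CAN, in (0, 1].
#' @param clm CAN apparent clearance, L/h.
#' @param v4 CAN central volume, L.
#' @param q1 CAN intercompartmental clearance, L/h.
#' @param v5 CAN peripheral volume, L.
#' @param dose_scale bioavailability multiplier on administered amounts.
#' @return An object of class `pk_params` (a named list).
#' @examples
#' p <- adult_params()
#' total_clearance(p)
#' @export
pk_params <- function(cl, clm1, v2, q, v3, ka, alag1 = 0, fm = 0.7,
                      clm, v4, q1, v5, dose_scale = 1) {
  p <- list(cl = cl, clm1 = clm1, v2 = v2, q = q, v3 = v3, ka = ka,
            alag1 = alag1, fm = fm, clm = clm, v4 = v4, q1 = q1, v5 = v5,
            dose_scale = dose_scale)
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("pk_params: all fields must be finite scalars; bad: ",
         paste(names(p)[!num], collapse = ", "))
  }
  pos <- c("cl", "clm1", "v2", "q", "v3", "ka", "clm", "v4", "q1", "v5",
           "dose_scale")
  # q/q1 may legitimately be zero (one-compartment limit); the rest must be > 0
  strict <- setdiff(pos, c("q", "q1"))
  if (any(unlist(p[strict]) <= 0)) {
    stop("pk_params: clearances, volumes, ka and dose_scale must be > 0")
  }
  if (p$q < 0 || p$q1 < 0) stop("pk_params: q and q1 must be >= 0")
  if (p$alag1 < 0) stop("pk_params: alag1 must be >= 0")
  if (p$fm <= 0 || p$fm > 1) stop("pk_params: fm must be in (0, 1]")
  invisible(p)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Parent-metabolite PK parameter set (apparent values)\n")
  flds <- unlist(x)
  cat(sprintf("  %-10s %s\n", names(flds), format(flds, digits = 6)), sep = "")
  invisible(x)
}

#' Adult reference parameter set
#'
#' Typical adult values for the SPIR/CAN model estimated from 92 healthy
#' adults dosed with 25 or 100 mg of the oral suspension (fasted).
#'
#' @return A `pk_params` object.
#' @export
adult_params <- function() {
  pk_params(cl = 629, clm1 = 217, v2 = 517, q = 89.9, v3 = 777,
            ka = 5.22, alag1 = 0.156, fm = 0.7,
            clm = 17, v4 = 189, q1 = 60, v5 = 448)
}

#' Total apparent clearance of the parent drug
#'
#' SPIR is cleared by two parallel routes: direct elimination (`cl`, the
#' non-CAN route, weighted by `1 - fm`) and metabolic conversion to CAN
#' (`clm1`, weighted by `fm`), so total clearance is
#' `cl * (1 - fm) + clm1 * fm`.
#'
#' @param params A `pk_params` object.
#' @return Total SPIR clearance, L/h.
#' @export
total_clearance <- function(params) {
  validate_pk_params(params)
  params$cl * (1 - params$fm) + params$clm1 * params$fm
}

#' Terminal slope of an analyte's concentration profile
#'
#' Returns the smallest-magnitude non-zero rate constant among the first-order
#' processes feeding the analyte: the absorption rate `ka` (unless
#' `include_depot = FALSE`) and the disposition eigenvalues of the parent
#' two-compartment block (plus, for CAN, the metabolite block).  For oral
#' dosing the log-linear tail decays at this rate; when absorption is slower
#' than disposition (flip-flop kinetics) the reported slope is `ka`.
#' Half-life is `log(2) / slope`.
#'
#' @param params A `pk_params` object.
#' @param analyte `"spir"` or `"can"`.
#' @param include_depot include `ka` among the candidate rates?
#' @return Terminal slope, 1/h.
#' @export
terminal_slope <- function(params, analyte = c("spir", "can"),
                           include_depot = TRUE) {
  analyte <- match.arg(analyte)
  validate_pk_params(params)
  cltot <- total_clearance(params)
  if (cltot <= 0 || params$clm <= 0) stop("degenerate clearances")
  rates <- two_cpt_eigenrates(cltot, params$v2, params$q, params$v3)
  if (analyte == "can") {
    rates <- c(rates,
               two_cpt_eigenrates(params$clm, params$v4, params$q1, params$v5))
  }
  if (include_depot) rates <- c(rates, params$ka)
  rates <- rates[rates > 1e-12]
  if (!length(rates)) stop("no non-zero disposition rates")
  min(rates)
}

# eigen-rates (positive) of a two-compartment disposition block given
# elimination clearance, central volume, intercompartmental clearance and
# peripheral volume; q = 0 collapses to the single rate cl/v
two_cpt_eigenrates <- function(cl, v, q, vp) {
  k10 <- cl / v
  if (q <= 0) return(k10)
  k12 <- q / v
  k21 <- q / vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  c((s + disc) / 2, (s - disc) / 2)
}

#' Read or write a parameter configuration file
#'
#' Flat key-value YAML with uppercase keys `CL, CLM1, V2, Q, V3, KA, ALAG1,
#' FM, CLM, V4, Q1, V5` (and optionally `F` for the bioavailability
#' multiplier).  Variability specifications use keys `OMEGA_<PARAM>`,
#' `COV_CL_V2`, `EPS1`, `EPS2` (see [variability_spec()]).
#'
#' @param path file path.
#' @param params a `pk_params` object (for writing).
#' @return `read_params_config()` returns a `pk_params` object.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  names(cfg) <- toupper(names(cfg))
  need <- c("CL", "CLM1", "V2", "Q", "V3", "KA", "ALAG1", "FM", "CLM",
            "V4", "Q1", "V5")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("parameter config missing keys: ",
                         paste(miss, collapse = ", "))
  pk_params(cl = cfg$CL, clm1 = cfg$CLM1, v2 = cfg$V2, q = cfg$Q,
            v3 = cfg$V3, ka = cfg$KA, alag1 = cfg$ALAG1, fm = cfg$FM,
            clm = cfg$CLM, v4 = cfg$V4, q1 = cfg$Q1, v5 = cfg$V5,
            dose_scale = if (!is.null(cfg$F)) cfg$F else 1)
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  validate_pk_params(params)
  out <- list(CL = params$cl, CLM1 = params$clm1, V2 = params$v2,
              Q = params$q, V3 = params$v3, KA = params$ka,
              ALAG1 = params$alag1, FM = params$fm, CLM = params$clm,
              V4 = params$v4, Q1 = params$q1, V5 = params$v5,
              F = params$dose_scale)
  yaml::write_yaml(out, path)
  invisible(path)
}
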
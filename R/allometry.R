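#' Allometric scaling rule
#'
#' Fixed-exponent allometry referenced to a 70 kg adult: clearances (including
#' intercompartmental) scale with weight to the 0.75 power, volumes linearly,
#' and rate constants, lag and fractions are weight-independent.
#'
#' @param exponent_clearance power for clearances (default 0.75).
#' @param exponent_volume power for volumes (default 1).
#' @param reference_weight adult reference weight, kg (default 70).
#' @return An `allometric_rule` list.
#' @export
allometric_rule <- function(exponent_clearance = 0.75, exponent_volume = 1,
                            reference_weight = 70) {
  if (reference_weight <= 0) stop("reference_weight must be > 0")
  structure(list(exponent_clearance = exponent_clearance,
                 exponent_volume = exponent_volume,
                 reference_weight = reference_weight),
            class = "allometric_rule")
}

#' Scale an adult parameter set to a body weight
#'
#' Applies `P_ped = P_adult * (WT / 70)^b` with `b = 0.75` for the five
#' clearances (`cl`, `clm1`, `clm`, `q`, `q1`) and `b = 1` for the four
#' volumes (`v2`, `v3`, `v4`, `v5`); `ka`, `alag1`, `fm` and `dose_scale`
#' are unchanged.
#'
#' @param adult adult `pk_params`.
#' @param weight body weight, kg (> 0).
#' @param rule an [allometric_rule()].
#' @return A `pk_params` object at the requested weight.
#' @export
scale_parameters <- function(adult, weight, rule = allometric_rule()) {
  validate_pk_params(adult)
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("weight must be a positive scalar")
  }
  r <- weight / rule$reference_weight
  fcl <- r^rule$exponent_clearance
  fv <- r^rule$exponent_volume
  p <- unclass(adult)
  for (k in c("cl", "clm1", "clm", "q", "q1")) p[[k]] <- p[[k]] * fcl
  for (k in c("v2", "v3", "v4", "v5")) p[[k]] <- p[[k]] * fv
  do.call(pk_params, p)
}

#' Body weight implied by a scaled central volume
#'
#' Inverts the exponent-1 volume rule: `WT = 70 * v_ped / v_adult`.  Used to
#' recover the CDC median weights that underlie the shipped pediatric
#' parameter grid from the printed central volumes.
#'
#' @param v2_ped pediatric central volume, L.
#' @param v2_adult adult central volume, L (default the adult SPIR V2).
#' @param rule an [allometric_rule()].
#' @return Weight, kg.
#' @export
implied_weight <- function(v2_ped, v2_adult = 517, rule = allometric_rule()) {
  if (any(v2_ped <= 0) || any(v2_adult <= 0)) stop("volumes must be > 0")
  rule$reference_weight * v2_ped / v2_adult
}

#' Default pediatric weight table
#'
#' Median body weights for the eight reference age/sex cells (ages 2, 6, 12
#' and 17 years, both sexes).  They are the CDC-chart medians implied by the
#' pediatric central-volume column of the published extrapolation grid,
#' recovered exactly as `70 * V2_ped / 517` so the grid can be rebuilt without
#' an external growth-chart download.
#'
#' @return A data.frame with columns `age_years`, `sex` (`"F"`/`"M"`) and
#'   `weight_kg`.
#' @export
default_weight_table <- function() {
  v2 <- c("2_F" = 93.28, "2_M" = 87.00, "6_F" = 159.46, "6_M" = 158.65,
          "12_F" = 315.00, "12_M" = 320.47, "17_F" = 474.09, "17_M" = 404.07)
  parts <- strsplit(names(v2), "_", fixed = TRUE)
  data.frame(age_years = as.numeric(vapply(parts, `[`, "", 1L)),
             sex = vapply(parts, `[`, "", 2L),
             weight_kg = unname(implied_weight(v2)))
}

#' Read a weight table from CSV
#'
#' Columns `age_years`, `sex`, `weight_kg`.
#'
#' @param path CSV file path.
#' @return A weight-table data.frame.
#' @export
read_weight_table <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_years", "sex", "weight_kg")
  if (!all(need %in% names(w))) {
    stop("weight table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(w$weight_kg <= 0)) stop("weights must be > 0")
  if (any(w$age_years < 2)) stop("weight table covers ages >= 2 years only")
  w[need]
}

lookup_weight <- function(weights, age, sex) {
  i <- which(weights$age_years == age & weights$sex == sex)
  if (!length(i)) stop("no weight for age ", age, " sex ", sex)
  weights$weight_kg[i[1]]
}

#' Pediatric parameter grid by age and sex
#'
#' Scales the adult parameter set to every (age, sex) cell of a weight table,
#' reproducing the published pediatric extrapolation grid when the default
#' weights are used.
#'
#' @param adult adult `pk_params`.
#' @param weights a weight table (default [default_weight_table()]).
#' @param rule an [allometric_rule()].
#' @return A data.frame with one row per age/sex cell: `age_years`, `sex`,
#'   `weight_kg` and the 12 structural parameters.
#' @export
pediatric_parameter_table <- function(adult = adult_params(),
                                      weights = default_weight_table(),
                                      rule = allometric_rule()) {
  rows <- lapply(seq_len(nrow(weights)), function(i) {
    p <- scale_parameters(adult, weights$weight_kg[i], rule)
    cbind(weights[i, c("age_years", "sex", "weight_kg")],
          as.data.frame(unclass(p)[c("cl", "v2", "q", "v3", "ka", "v4",
                                     "clm", "q1", "v5", "alag1", "fm",
                                     "clm1")]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
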
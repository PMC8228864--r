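# independent brute-force FO information assembly: dense loops, its own
# finite-difference scheme, no shared code with expected_rse_fim internals
bruteforce_fim <- function(design, typical, spec, estimated) {
  h <- 1e-5
  om_names <- names(spec$omega2)
  om <- diag(spec$omega2, nrow = length(om_names))
  dimnames(om) <- list(om_names, om_names)
  om["cl", "v2"] <- om["v2", "cl"] <- spec$cov_cl_v2
  pred <- function(p, s) {
    prof <- solve_profile(do.call(pk_params, p),
                          dose_events(0, s$amt), s$times)
    c(prof$spir, prof$can)
  }
  fim <- matrix(0, length(estimated), length(estimated))
  for (s in design) {
    base_p <- unclass(scale_parameters(typical, s$weight))
    f0 <- pred(base_p, s)
    keep <- f0 > 1e-12
    nk <- sum(keep)
    # dtheta: adult-scale perturbation propagated through the scaling
    jac <- matrix(0, nk, length(estimated))
    for (j in seq_along(estimated)) {
      pu <- unclass(typical); pu[[estimated[j]]] <- pu[[estimated[j]]] * exp(h)
      pd <- unclass(typical); pd[[estimated[j]]] <- pd[[estimated[j]]] * exp(-h)
      fu <- pred(unclass(scale_parameters(do.call(pk_params, pu), s$weight)), s)
      fd <- pred(unclass(scale_parameters(do.call(pk_params, pd), s$weight)), s)
      jac[, j] <- (log(fu[keep]) - log(fd[keep])) / (2 * h)
    }
    g <- matrix(0, nk, length(om_names))
    for (k in seq_along(om_names)) {
      pu <- base_p; pu[[om_names[k]]] <- pu[[om_names[k]]] * exp(h)
      pd <- base_p; pd[[om_names[k]]] <- pd[[om_names[k]]] * exp(-h)
      g[, k] <- (log(pred(pu, s)[keep]) - log(pred(pd, s)[keep])) / (2 * h)
    }
    eps <- rep(c(spec$eps1, spec$eps2), each = length(s$times))[keep]
    v <- g %*% om %*% t(g) + diag(eps, nk)
    fim <- fim + t(jac) %*% solve(v) %*% jac
  }
  fim
}

test_that("the FO information matrix matches a brute-force assembly", {
  spec <- variability_spec()
  design <- list(list(weight = 20, amt = 10, times = c(0.5, 1, 2, 6, 24, 48)),
                 list(weight = 45, amt = 22, times = c(0.3, 1.5, 4, 8, 30)))
  fast <- expected_rse_fim(design, spec = spec)
  slow <- bruteforce_fim(design, adult_params(), spec, spirped:::default_estimated())
  expect_equal(unname(fast$fim), unname(slow), tolerance = 1e-6)
})

test_that("doubling the cohort halves variances, scaling %RSE by sqrt 2", {
  spec <- variability_spec()
  design <- list(list(weight = 20, amt = 10, times = c(0.5, 1, 2, 6, 24, 48)),
                 list(weight = 45, amt = 22, times = c(0.3, 1.5, 4, 8, 30)))
  one <- expected_rse_fim(design, spec = spec)
  two <- expected_rse_fim(c(design, design), spec = spec)
  expect_equal(two$rse, one$rse / sqrt(2), tolerance = 1e-10)
})

test_that("adding a sampling window never loses information", {
  spec <- variability_spec()
  base <- list(list(weight = 30, amt = 15, times = c(0.5, 2, 8, 48)))
  more <- list(list(weight = 30, amt = 15, times = c(0.5, 2, 8, 48, 120)))
  a <- expected_rse_fim(base, spec = spec)
  b <- expected_rse_fim(more, spec = spec)
  expect_true(all(b$rse <= a$rse + 1e-9))
})

test_that("an uninformative design raises a structured error", {
  spec <- variability_spec()
  tiny <- list(list(weight = 30, amt = 15, times = c(0.05)))  # pre-lag only
  expect_error(expected_rse_fim(tiny, spec = spec), "informative")
})

test_that("a noise-free rich fit started at truth recovers it exactly", {
  set.seed(801)
  ds <- generate_adult_study(vspec = zero_variability())
  ft <- fit_pooled(ds, init = adult_params(), spec = NULL,
                   truth = adult_params(), allometric = FALSE)
  expect_true(ft$converged)
  expect_lt(max(abs(ft$table$pct_bias)), 0.1)
})

test_that("zero-variability replicates give near-zero empirical %RSE", {
  set.seed(802)
  ev <- evaluate_design(n_replicates = 3, spec = zero_variability())
  expect_lt(max(ev$rse), 0.1)
  expect_equal(ev$convergence_fraction, 1)
})

test_that("seeded design evaluations reproduce exactly", {
  set.seed(803)
  a <- evaluate_design(n_replicates = 2, spec = zero_variability())
  set.seed(803)
  b <- evaluate_design(n_replicates = 2, spec = zero_variability())
  expect_identical(a$estimates, b$estimates)
})

test_that("sparse replicate estimates center on the generating values", {
  # moderate replicate count keeps this quick; the full 100-replicate
  # comparison against the information bound runs with the acceptance checks
  set.seed(804)
  ev <- evaluate_design(n_replicates = 25)
  key <- c("cl", "v2", "clm1", "clm")
  expect_lt(max(abs(ev$median_bias[key])), 10)
  expect_equal(ev$convergence_fraction, 1, tolerance = 0.2)
})
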
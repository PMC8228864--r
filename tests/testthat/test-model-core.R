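test_that("no drug appears before the absorption lag", {
  prof <- solve_profile(adult_params(), dose_events(0, 100),
                        times = c(0.01, 0.05, 0.1, 0.15))
  expect_equal(max(prof$spir), 0)
  expect_equal(max(prof$can), 0)
})

test_that("total clearance is the fm-weighted combination of the two routes", {
  expect_equal(total_clearance(adult_params()), 629 * 0.3 + 217 * 0.7)
  expect_equal(total_clearance(adult_params()), 340.6)
  # convex combination of equal clearances is that clearance, any fm
  for (fm in c(0.1, 0.5, 0.99)) {
    p <- pk_params(cl = 55, clm1 = 55, v2 = 100, q = 10, v3 = 200, ka = 1,
                   fm = fm, clm = 8, v4 = 50, q1 = 5, v5 = 90)
    expect_equal(total_clearance(p), 55)
  }
  p1 <- pk_params(cl = 70, clm1 = 31, v2 = 100, q = 10, v3 = 200, ka = 1,
                  fm = 1, clm = 8, v4 = 50, q1 = 5, v5 = 90)
  expect_equal(total_clearance(p1), 31)
})

test_that("simulated AUCs obey the parent and metabolite mass balances", {
  prof <- solve_profile(adult_params(), dose_events(0, 100), dense_auc_grid())
  spir <- nca(prof$time, prof$spir)
  can <- nca(prof$time, prof$can)
  # AUCinf = Dose / CLtot for the parent; amount formed / CLM for metabolite
  expect_equal(spir$auc_inf, 100 / 340.6, tolerance = 0.005)
  expect_equal(can$auc_inf, 100 * 0.7 * 217 / (340.6 * 17), tolerance = 0.005)
})

test_that("one-compartment limit reproduces the lagged Bateman function", {
  p <- pk_params(cl = 50, clm1 = 50, v2 = 30, q = 0, v3 = 1, ka = 1.2,
                 alag1 = 0.3, fm = 1, clm = 10, v4 = 20, q1 = 0, v5 = 1)
  tt <- seq(0, 30, 0.1)
  prof <- solve_profile(p, dose_events(0, 10), tt)
  ke <- 50 / 30
  ts <- pmax(tt - 0.3, 0)
  bateman <- ifelse(tt > 0.3,
                    10 * 1.2 / (30 * (1.2 - ke)) *
                      (exp(-ke * ts) - exp(-1.2 * ts)), 0)
  expect_equal(prof$spir, bateman, tolerance = 1e-10)
})

test_that("profiles are dose-linear and obey superposition", {
  tt <- seq(0, 48, 0.5)
  p <- adult_params()
  one <- solve_profile(p, dose_events(0, 50), tt)
  three <- solve_profile(p, dose_events(0, 150), tt)
  expect_equal(three$spir, 3 * one$spir, tolerance = 1e-12)
  expect_equal(three$can, 3 * one$can, tolerance = 1e-12)

  both <- solve_profile(p, dose_events(c(0, 12), c(50, 50)), tt)
  shifted <- solve_profile(p, dose_events(12, 50), tt)
  expect_equal(both$spir, one$spir + shifted$spir, tolerance = 1e-12)
  expect_equal(both$can, one$can + shifted$can, tolerance = 1e-12)
})

test_that("matrix-exponential and stiff ODE solutions agree", {
  set.seed(401)
  tt <- sort(unique(c(seq(0.05, 8, 0.05), seq(8.5, 96, 0.5))))
  for (i in 1:20) {
    p <- random_params()
    a <- solve_profile(p, dose_events(0, 40), tt)
    b <- solve_profile(p, dose_events(0, 40), tt, method = "ode")
    for (an in c("spir", "can")) {
      mask <- b[[an]] > max(b[[an]]) * 1e-6   # above integrator noise floor
      rel <- abs(a[[an]][mask] - b[[an]][mask]) / b[[an]][mask]
      expect_lt(max(rel), 1e-7)
    }
  }
})

test_that("terminal slope matches the disposition eigenvalue analysis", {
  p <- adult_params()
  # slow eigenvalue of the parent 2x2 block at CLtot = 340.6
  lz <- terminal_slope(p, "spir", include_depot = FALSE)
  expect_equal(lz, 0.0887, tolerance = 1e-3)
  expect_equal(log(2) / lz, 7.82, tolerance = 1e-3)
  # one-compartment limit: single rate CLtot / V2
  p1 <- pk_params(cl = 629, clm1 = 217, v2 = 517, q = 0, v3 = 777,
                  ka = 5.22, fm = 0.7, clm = 17, v4 = 189, q1 = 0, v5 = 448)
  expect_equal(terminal_slope(p1, "spir", include_depot = FALSE), 340.6 / 517)
})

test_that("reported slope under slowed absorption matches the simulated tail", {
  fed <- apply_scenario(adult_params(), scenario_spec(fed = TRUE))
  lz <- terminal_slope(fed, "spir")
  # independent check: log-linear regression on a dense simulated tail
  tt <- seq(100, 400, 1)
  prof <- solve_profile(fed, dose_events(0, 100), tt)
  slope <- -unname(coef(lm(log(prof$spir) ~ tt))[2])
  expect_equal(lz, slope, tolerance = 1e-4)
  expect_equal(lz, min(fed$ka, spirped:::two_cpt_eigenrates(
    total_clearance(fed), fed$v2, fed$q, fed$v3)))
})

test_that("cumulative elimination balances the administered dose", {
  # integrate outflow: SPIR eliminated (non-CAN) + CAN eliminated must equal
  # the dose once both analytes are washed out
  p <- adult_params()
  tt <- dense_auc_grid()
  prof <- solve_profile(p, dose_events(0, 100), tt)
  cltot <- total_clearance(p)
  auc_s <- nca(prof$time, prof$spir)$auc_inf
  auc_c <- nca(prof$time, prof$can)$auc_inf
  # parent: total amount cleared = CLtot * AUC = dose; metabolite: amount
  # cleared = CLM * AUC = amount formed = dose * fm * clm1 / CLtot
  expect_equal(auc_s * cltot, 100, tolerance = 0.005)
  expect_equal(auc_c * p$clm, 100 * p$fm * p$clm1 / cltot, tolerance = 0.005)
})

test_that("invalid grids and parameters are rejected", {
  p <- adult_params()
  expect_error(solve_profile(p, dose_events(0, 100), c(0, 2, 1)),
               "strictly increasing")
  expect_error(pk_params(cl = -1, clm1 = 217, v2 = 517, q = 89.9, v3 = 777,
                         ka = 5.22, fm = 0.7, clm = 17, v4 = 189, q1 = 60,
                         v5 = 448), "must be > 0")
  expect_error(pk_params(cl = 629, clm1 = 217, v2 = 517, q = 89.9, v3 = 777,
                         ka = 5.22, fm = 1.4, clm = 17, v4 = 189, q1 = 60,
                         v5 = 448), "fm")
  expect_error(dose_events(-1, 10), "dose times")
})
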
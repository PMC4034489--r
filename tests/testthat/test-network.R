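test_that("at the all-zero state only the constitutive terms fire", {
  d <- molecular_rhs(rep(0, 9), 0)
  p <- reaction_parameters()
  cc <- network_constants()
  expect_equal(d[["x2"]], p[["k4"]])
  expect_equal(d[["x8"]], p[["k14"]] * cc$R_tot)
  expect_equal(unname(d[c(1, 3:7, 9)]), rep(0, 7))
})

test_that("rhs matches an independent transcription on random states", {
  set.seed(42)
  p <- reaction_parameters()
  cc <- network_constants()
  for (i in 1:50) {
    x <- random_state(cc)
    g <- runif(1, 0, 5)
    expect_equal(unname(molecular_rhs(x, g, p, cc)),
                 rhs_reference(x, g, p, cc), tolerance = 1e-12)
  }
})

test_that("non-finite input is rejected with the offending component", {
  expect_error(molecular_rhs(c(1, NaN, rep(0, 7)), 1), "x2")
  expect_error(molecular_rhs(rep(0, 9), -1), "glucose")
  expect_error(molecular_rhs(rep(0, 9), NA_real_), "glucose")
})

test_that("AMPK at its pool bound with no scaffold can only decay", {
  cc <- network_constants()
  x <- rep(0, 9)
  x[6] <- cc$A_tot
  d <- molecular_rhs(x, 0)
  expect_lte(d[["x6"]], 0)
})

test_that("perturbing k2 touches exactly the binding-reaction components", {
  set.seed(7)
  p <- reaction_parameters()
  p2 <- scale_parameter(p, "k2", 2)
  cc <- network_constants()
  for (i in 1:100) {
    x <- random_state(cc)
    g <- runif(1, 0, 5)
    diff <- molecular_rhs(x, g, p2, cc) - molecular_rhs(x, g, p, cc)
    expect_true(all(diff[4:9] == 0))
    expect_equal(diff[["x1"]], -p[["k2"]] * x[1] * x[2])
    expect_equal(diff[["x2"]], diff[["x1"]])
    expect_equal(diff[["x3"]], -diff[["x1"]])
  }
})

test_that("no loss term fires on a zeroed component (non-negativity)", {
  set.seed(11)
  cc <- network_constants()
  for (i in 1:200) {
    x <- random_state(cc)
    zero <- sample(9, sample(1:4, 1))
    x[zero] <- 0
    d <- molecular_rhs(x, runif(1, 0, 5))
    expect_true(all(d[zero] >= 0))
  }
})

test_that("with only k4 active the mRNA grows exactly linearly", {
  eps <- 1e-30
  over <- as.list(rep(eps, 31))
  names(over) <- perturbable_parameters()
  over$k4 <- 1.4583e-2
  p <- do.call(reaction_parameters, over)
  out <- integrate_cell(rep(0, 9), 0, p, dt_macro = 10, n_sub = 10)
  expect_equal(out[["x2"]], p[["k4"]] * 10, tolerance = 1e-10)
  expect_equal(unname(out[-2]), rep(0, 8), tolerance = 1e-20)
})

test_that("halving the substep changes the result below 1e-6 relative", {
  x0 <- rep(0, 9)
  a <- integrate_cell(x0, 4.5, dt_macro = 2e-4, n_sub = 400)
  b <- integrate_cell(x0, 4.5, dt_macro = 2e-4, n_sub = 800)
  expect_lt(max(abs(a - b) / (1 + abs(b))), 1e-6)
})

test_that("fixed-step integration agrees with an independent rk4 solver", {
  p <- toy_params()
  cc <- network_constants()
  x0 <- random_state(cc) * 0.1
  g <- 2.25
  mine <- integrate_cell(x0, g, p, cc, dt_macro = 1, n_sub = 100)
  f <- function(t, y, parms) list(rhs_reference(y, g, p, cc))
  ds <- deSolve::rk(x0, c(0, 1), f, NULL, method = "rk4", hini = 0.01)
  expect_equal(unname(mine), unname(ds[2, 2:10]), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the stiff implicit advance agrees with lsoda", {
  p <- reaction_parameters()
  cc <- network_constants()
  g <- 2.25
  mine <- advance_states(matrix(0, 1, 9), g, p, cc, dt = 1e5,
                         h0 = 1e-4, hmax = 2000)
  f <- function(t, y, parms) list(rhs_reference(pmax(y, 0), g, p, cc))
  ds <- deSolve::lsoda(rep(0, 9), c(0, 1e5), f, NULL,
                       rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
  expect_equal(unname(drop(mine)), unname(ds[2, 2:10]), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("integration respects the conserved pool bounds", {
  set.seed(5)
  cc <- network_constants()
  pools <- c(Inf, Inf, Inf, Inf, cc$S_tot, cc$A_tot, cc$T_tot, cc$R_tot,
             cc$M_tot)
  for (i in 1:10) {
    x <- random_state(cc)
    out <- advance_states(matrix(x, 1), runif(1, 0, 5), dt = 3600)
    expect_true(all(drop(out) <= pools + 1e-9))
    expect_true(all(drop(out) >= 0))
  }
})

test_that("steady states encode the glucose switch", {
  s0 <- steady_state(0)
  expect_equal(s0[["x1"]], 0, tolerance = 1e-8)
  levels <- default_glucose_levels()
  ss <- sapply(levels, steady_state)
  expect_true(all(diff(ss["x1", ]) > 0))   # miR-451 rises with glucose
  expect_true(all(diff(ss["x6", ]) < 0))   # AMPK falls with glucose
  expect_true(all(diff(ss["x9", ]) > 0))   # mTORC1 rises with glucose
  expect_gt(ss["x1", 4], ss["x1", 1])
})

test_that("steady_state reports non-convergence instead of a bad state", {
  expect_error(steady_state(4.5, tol = 1e-12, t_max = 10), "residual")
})

test_that("threshold calibration is a midpoint and is order-invariant", {
  thr <- calibrate_thresholds()
  s_lo <- steady_state(0.3)
  s_hi <- steady_state(4.5)
  expect_equal(thr$theta_A, (s_lo[["x6"]] + s_hi[["x6"]]) / 2)
  expect_equal(thr$theta_M, (s_lo[["x9"]] + s_hi[["x9"]]) / 2)
  thr2 <- calibrate_thresholds(glucose_lo = 4.5, glucose_hi = 0.3)
  expect_equal(thr, thr2)
})

test_that("calibrated thresholds classify the extreme steady states", {
  thr <- calibrate_thresholds()
  expect_identical(decide_phenotype(steady_state(0.3), thr), "MIGRATING")
  expect_identical(decide_phenotype(steady_state(4.5), thr),
                   "PROLIFERATING")
})

test_that("phenotype decision resolves boundaries and conflicts to rest", {
  thr <- structure(list(theta_A = 10, theta_M = 5),
                   class = "gs_thresholds")
  st <- function(x6, x9) { x <- rep(0, 9); x[6] <- x6; x[9] <- x9; x }
  expect_identical(decide_phenotype(st(10, 5), thr), "QUIESCENT")
  expect_identical(decide_phenotype(st(20, 0), thr), "MIGRATING")
  expect_identical(decide_phenotype(st(0, 10), thr), "PROLIFERATING")
  expect_identical(decide_phenotype(st(20, 10), thr), "QUIESCENT")
  expect_identical(decide_phenotype(st(0, 0), thr), "QUIESCENT")
})

test_that("molecular integration is deterministic", {
  x <- random_state()
  a <- integrate_cell(x, 1.125, dt_macro = 1e-4, n_sub = 100)
  b <- integrate_cell(x, 1.125, dt_macro = 1e-4, n_sub = 100)
  expect_identical(a, b)
  m <- matrix(x, 1)
  expect_identical(advance_states(m, 1.125, dt = 3600),
                   advance_states(m, 1.125, dt = 3600))
})
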
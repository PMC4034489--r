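test_that("coefficient and delta formulas match direct substitution", {
  expect_equal(sensitivity_coefficient(100, 100, 1.5), 0)
  expect_equal(sensitivity_coefficient(150, 100, 1.5), 1)
  expect_equal(delta_M(100, 100), 0)
  expect_equal(delta_M(50, 100), -0.5)
  expect_equal(delta_M(1000, 100), 9)
  expect_error(sensitivity_coefficient(1, 1, 1), "b = 1")
  expect_error(sensitivity_coefficient(1, 0, 2), "baseline")
  expect_error(sensitivity_coefficient(1, 1, -2), "b must be")
  expect_error(delta_M(1, 0), "baseline")
})

test_that("a delta of a translates into M_pert = (a + 1) * M_base", {
  set.seed(2)
  M <- runif(200, 1, 1e4)
  a <- runif(200, -0.99, 10)
  expect_equal(delta_M((a + 1) * M, M), a, tolerance = 1e-12)
})

test_that("the design enumerates the full parameter-factor-glucose cross", {
  d <- lsa_design(c("k1", "k2"), c(0.5, 2, 5), 4.5)
  expect_equal(nrow(d), 6)
  expect_error(lsa_design(factors = c(0.5, 1)), "factor 1")
})

test_that("the sweep computes closed-form coefficients on the surrogate", {
  params <- c("k1", "k2", "k4")
  w <- cbind(M_time = c(0.3, -0.4, 1.2), M_total = c(0.5, 0.2, 1.5),
             M_mig = c(0.1, 0.3, 1.0), M_prolif = c(0.2, -0.1, 0.8))
  rownames(w) <- params
  ## totals dwarf the subpopulation counts so the count-consistency guard
  ## never binds and the analytic response stays exact
  base <- data.frame(glucose0 = c(0.3, 4.5), M_time = c(2e6, 4e6),
                     M_total = c(3e8, 5e8), M_mig = c(1e6, 1.2e6),
                     M_prolif = c(1e6, 2e6))
  spec <- surrogate_spec(w, base, sigma = 0)
  sw <- run_lsa(surrogate_engine(spec), params,
                factors = c(0.5, 0.8, 1.2, 2, 5),
                glucose_levels = c(0.3, 4.5), replicates = 2)
  expect_equal(nrow(sw), 3 * 5 * 2)
  expect_true(all(sw$ok))
  for (e in c("time", "total", "mig", "prolif")) {
    expected <- (sw$factor^w[sw$param, paste0("M_", e)] - 1) /
      (sw$factor - 1)
    expect_equal(sw[[paste0("S_", e)]], unname(expected), tolerance = 1e-4)
  }
  ## dM identities on the same sweep
  expect_equal(sw$dM_time, unname(sw$factor^w[sw$param, "M_time"] - 1),
               tolerance = 1e-4)
})

test_that("simulator failures are flagged, not dropped", {
  spec <- default_surrogate_spec(c("k1", "k2"), dominant = "k1")
  base_engine <- surrogate_engine(spec)
  flaky <- function(perturb, g, seed) {
    if (!is.null(perturb) && names(perturb) == "k2" && perturb == 5)
      stop("boom")
    base_engine(perturb, g, seed)
  }
  sw <- run_lsa(flaky, c("k1", "k2"), factors = c(0.5, 5),
                glucose_levels = 0.3, replicates = 1)
  expect_equal(nrow(sw), 4)
  bad <- sw$param == "k2" & sw$factor == 5
  expect_false(any(sw$ok[bad]))
  expect_true(all(sw$ok[!bad]))
  expect_true(all(is.na(sw$S_time[bad])))
})

test_that("summaries take the absolute maximum with its glucose level", {
  rec <- data.frame(param = "k1", factor = c(2, 5), glucose0 = c(0.3, 4.5),
                    S_time = c(2, -5), S_total = c(1, 2),
                    S_mig = c(0, 1), S_prolif = c(-3, 1), ok = TRUE)
  sm <- summarize_max(rec)
  expect_equal(sm$m_time, 5)
  expect_equal(sm$g_time, 4.5)
  expect_equal(sm$m_prolif, 3)
  expect_equal(sm$g_prolif, 0.3)
  expect_error(summarize_max(rec[0, ]), "no sweep records")
})

test_that("surrogate weight ranking is recovered by the summary", {
  params <- paste0("k", c(1, 2, 3, 4, 5))
  spec <- default_surrogate_spec(params, dominant = "k3")
  sw <- run_lsa(surrogate_engine(spec), params, factors = c(0.5, 2),
                glucose_levels = c(0.3, 4.5), replicates = 1)
  sm <- summarize_max(sw)
  for (e in c("m_time", "m_total", "m_mig", "m_prolif"))
    expect_equal(sm$param[which.max(sm[[e]])], "k3")
})

test_that("group selection applies the printed thresholds per level", {
  rec <- data.frame(
    param = c("a", "a", "b", "b"), factor = c(50, 0.01, 100, 10),
    glucose0 = c(0.3, 4.5, 0.3, 4.5),
    dM_time = c(9.5, 0, 8.9, 0), dM_total = c(0, -0.85, 0, -0.5),
    ok = TRUE)
  g <- select_groups(rec)
  expect_equal(g$param[g$group == "plus"], "a")
  expect_equal(g$factor[g$group == "plus"], 50)
  expect_equal(g$param[g$group == "minus"], "a")
  expect_error(select_groups(rec[rec$glucose0 == 0.3, ]), "no records")
  ## all-zero deltas select nothing
  rec$dM_time <- 0; rec$dM_total <- 0
  expect_equal(nrow(select_groups(rec)), 0)
})

test_that("pair enumeration crosses groups and excludes same-parameter", {
  g <- data.frame(param = c("a", "a", "b", "b", "b"),
                  group = c("plus", "minus", "plus", "minus", "minus"),
                  factor = c(2, 0.5, 10, 0.1, 0.01))
  pairs <- enumerate_pairs(g)
  ## brute force oracle
  plus <- g[g$group == "plus", ]; minus <- g[g$group == "minus", ]
  expected <- 0
  for (i in seq_len(nrow(plus)))
    for (j in seq_len(nrow(minus)))
      if (plus$param[i] != minus$param[j]) expected <- expected + 1
  expect_equal(nrow(pairs), expected)
  expect_true(all(pairs$param1 != pairs$param2))
  ## one parameter with only its own entries pairs with nothing
  solo <- data.frame(param = "a", group = c("plus", "minus"),
                     factor = c(2, 0.5))
  expect_equal(nrow(enumerate_pairs(solo)), 0)
  ## disjoint parameters give the full product
  dis <- data.frame(param = c("a", "a", "b", "b", "b"),
                    group = c("plus", "plus", "minus", "minus", "minus"),
                    factor = c(2, 10, 0.5, 0.1, 0.01))
  expect_equal(nrow(enumerate_pairs(dis)), 6)
})

test_that("pair screening applies the margin and the every-level filter", {
  rec <- expand.grid(glucose0 = c(1.125, 2.25, 4.5), pair = 1:3)
  rec$param1 <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  rec$factor1 <- 50
  rec$param2 <- "z"; rec$factor2 <- 0.01
  rec$dM_time <- c(0.02, 0.02, 0.02,  0.005, 0.02, 0.02,  0.02, 0.02, 0.02)
  rec$dM_total <- c(-0.02, -0.02, -0.02,  -0.5, -0.5, -0.5,
                    -0.02, -0.02, -0.005)
  out <- screen_pairs(rec, margin = 0.01)
  expect_true(all(out$per_level$dM_time > 0.01))
  expect_true(all(out$per_level$dM_total < -0.01))
  expect_equal(out$all_levels$param1, "a")  # only pair 1 passes everywhere
  ## boundary examples of the margin rule
  one <- data.frame(param1 = "a", factor1 = 2, param2 = "b", factor2 = 3,
                    glucose0 = 4.5, dM_time = 0.02, dM_total = -0.02)
  expect_equal(nrow(screen_pairs(one, 0.01)$per_level), 1)
  one$dM_time <- 0.005; one$dM_total <- -0.5
  expect_equal(nrow(screen_pairs(one, 0.01)$per_level), 0)
})

test_that("coefficient sign, antisymmetry and magnitude properties hold", {
  set.seed(99)
  n <- 1500
  M <- runif(n, 1, 1e3)
  b <- c(runif(n / 2, 0.01, 0.99), runif(n / 2, 1.01, 100))
  Mp <- M * exp(runif(n, -1, 1))
  S <- sensitivity_coefficient(Mp, M, b)
  same_dir <- (b < 1 & Mp < M) | (b > 1 & Mp > M)
  opp_dir <- (b < 1 & Mp > M) | (b > 1 & Mp < M)
  expect_true(all(S[same_dir] > 0))
  expect_true(all(S[opp_dir] < 0))
  ## antisymmetry: b1 - 1 = 1 - b2 with equal outputs flips the sign
  b1 <- runif(500, 1.01, 1.9)
  b2 <- 2 - b1
  Meq <- runif(500, 10, 100) * exp(runif(500, -0.5, 0.5))
  Mb <- runif(500, 10, 100)
  expect_equal(sensitivity_coefficient(Meq, Mb, b1),
               -sensitivity_coefficient(Meq, Mb, b2), tolerance = 1e-12)
  ## magnitude: equal increased outputs, 1 < b1 < b2 gives S(b1) > S(b2)
  b1 <- runif(500, 1.01, 5)
  b2 <- b1 + runif(500, 0.01, 20)
  Mb <- runif(500, 10, 100)
  Mup <- Mb * exp(runif(500, 0.01, 1))
  expect_true(all(sensitivity_coefficient(Mup, Mb, b1) >
                    sensitivity_coefficient(Mup, Mb, b2)))
})
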
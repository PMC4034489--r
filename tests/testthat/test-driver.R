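test_that("an empty world evolves glucose only", {
  cfg <- simulation_config(glucose0 = 1, n_side = 15, radius = 0,
                           seed = 1, max_steps = 5,
                           thresholds = structure(
                             list(theta_A = 1, theta_M = 1),
                             class = "gs_thresholds"))
  w <- make_world(15, cbind(8, 8), "QUIESCENT", matrix(1, 15, 15))
  w$agents <- structure(list(row = integer(), col = integer(),
                             phenotype = character(), clock = integer(),
                             mol = matrix(0, 0, 9)),
                        class = "gs_agents")
  w$occupancy[] <- FALSE
  w2 <- sim_step(w, cfg)
  expect_equal(length(w2$agents$row), 0)
  expect_equal(w2$step, 1L)
  expect_equal(w2$glucose$values, w$glucose$values)  # uniform, no cells
})

test_that("identical configuration and seed give identical trajectories", {
  thr <- calibrate_thresholds()
  cfg <- simulation_config(glucose0 = 0.3, n_side = 24, radius = 2,
                           seed = 5, thresholds = thr, max_steps = 50)
  a <- run_simulation(cfg, keep_world = TRUE)
  b <- run_simulation(cfg, keep_world = TRUE)
  expect_identical(a, b)
  wa <- attr(a, "world")
  expect_identical(wa$agents, attr(b, "world")$agents)
  expect_identical(wa$glucose$values, attr(b, "world")$glucose$values)
})

test_that("phenotype counts partition the final population", {
  thr <- calibrate_thresholds()
  cfg <- simulation_config(glucose0 = 2.25, n_side = 24, radius = 2,
                           seed = 3, thresholds = thr, max_steps = 40)
  ep <- run_simulation(cfg, keep_world = TRUE)
  w <- attr(ep, "world")
  phen <- w$agents$phenotype
  expect_equal(ep$M_total, length(phen))
  expect_equal(ep$M_mig + ep$M_prolif +
                 sum(phen == "QUIESCENT"), ep$M_total)
  expect_lte(ep$M_mig + ep$M_prolif, ep$M_total)
})

test_that("a seed touching the boundary terminates at step zero", {
  thr <- structure(list(theta_A = 1, theta_M = 1),
                   class = "gs_thresholds")
  cfg <- simulation_config(glucose0 = 0.3, n_side = 9, radius = 4,
                           seed = 1, thresholds = thr, max_steps = 10)
  ep <- run_simulation(cfg)
  expect_equal(ep$M_time, 0L)
  expect_equal(ep$terminated_by, "boundary")
  expect_equal(ep$M_total, disc_count(4))
})

test_that("the step cap is reported as a termination cause, not an error", {
  thr <- calibrate_thresholds()
  cfg <- simulation_config(glucose0 = 4.5, n_side = 40, radius = 2,
                           seed = 2, thresholds = thr, max_steps = 3)
  ep <- run_simulation(cfg)
  expect_equal(ep$M_time, 3L)
  expect_equal(ep$terminated_by, "cap")
})

test_that("one step at uniform high glucose produces no migrating cells", {
  thr <- calibrate_thresholds()
  cfg <- simulation_config(glucose0 = 4.5, n_side = 30, radius = 3,
                           seed = 4, thresholds = thr, max_steps = 5)
  set.seed(cfg$seed)
  w <- init_world(cfg)
  expect_false(any(w$agents$phenotype == "MIGRATING"))
  w <- sim_step(w, cfg)
  expect_false(any(w$agents$phenotype == "MIGRATING"))
  expect_true(all(w$agents$phenotype %in%
                    c("PROLIFERATING", "QUIESCENT")))
})

test_that("agent count never decreases along a run", {
  thr <- calibrate_thresholds()
  cfg <- simulation_config(glucose0 = 4.5, n_side = 24, radius = 2,
                           seed = 6, thresholds = thr, max_steps = 60)
  set.seed(cfg$seed)
  w <- init_world(cfg)
  n <- length(w$agents$row)
  for (k in 1:30) {
    w <- sim_step(w, cfg)
    n2 <- length(w$agents$row)
    expect_gte(n2, n)
    n <- n2
  }
  expect_no_error(validate_world(w))
})

test_that("replicate seeds derive from the base by a fixed rule", {
  expect_equal(replicate_seeds(100, 3), c(101L, 102L, 103L))
})

test_that("the agent-based engine applies perturbations to its parameters", {
  thr <- calibrate_thresholds()
  tmpl <- simulation_config(glucose0 = 0.3, n_side = 20, radius = 2,
                            thresholds = thr, max_steps = 30)
  engine <- abm_engine(tmpl)
  ep <- engine(NULL, 0.3, 7)
  expect_s3_class(ep, "gs_endpoints")
  expect_gte(ep$M_total, disc_count(2))
  ep2 <- engine(c(k4 = 2), 0.3, 7)
  expect_s3_class(ep2, "gs_endpoints")
})

test_that("run records and config documents serialise", {
  thr <- structure(list(theta_A = 1, theta_M = 1),
                   class = "gs_thresholds")
  cfg <- simulation_config(glucose0 = 0.3, n_side = 9, radius = 4,
                           thresholds = thr)
  ep <- run_simulation(cfg)
  rec <- run_record(cfg, ep)
  parts <- strsplit(rec, "\t")[[1]]
  expect_length(parts, 8)
  expect_equal(as.integer(parts[4]), ep$M_time)
  path <- tempfile()
  write_config(cfg, path)
  lines <- readLines(path)
  expect_true(any(grepl("^glucose0\t0.3$", lines)))
  expect_true(any(grepl("^param.k4\t", lines)))
})

test_that("trajectory snapshots encode phenotypes as Q/M/P", {
  w <- make_world(9, rbind(c(2, 2), c(3, 3)),
                  c("MIGRATING", "PROLIFERATING"), matrix(1, 9, 9))
  path <- tempfile()
  write_snapshot(w, path)
  df <- read.delim(path)
  expect_equal(df$phenotype, c("M", "P"))
  expect_equal(df$step, c(0, 0))
  w$step <- 1L
  write_snapshot(w, path, append = TRUE)
  expect_equal(nrow(read.delim(path)), 4)
})
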
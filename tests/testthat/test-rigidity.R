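test_that("instant rigidity formulas match hand arithmetic", {
  expect_equal(rigidity_compression(100, 2), 50)      # N/mm
  expect_equal(rigidity_compression(0, 2), 0)
  expect_error(rigidity_compression(10, 0), "zero displacement")
  expect_equal(rigidity_torsion(10, 0.2, angle_rad = 0.1, variant = "angle"), 20)
  expect_equal(rigidity_torsion(10, 0.2, displacement_mm = 4, variant = "shift"), 0.5)
  expect_error(rigidity_torsion(10, 0.2, angle_rad = 0, variant = "angle"),
               "zero denominator")
  expect_equal(rigidity_bending(20, 0.15, angle_rad = 0.05, variant = "angle"), 60)
  # odd symmetry: reversed load and angle give the same magnitude
  expect_equal(rigidity_bending(-20, 0.15, angle_rad = -0.05, variant = "angle"), 60)
  expect_error(rigidity_bending(5, -1, angle_rad = 0.1), "arm")
  # random steps against a direct re-evaluation
  set.seed(3)
  for (i in 1:10) {
    f <- runif(1, 5, 200); r <- runif(1, 0.05, 0.4); d <- runif(1, 0.1, 8)
    expect_equal(rigidity_torsion(f, r, displacement_mm = d), f * r / d,
                 tolerance = 1e-12)
  }
})

test_that("step aggregation averages the configured number of readings", {
  r <- data.frame(mode = "compression", step = 1L,
                  force_N = c(10, 12, 14), displacement_mm = 2)
  agg <- aggregate_steps(r, n_avg = 3)
  expect_equal(agg$force_N, 12)
  expect_equal(agg$n_readings_averaged, 3L)
  # n_avg = 1 passes the first reading through
  expect_equal(aggregate_steps(r, n_avg = 1)$force_N, 10)
  expect_error(aggregate_steps(r, n_avg = 5), "fewer than")
  # voltages route through the calibration
  fit <- fit_linear(data.frame(voltage = 0:2, force = c(0, 100, 200)))
  rv <- data.frame(mode = "compression", step = 1L,
                   voltage = c(0.5, 0.5), displacement_mm = 1)
  expect_equal(aggregate_steps(rv, n_avg = 2, fit = fit)$force_N, 50)
  expect_error(aggregate_steps(rv, n_avg = 1), "calibration")
})

test_that("averaging n readings shrinks force noise like 1/sqrt(n)", {
  # Monte-Carlo vs the closed form, within 20%
  set.seed(202)
  n_avg <- 4L; sigma <- 3; n_trials <- 200L
  means <- replicate(n_trials, {
    r <- data.frame(mode = "compression", step = 1L,
                    force_N = 100 + rnorm(n_avg, 0, sigma),
                    displacement_mm = 2)
    aggregate_steps(r, n_avg = n_avg)$force_N
  })
  expect_lt(abs(sd(means) - sigma / sqrt(n_avg)) / (sigma / sqrt(n_avg)), 0.2)
})

test_that("run_protocol recovers programmed stiffness within 2%", {
  arms <- c(bending = 0.15, torsion = 0.2)
  specs <- list(
    list(mode = "compression", k = 80, arm = NULL),
    list(mode = "flexion", k = 3, arm = 0.15),
    list(mode = "torsion_left", k = 1.5, arm = 0.2)
  )
  steps <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    simulate_load_steps(s$mode, s$k, forces = seq(60, 120, by = 12),
                        arm_m = s$arm, repeats = 10, seed = 40 + i)
  }))
  res <- run_protocol(steps, arms = arms, variant = "shift")
  expect_equal(sort(names(res)), sort(sapply(specs, `[[`, "mode")))
  for (s in specs)
    expect_lt(abs(res[[s$mode]]$mean - s$k) / s$k, 0.02)
  expect_equal(res$compression$units, "N/mm")
  expect_equal(res$flexion$units, "Nm/mm")
})

test_that("protocol summaries behave on repeats, and modes can be absent", {
  st <- simulate_load_steps("compression", 50, forces = c(50, 100),
                            repeats = 10, noise_sd = 0)
  res <- run_protocol(st)
  expect_equal(res$compression$sd, 0)        # identical repeats
  expect_equal(res$compression$n_repeats, 10L)
  expect_message(run_protocol(st, expect_modes = c("compression", "flexion")),
                 "flexion")
  # doubling every force doubles every rigidity value exactly
  st2 <- st; st2$force_N <- 2 * st2$force_N
  res2 <- run_protocol(st2)
  expect_equal(res2$compression$values$rigidity,
               2 * res$compression$values$rigidity)
  expect_error(run_protocol(transform(st, mode = "sideways")), "unknown")
})

test_that("angle and shift variants carry their own units and checks", {
  st <- data.frame(mode = "torsion_right", rep = 1L, step = 1:3,
                   force_N = c(10, 20, 30), displacement_mm = NA_real_,
                   angle_rad = c(0.05, 0.1, 0.15), arm_m = 0.2)
  res <- run_protocol(st, variant = "angle")
  expect_equal(res$torsion_right$units, "Nm/rad")
  expect_equal(res$torsion_right$values$rigidity, rep(40, 3))
  # shift variant on angle-only data is rejected
  expect_error(run_protocol(st, variant = "shift"), "displacement_mm")
  # missing arm with no default
  st$arm_m <- NA_real_
  expect_error(run_protocol(st, variant = "angle"), "arm")
})

test_that("normalization to the intact specimen is exact and type-safe", {
  st <- simulate_load_steps("flexion", 3, forces = c(50, 100), arm_m = 0.15,
                            repeats = 3, noise_sd = 0)
  intact <- run_protocol(st, variant = "shift")
  expect_equal(normalize_to_intact(intact$flexion, intact$flexion), 100)
  # a 12% stiffer treated specimen reads 112%
  st2 <- st
  st2$displacement_mm <- st2$displacement_mm / 1.12
  treated <- run_protocol(st2, variant = "shift")
  expect_equal(normalize_to_intact(intact$flexion, treated$flexion), 112,
               tolerance = 1e-9)
  tab <- normalize_to_intact(intact, treated)
  expect_equal(tab$percent, 112, tolerance = 1e-9)
  # unit/mode mismatches are rejected
  stc <- simulate_load_steps("compression", 50, forces = c(50, 100),
                             repeats = 3, noise_sd = 0)
  comp <- run_protocol(stc)
  expect_error(normalize_to_intact(intact$flexion, comp$compression),
               "mismatch")
  zero <- intact$flexion
  zero$mean <- 0
  expect_error(normalize_to_intact(zero, intact$flexion), "zero")
})
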
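test_that("zero-phase Butterworth filter preserves DC and attenuates", {
  expect_equal(lowpass_filter(rep(3.5, 200), fs = 1000), rep(3.5, 200),
               tolerance = 1e-9)
  imp <- c(rep(0, 500), 1, rep(0, 500))
  expect_equal(sum(lowpass_filter(imp, 1000)), 1, tolerance = 1e-6)
  t <- seq(0, 1, by = 1 / 1000)
  hi <- sin(2 * pi * 50 * t)
  out <- lowpass_filter(hi, 1000)
  atten_db <- 20 * log10(max(abs(out[200:800])))
  expect_lt(atten_db, -20)
  # passband signal survives (5 Hz well under the 15 Hz cutoff)
  lo <- sin(2 * pi * 5 * t)
  expect_gt(max(abs(lowpass_filter(lo, 1000)[200:800])), 0.9)
  expect_error(lowpass_filter(1:5, 1000), "too short")
})

test_that("grip/load composition follows the two-sensor definition", {
  tr <- list(samples = data.frame(t = 0:2 / 1000,
                                  fyA = c(2, 2, 2), fyB = c(4, 4, 4),
                                  fzA = c(1, 1, 1), fzB = c(1, 1, 1)))
  comp <- compose_gf_lf(tr)
  expect_equal(comp$gf, rep(3, 3))
  expect_equal(comp$lf, rep(2, 3))
  # all-zero trace and symmetry
  z <- list(samples = data.frame(t = 0:2, fyA = 0, fyB = 0, fzA = 0, fzB = 0))
  expect_equal(compose_gf_lf(z)$gf, rep(0, 3))
  s <- list(samples = data.frame(t = 0:2, fyA = c(1, 2, 3), fyB = c(1, 2, 3),
                                 fzA = 0, fzB = 0))
  expect_equal(compose_gf_lf(s)$gf, c(1, 2, 3))
  bad <- list(samples = list(fyA = 1:3, fyB = 1:2, fzA = 1:3, fzB = 1:3))
  expect_error(compose_gf_lf(bad), "mismatch")
})

test_that("threshold crossings on ramps match analytic times", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  ramp <- 10 * t
  ev <- detect_events(gf = ramp, lf = ramp, fs = fs, object_weight = 2.2)
  expect_equal(ev$t_gf_onset, 0.010)
  expect_equal(ev$t_contact_trigger, 0.040)
  expect_equal(ev$t_liftoff, 0.220)
  expect_true(ev$lifted)
  # never-lifted trace
  ev2 <- detect_events(gf = ramp, lf = rep(0, length(t)), fs = fs,
                       object_weight = 2.2)
  expect_false(ev2$lifted)
  expect_true(is.na(ev2$t_liftoff))
  # a sub-debounce blip does not count as onset
  blip <- rep(0, 1000); blip[100:104] <- 1; blip[500:1000] <- 1
  ev3 <- detect_events(gf = blip, lf = blip, fs = fs, object_weight = 0.5)
  expect_equal(ev3$t_gf_onset, 0.499)
})

test_that("central-difference rates match analytic derivatives", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  r <- compute_rates(gf = 5 * t, lf = 2 * t, fs = fs)
  n <- length(t)
  expect_equal(r$gfr[2:(n - 1)], rep(5, n - 2))
  expect_equal(r$lfr[2:(n - 1)], rep(2, n - 2))
  expect_equal(compute_rates(rep(1, 100), rep(1, 100), fs)$gfr, rep(0, 100))
  s <- sin(2 * pi * t)
  d <- compute_rates(s, s, fs)$gfr
  expect_lt(max(abs(d[2:(n - 1)] - 2 * pi * cos(2 * pi * t[2:(n - 1)]))),
            1e-3)
  expect_error(compute_rates(1:2, 1:2, fs), "at least 3")
})

# build a trace whose load-force rate is a sequence of triangular pulses of
# given heights, to exercise the peak / first-peak selection rules
rate_pulse_trace <- function(heights, fs = 1000) {
  rate <- c(rep(0, 50))
  for (h in heights) {
    rate <- c(rate, seq(0, h, length.out = 100), seq(h, 0, length.out = 100),
              rep(0, 50))
  }
  lf <- cumsum(rate) / fs
  lf <- c(lf, rep(tail(lf, 1), 1200))
  rate <- c(rate, rep(0, 1200))
  list(lf = lf, rate = rate, fs = fs)
}

test_that("first-peak selection applies the 30% rule", {
  fs <- 1000
  mk_events <- function(n, liftoff) {
    structure(list(t_gf_onset = 0, t_lf_onset = 0,
                   t_contact_trigger = NA_real_, t_liftoff = liftoff,
                   lifted = TRUE), class = "ll_lift_events")
  }
  tr <- rate_pulse_trace(c(4, 10))
  ev <- mk_events(length(tr$lf), 0.55)
  m <- extract_metrics(tr$lf, tr$lf, tr$rate, tr$rate, ev, fs)
  expect_equal(m$peak_LFR, 10)
  expect_equal(m$peak1_LFR, 4)   # 4 >= 0.3 * 10 -> first peak wins
  tr2 <- rate_pulse_trace(c(2, 10))
  m2 <- extract_metrics(tr2$lf, tr2$lf, tr2$rate, tr2$rate, ev, fs)
  expect_equal(m2$peak1_LFR, 10) # 2 < 0.3 * 10 -> skipped
  expect_true(m2$peak1_LFR <= m2$peak_LFR)
  expect_gte(m2$tp_LFR, 0)
  # time to peak measured from GF onset to the global maximum
  expect_equal(m$tp_LFR, which.max(tr$rate[1:(0.6 * fs)]) / fs - 1 / fs)
})

test_that("static grip force averages the 600-800 ms hold window", {
  fs <- 1000
  gf <- rep(5, 2500)
  lf <- c(seq(0, 3, length.out = 500), rep(3, 2000))
  ev <- structure(list(t_gf_onset = 0.01, t_lf_onset = 0.02,
                       t_contact_trigger = NA_real_, t_liftoff = 0.4,
                       lifted = TRUE), class = "ll_lift_events")
  rates <- compute_rates(gf, lf, fs)
  m <- extract_metrics(gf, lf, rates$gfr, rates$lfr, ev, fs)
  expect_equal(m$gf_static, 5)
  # trace ending before liftoff + 800 ms raises
  ev_late <- structure(list(t_gf_onset = 0.01, t_lf_onset = 0.02,
                            t_contact_trigger = NA_real_, t_liftoff = 2.0,
                            lifted = TRUE), class = "ll_lift_events")
  expect_error(extract_metrics(gf, lf, rates$gfr, rates$lfr, ev_late, fs),
               "ends before")
})

test_that("TMS pulse schedules follow the burst rules", {
  ev <- structure(list(t_contact_trigger = 1.0, t_liftoff = 2.0,
                       lifted = TRUE), class = "ll_lift_events")
  expect_equal(schedule_tms(ev, "dynamic"), c(1.0, 1.1, 1.2))
  expect_equal(schedule_tms(ev, "static"), c(2.5, 2.6, 2.7))
  expect_equal(schedule_tms(ev, "none"), numeric(0))
  ev_na <- structure(list(t_contact_trigger = NA_real_, t_liftoff = NA_real_),
                     class = "ll_lift_events")
  expect_error(schedule_tms(ev_na, "dynamic"), "contact")
  expect_error(schedule_tms(ev_na, "static"), "liftoff")
  expect_error(schedule_tms(ev, "sometimes"), "unknown")
})

test_that("exclusion rules split perceptual and force sets correctly", {
  base <- data.frame(analyzable = rep(TRUE, 120),
                     tms_failed = FALSE, not_lifted = FALSE,
                     multiple_lifts = FALSE, dropped = FALSE,
                     data_failure = FALSE)
  ex <- apply_exclusions(base)
  expect_equal(sum(ex$perceptual), 120)
  expect_equal(sum(ex$force), 120)

  tf <- base; tf$tms_failed[1] <- TRUE
  ex <- apply_exclusions(tf)
  expect_equal(c(sum(ex$perceptual), sum(ex$force)), c(119, 119))

  dr <- base; dr$dropped[1] <- TRUE
  ex <- apply_exclusions(dr)
  expect_equal(c(sum(ex$perceptual), sum(ex$force)), c(120, 119))

  na <- base; na$analyzable[1:5] <- FALSE
  ex <- apply_exclusions(na)
  expect_equal(c(sum(ex$perceptual), sum(ex$force)), c(115, 115))

  # force exclusions are a superset of perceptual exclusions
  set.seed(1)
  rnd <- base
  for (f in c("tms_failed", "not_lifted", "multiple_lifts", "dropped"))
    rnd[[f]] <- runif(120) < 0.2
  ex <- apply_exclusions(rnd)
  expect_true(all(ex$force <= ex$perceptual))
})

test_that("peak extraction agrees with the brute-force oracle on traces", {
  set.seed(42)
  pairs <- list(c("light", "light"), c("heavy", "light"),
                c("light", "heavy"), c("heavy", "heavy"))
  for (i in 1:40) {
    pr <- pairs[[sample.int(4, 1)]]
    p <- sim_params(noise_sd_force = runif(1, 0, 0.1))
    sim <- simulate_trial(pr[2], pr[1],
                          sample(c("dynamic", "static", "none"), 1),
                          sample(c("aIPS", "LO"), 1), p)
    comp <- compose_gf_lf(sim$trace)
    gf <- lowpass_filter(comp$gf, p$fs)
    lf <- lowpass_filter(comp$lf, p$fs)
    ev <- detect_events(gf, lf, p$fs, object_weight(pr[2]))
    if (!ev$lifted) next
    rates <- compute_rates(gf, lf, p$fs)
    m <- extract_metrics(gf, lf, rates$gfr, rates$lfr, ev, p$fs)
    i0 <- round(ev$t_gf_onset * p$fs) + 1
    i1 <- min(length(lf), round((ev$t_liftoff + 0.05) * p$fs) + 1)
    o_l <- oracle_peaks(rates$lfr, i0, i1)
    o_g <- oracle_peaks(rates$gfr, i0, i1)
    expect_equal(m$peak_LFR, o_l$peak)
    expect_equal(m$peak1_LFR, o_l$first)
    expect_equal(m$peak_GFR, o_g$peak)
    expect_equal(m$peak1_GFR, o_g$first)
  }
})

test_that("noiseless liftoff detection matches simulator ground truth", {
  set.seed(9)
  p <- quiet_params()
  pairs <- list(c("light", "light"), c("heavy", "light"),
                c("light", "heavy"), c("heavy", "heavy"))
  for (pr in pairs) {
    sim <- simulate_trial(pr[2], pr[1], params = p)
    an <- analyze_trace(sim$trace, object_weight(pr[2]))
    expect_lte(abs(an$events$t_liftoff - sim$truth$t_liftoff), 2e-3 + 1e-9)
  }
})
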
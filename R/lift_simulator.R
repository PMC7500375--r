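#' Simulation parameters for synthetic grasp-and-lift trials
#'
#' Returns the default parameter set of the trace generator, optionally
#' overridden.  Defaults encode the physical constants of the experimental
#' setup (object masses in grams on a 120 g manipulandum, 1 kHz sampling)
#' and a generative model in which the planned peak load-force rate is
#' proportional to the expected weight, expectation being a convex mixture of
#' the previous and current object's weight (`memory_weight` is the fraction
#' taken from the previous lift, i.e. the strength of the sensorimotor
#' memory).
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `ll_sim_params`:
#' \describe{
#'   \item{fs}{sampling rate, Hz (1000)}
#'   \item{gravity}{m/s^2 (9.81)}
#'   \item{cube_masses}{g: light 105, heavy 525, medium 317, practice 260}
#'   \item{manipulandum_mass}{g (120)}
#'   \item{memory_weight}{fraction of expectation from previous weight (1)}
#'   \item{lfr_gain}{planned peak LFR per N of expected weight (7 /s)}
#'   \item{gf_lf_ratio}{grip-to-load coupling ratio (1.3)}
#'   \item{safety_margin}{N of grip force above the coupled level (0.45)}
#'   \item{correction_gain}{scaling of the corrective second loading pulse on
#'     under-scaled trials (0.85)}
#'   \item{reaction_latency, brake_latency, gf_lead, reach_delay,
#'     reach_jitter, settle_time}{timing constants of the lift, s}
#'   \item{overshoot}{transient N above weight at the end of loading (0.3)}
#'   \item{tms_effects}{list: `d_pGFR_dynamic` extra grip-rate drive under
#'     dynamic TMS for both groups (4 N/s); `d_pLFR_dynamic_LO_heavy` extra
#'     load-rate drive for the LO group, dynamic TMS, heavy objects (6 N/s);
#'     `d_percept_static_heavy` signed weight-report shift (internal newton
#'     scale) for static TMS on heavy objects (-0.1)}
#'   \item{percept_prev_gain}{report decrement per N of previous weight above
#'     the light/heavy midpoint (0.0375)}
#'   \item{noise_sd_force}{per-channel force noise SD, N (0.05)}
#'   \item{noise_sd_report}{report noise SD on the internal newton scale (0.2)}
#'   \item{participant_scale_range, participant_offset_range}{uniform ranges
#'     for the self-chosen report scale}
#'   \item{artifact_probs}{list `p_drop`, `p_multilift`, `p_tms_fail`}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    fs = 1000,
    gravity = 9.81,
    cube_masses = c(light = 105, heavy = 525, medium = 317, practice = 260),
    manipulandum_mass = 120,
    memory_weight = 1.0,
    lfr_gain = 7,
    gf_lf_ratio = 1.3,
    safety_margin = 0.45,
    correction_gain = 0.85,
    overshoot = 0.3,
    reaction_latency = 0.1,
    brake_latency = 0.05,
    gf_lead = 0.05,
    reach_delay = 0.35,
    reach_jitter = 0.1,
    settle_time = 0.15,
    tms_effects = list(
      d_pGFR_dynamic = 4,
      d_pLFR_dynamic_LO_heavy = 6,
      d_percept_static_heavy = -0.1
    ),
    percept_prev_gain = 0.0375,
    noise_sd_force = 0.05,
    noise_sd_report = 0.2,
    participant_scale_range = c(0.5, 3),
    participant_offset_range = c(0, 2),
    artifact_probs = list(p_drop = 0.002, p_multilift = 0.002,
                          p_tms_fail = 0.003)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (is.list(p[[nm]]) && is.list(dots[[nm]])) {
        p[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        p[[nm]] <- dots[[nm]]
      }
    }
  }
  ap <- unlist(p$artifact_probs)
  stopifnot(all(ap >= 0), all(ap <= 1), p$memory_weight >= 0,
            p$memory_weight <= 1, all(p$cube_masses >= 0), p$lfr_gain > 0)
  class(p) <- "ll_sim_params"
  p
}

#' Total weight (N) of an object on the manipulandum
#'
#' `(cube mass + manipulandum mass) / 1000 * gravity`; the light and heavy
#' objects weigh 2.207 and 6.327 N with the default masses.
#'
#' @param object object label (`light`, `heavy`, `medium`, `practice`).
#' @param params an [sim_params()] list.
#' @export
object_weight <- function(object, params = sim_params()) {
  m <- params$cube_masses[object]
  if (any(is.na(m))) stop("undefined object mass for: ",
                          paste(object[is.na(m)], collapse = ", "))
  unname((m + params$manipulandum_mass) / 1000 * params$gravity)
}

# minimum-jerk position profile on tau in [0, 1]
mjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# symmetric up-down bump of unit amplitude over [0, Tb]; returns values at t
mj_bump <- function(t, t0, Tb) {
  up <- mjerk((t - t0) / (Tb / 2))
  down <- 1 - mjerk((t - t0 - Tb / 2) / (Tb / 2))
  ifelse(t < t0 + Tb / 2, up, down) * as.numeric(t >= t0 & t <= t0 + Tb)
}

# peak rate of a minimum-jerk excursion of amplitude A over duration T
MJ_PEAK <- 1.875   # max of d/dtau (10 tau^3 - 15 tau^4 + 6 tau^5)

#' Simulate one grasp-and-lift trial
#'
#' Generates the two-sensor force trace and the raw weight report for a
#' single trial.  Load force rises as one minimum-jerk pulse whose peak rate
#' is `lfr_gain` times the expected weight (a `memory_weight` mixture of the
#' previous and current weight).  When the expectation falls short of the
#' true weight the pulse stalls below liftoff and a corrective second pulse
#' (peak rate `correction_gain * lfr_gain * weight`) follows after a reaction
#' latency, producing the characteristic double peak in the load-force rate.
#' When the expectation exceeds the true weight the pulse is truncated at
#' liftoff.  Grip force leads load force by `gf_lead` seconds and then tracks
#' it as `gf_lf_ratio * LF + safety_margin`.  TMS perturbations are injected
#' as extra rate drive during loading (grip: dynamic TMS, both groups; load:
#' dynamic TMS, LO group, heavy objects) or as a report shift (static TMS,
#' heavy objects).
#'
#' Uses the current R random number generator state; seed upstream for
#' reproducibility.
#'
#' @param object current object label.
#' @param prev_object previous object label, or `NA` for the first trial
#'   (expectation then defaults to the true weight).
#' @param tms_condition `"dynamic"`, `"static"` or `"none"`.
#' @param group participant group, `"aIPS"` or `"LO"`.
#' @param params an [sim_params()] list.
#' @param participant_scale,participant_offset self-chosen report scale.
#' @return a list with elements `trace` (class `ll_force_trace`: `fs`,
#'   `samples` data frame `t, fxA, fyA, fzA, fxB, fyB, fzB`, and `meta`),
#'   `percept` (`raw_estimate`), `truth` (noiseless `t_liftoff`, `lf_plateau`,
#'   planned peak rates) and `flags` (`dropped`, `multiple_lifts`,
#'   `tms_failed`).
#' @export
simulate_trial <- function(object, prev_object = NA, tms_condition = "none",
                           group = "aIPS", params = sim_params(),
                           participant_scale = 1, participant_offset = 0) {
  stopifnot(tms_condition %in% ll_conditions, group %in% c("aIPS", "LO"))
  W <- object_weight(object, params)
  W_prev <- if (is.na(prev_object)) W else object_weight(prev_object, params)
  W_exp <- params$memory_weight * W_prev + (1 - params$memory_weight) * W

  fs <- params$fs
  ov <- params$overshoot
  target1 <- W_exp + ov          # planned loading endpoint
  stop_lvl <- W + ov             # where loading actually ends
  r1 <- params$lfr_gain * W_exp
  T1 <- MJ_PEAK * target1 / r1

  t_gf <- params$reach_delay + stats::runif(1, 0, params$reach_jitter)
  t0 <- t_gf + params$gf_lead    # LF onset

  # segment bookkeeping: last full (untruncated) loading pulse drives the
  # TMS bump placement
  settle_rate <- 0
  if (target1 > stop_lvl + 1e-12) {
    # over-scaled: braking starts one feedback delay after the load force
    # passes the stop level, carrying the instantaneous rate into the
    # braking segment (so the planned rate peak is genuinely reached)
    tau_tr <- stats::uniroot(function(x) mjerk(x) - stop_lvl / target1,
                             c(0, 1), tol = 1e-12)$root
    tau_s <- min(tau_tr + params$brake_latency / T1, 1)
    t_settle0 <- t0 + tau_s * T1
    settle_rate <- target1 / T1 * 30 * (tau_s^2 - 2 * tau_s^3 + tau_s^4)
    corrective <- FALSE
    pulse_t0 <- t0; pulse_T <- T1; pulse_full <- FALSE
  } else if (target1 < stop_lvl - 1e-12) {
    # under-scaled: full pulse A, plateau, corrective pulse B
    r2 <- params$correction_gain * params$lfr_gain * W
    T2 <- MJ_PEAK * (stop_lvl - target1) / r2
    t_b0 <- t0 + T1 + params$reaction_latency
    t_settle0 <- t_b0 + T2
    corrective <- TRUE
    pulse_t0 <- t_b0; pulse_T <- T2; pulse_full <- TRUE
  } else {
    t_settle0 <- t0 + T1
    corrective <- FALSE
    pulse_t0 <- t0; pulse_T <- T1; pulse_full <- TRUE
  }
  Ts <- params$settle_time
  t_plateau <- t_settle0 + Ts

  t_end <- max(t_plateau + 1.4, 2.2)
  t <- seq(0, t_end, by = 1 / fs)

  lf <- numeric(length(t))
  a <- t >= t0 & t < t0 + T1
  lf[a] <- target1 * mjerk((t[a] - t0) / T1)
  lf[t >= t0 + T1] <- target1
  if (corrective) {
    r2T <- pulse_T
    b <- t >= pulse_t0 & t < pulse_t0 + r2T
    lf[b] <- target1 + (stop_lvl - target1) * mjerk((t[b] - pulse_t0) / r2T)
    lf[t >= pulse_t0 + r2T] <- stop_lvl
  }
  # settle back to the true weight: cubic Hermite from the level and rate at
  # the end of loading to (W, 0), so the rate stays continuous
  start_lvl <- lf[which(t >= t_settle0)[1L]]
  s <- t >= t_settle0
  tau <- pmin((t[s] - t_settle0) / Ts, 1)
  h00 <- 2 * tau^3 - 3 * tau^2 + 1
  h10 <- tau^3 - 2 * tau^2 + tau
  h01 <- 3 * tau^2 - 2 * tau^3
  lf[s] <- h00 * start_lvl + h10 * Ts * settle_rate + h01 * W
  lf[t >= t_plateau] <- W

  # TMS extra load-rate drive: LO group, dynamic TMS, heavy objects only
  d_lfr <- params$tms_effects$d_pLFR_dynamic_LO_heavy
  if (tms_condition == "dynamic" && group == "LO" && object == "heavy" &&
      pulse_full && d_lfr > 0) {
    Tb <- 0.2
    amp <- d_lfr * (Tb / 2) / MJ_PEAK
    ctr <- pulse_t0 + 0.58 * pulse_T
    lf <- lf + amp * mj_bump(t, ctr - Tb / 2, Tb)
  }

  # grip force: early minimum-jerk lead to the safety margin, then coupling
  gf <- numeric(length(t))
  lead <- t >= t_gf & t < t0
  gf[lead] <- params$safety_margin * mjerk((t[lead] - t_gf) / params$gf_lead)
  after <- t >= t0
  gf[after] <- params$safety_margin + params$gf_lf_ratio * lf[after]

  d_gfr <- params$tms_effects$d_pGFR_dynamic
  if (tms_condition == "dynamic" && d_gfr > 0) {
    Tb <- 0.2
    amp <- d_gfr * (Tb / 2) / MJ_PEAK
    ctr <- pulse_t0 + 0.58 * pulse_T
    gf <- gf + amp * mj_bump(t, ctr - Tb / 2, Tb)
  }

  truth <- list(
    t_liftoff = t[which(lf >= W)[1]],
    lf_plateau = W,
    planned_peak_lfr = r1,
    t_gf_onset = t_gf,
    t_lf_onset = t0,
    corrective = corrective
  )

  n <- length(t)
  sd_f <- params$noise_sd_force
  noise <- function() if (sd_f > 0) stats::rnorm(n, 0, sd_f) else numeric(n)
  samples <- data.frame(
    t = t,
    fxA = noise(), fyA = gf + noise(), fzA = lf / 2 + noise(),
    fxB = noise(), fyB = gf + noise(), fzB = lf / 2 + noise()
  )
  trace <- structure(list(fs = fs, samples = samples,
                          meta = list(object = object,
                                      prev_object = prev_object,
                                      tms_condition = tms_condition,
                                      group = group)),
                     class = "ll_force_trace")

  # weight report on the participant's own scale
  mid <- mean(object_weight(c("light", "heavy"), params))
  bias <- -params$percept_prev_gain * (W_prev - mid)
  tms_term <- if (tms_condition == "static" && object == "heavy")
    params$tms_effects$d_percept_static_heavy else 0
  pnoise <- if (params$noise_sd_report > 0)
    stats::rnorm(1, 0, params$noise_sd_report) else 0
  raw <- participant_scale * (W + bias + tms_term + pnoise) + participant_offset
  raw <- max(raw, 0.01)

  ap <- params$artifact_probs
  flags <- list(
    dropped = stats::runif(1) < ap$p_drop,
    multiple_lifts = stats::runif(1) < ap$p_multilift,
    tms_failed = tms_condition != "none" && stats::runif(1) < ap$p_tms_fail
  )

  list(trace = trace, percept = list(raw_estimate = raw), truth = truth,
       flags = flags)
}

#' Simulate a two-group cohort of lifting sessions
#'
#' Gives every participant an independent session design (derived seed), a
#' self-chosen report scale/offset, and simulates every trial in sequence so
#' that the sensorimotor-memory structure follows the realised object order.
#'
#' @param n_per_group participants per group (`aIPS` and `LO`).
#' @param params an [sim_params()] list.
#' @param seed master seed; per-participant seeds are split off
#'   deterministically with a counter.
#' @param n_reps_per_cell repetitions per design cell (default 10; use 1 for
#'   small test datasets).
#' @param keep_traces retain the full force traces (memory-heavy at full
#'   size; disable to keep only reports, flags and ground truth).
#' @return list with `trials` (one row per trial: participant, group, design
#'   columns, `raw_estimate`, artifact flags, ground-truth liftoff) and
#'   `traces` (list of `ll_force_trace`, or `NULL`), plus `seed` and `params`.
#' @export
simulate_cohort <- function(n_per_group, params = sim_params(), seed = 1,
                            n_reps_per_cell = 10L, keep_traces = TRUE) {
  stopifnot(n_per_group >= 1)
  set.seed(as.integer(seed))
  n_total <- 2L * n_per_group
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  scales <- stats::runif(n_total, params$participant_scale_range[1],
                         params$participant_scale_range[2])
  offsets <- stats::runif(n_total, params$participant_offset_range[1],
                          params$participant_offset_range[2])

  rows <- list()
  traces <- if (keep_traces) list() else NULL
  pid <- 0L
  for (grp in c("aIPS", "LO")) {
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      design <- generate_session(sub_seeds[pid], n_reps_per_cell)
      set.seed(sub_seeds[pid] %% 1000003L + 7L)
      prev <- NA_character_
      for (j in seq_len(nrow(design))) {
        sim <- simulate_trial(design$object[j], prev,
                              design$tms_condition[j], grp, params,
                              scales[pid], offsets[pid])
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, group = grp,
          index = design$index[j], object = design$object[j],
          tms_condition = design$tms_condition[j],
          order_pair = design$order_pair[j],
          analyzable = design$analyzable[j],
          raw_estimate = sim$percept$raw_estimate,
          dropped = sim$flags$dropped,
          multiple_lifts = sim$flags$multiple_lifts,
          tms_failed = sim$flags$tms_failed,
          t_liftoff_truth = sim$truth$t_liftoff,
          stringsAsFactors = FALSE
        )
        if (keep_traces) traces[[length(traces) + 1L]] <- sim$trace
        prev <- design$object[j]
      }
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, traces = traces, seed = as.integer(seed),
       params = params)
}
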
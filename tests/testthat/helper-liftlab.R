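# shared fixtures and independent oracles for the test suite

# noiseless, jitter-free, artifact-free simulation parameters
quiet_params <- function(...) {
  args <- list(noise_sd_force = 0, noise_sd_report = 0, reach_jitter = 0,
               artifact_probs = list(p_drop = 0, p_multilift = 0,
                                     p_tms_fail = 0))
  args <- utils::modifyList(args, list(...))
  do.call(sim_params, args)
}

no_tms_effects <- list(d_pGFR_dynamic = 0, d_pLFR_dynamic_LO_heavy = 0,
                       d_percept_static_heavy = 0)

# brute-force local-maximum scan, written independently of the package's
# extraction path: checks every sample against its neighbours
oracle_local_max_idx <- function(x) {
  idx <- c()
  for (i in 2:(length(x) - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) idx <- c(idx, i)
    # flat-top plateau: first sample counts
    if (x[i] > x[i - 1] && x[i] == x[i + 1]) {
      j <- i + 1
      while (j < length(x) && x[j + 1] == x[j]) j <- j + 1
      if (j < length(x) && x[j + 1] < x[j]) idx <- c(idx, i)
    }
  }
  idx
}

# oracle peak / first-peak extraction over a window of a rate series
oracle_peaks <- function(rate, i0, i1, frac = 0.3) {
  w <- rate[i0:i1]
  peak <- max(w)
  lm <- oracle_local_max_idx(w)
  cand <- lm[w[lm] >= frac * peak]
  first <- if (length(cand)) w[cand[1]] else peak
  list(peak = peak, first = first)
}

# count prominent local maxima in the loading-phase load-force rate of a
# raw (unfiltered) simulated trace; independent of package rate code
oracle_count_lfr_peaks <- function(trace, min_height = 2) {
  lf <- trace$samples$fzA + trace$samples$fzB
  rate <- diff(lf) * trace$fs
  idx <- oracle_local_max_idx(rate)
  sum(rate[idx] >= min_height)
}

# balanced synthetic cell-mean data for ANOVA tests
make_cells <- function(n_per_group, effects = list(), sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(current_weight = c("light", "heavy"),
                      prev_weight = c("light", "heavy"),
                      tms_condition = c("dynamic", "static", "none"),
                      stringsAsFactors = FALSE)
  out <- list()
  pid <- 0
  for (g in c("aIPS", "LO")) {
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1
      d <- grid
      d$participant <- pid
      d$group <- g
      d$value <- stats::rnorm(nrow(grid), sd = sd)
      if (!is.null(effects$current))
        d$value <- d$value + ifelse(d$current_weight == "heavy", 1, -1) *
          effects$current / 2
      if (!is.null(effects$prev))
        d$value <- d$value + ifelse(d$prev_weight == "heavy", 1, -1) *
          effects$prev / 2
      if (!is.null(effects$group))
        d$value <- d$value + ifelse(g == "LO", 1, -1) * effects$group / 2
      out[[pid]] <- d
    }
  }
  cells <- do.call(rbind, out)
  cells$order_pair <- paste0(
    ifelse(cells$prev_weight == "light", "L", "H"),
    ifelse(cells$current_weight == "light", "L", "H"))
  cells$dv_name <- "y"
  cells
}
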
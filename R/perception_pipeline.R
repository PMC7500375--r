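#' Standardise weight reports within participants
#'
#' Converts each participant's raw weight estimates to z scores using that
#' participant's grand mean and grand (sample, n-1 denominator) standard
#' deviation over the included trials, removing the arbitrary self-chosen
#' report scale: the z scores are invariant to any positive affine transform
#' of the raw reports.
#'
#' @param raw numeric raw estimates.
#' @param participant participant id per estimate (a single participant may
#'   be implied by omitting this).
#' @return numeric vector of z scores, per-participant mean 0 and SD 1.
#' @export
zscore_estimates <- function(raw, participant = rep(1L, length(raw))) {
  stopifnot(length(raw) == length(participant))
  out <- numeric(length(raw))
  for (p in unique(participant)) {
    i <- participant == p
    if (sum(i) < 2L) stop("participant ", p, ": need >= 2 estimates")
    s <- stats::sd(raw[i])
    if (s == 0) stop("participant ", p, ": zero variance in raw estimates")
    out[i] <- (raw[i] - mean(raw[i])) / s
  }
  out
}

#' Participant-level cell means of a dependent variable
#'
#' Averages a per-trial dependent variable for each participant within every
#' order-pair by TMS-condition cell, using only trials retained in the
#' appropriate exclusion set.
#'
#' @param trials data frame with columns `participant`, `group`,
#'   `order_pair`, `tms_condition`, and the dependent variable.
#' @param dv name of the dependent-variable column.
#' @param include logical vector marking included trials (e.g. from
#'   [apply_exclusions()]); defaults to all rows with a defined order pair.
#' @return data frame of class `ll_cell_means` with one row per participant
#'   x order pair x TMS condition: columns `participant`, `group`,
#'   `order_pair`, `tms_condition`, `prev_weight`, `current_weight`,
#'   `dv_name`, `value`, `n_trials`.
#' @export
cell_means <- function(trials, dv, include = NULL) {
  stopifnot(dv %in% names(trials))
  if (is.null(include)) include <- trials$order_pair %in% ll_order_pairs
  d <- trials[include & trials$order_pair %in% ll_order_pairs, ]
  agg <- stats::aggregate(d[[dv]],
                          by = list(participant = d$participant,
                                    group = d$group,
                                    order_pair = d$order_pair,
                                    tms_condition = d$tms_condition),
                          FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  cnt <- stats::aggregate(d[[dv]],
                          by = list(participant = d$participant,
                                    group = d$group,
                                    order_pair = d$order_pair,
                                    tms_condition = d$tms_condition),
                          FUN = length)
  agg$n_trials <- cnt$x
  agg$prev_weight <- ifelse(substr(agg$order_pair, 1, 1) == "L",
                            "light", "heavy")
  agg$current_weight <- ifelse(substr(agg$order_pair, 2, 2) == "L",
                               "light", "heavy")
  agg$dv_name <- dv
  agg <- agg[order(agg$participant, agg$order_pair, agg$tms_condition), ]
  rownames(agg) <- NULL
  class(agg) <- c("ll_cell_means", "data.frame")
  agg
}

#' Previous-weight difference scores
#'
#' For each participant, TMS condition and current weight, subtracts the cell
#' value with a previous light object from the value with a previous heavy
#' object: `HL - LL` for current light and `HH - LH` for current heavy.  A
#' nonzero difference indexes sensitivity to the previously lifted weight
#' (positive for force parameters scaled up after heavy lifts, negative for
#' the perceptual after-heavy bias).
#'
#' @param cells an [cell_means()] data frame (typically of z-scored values).
#' @return data frame with columns `participant`, `group`, `tms_condition`,
#'   `current_weight`, `dv_name`, `diff`.  Participant/condition combinations
#'   with a missing cell are skipped with a message.
#' @export
previous_weight_differences <- function(cells) {
  key <- interaction(cells$participant, cells$tms_condition,
                     cells$current_weight, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    d <- cells[key == k, ]
    heavy_prev <- d$value[d$prev_weight == "heavy"]
    light_prev <- d$value[d$prev_weight == "light"]
    if (length(heavy_prev) != 1L || length(light_prev) != 1L) {
      message("skipping incomplete cell pair: ", k)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      participant = d$participant[1], group = d$group[1],
      tms_condition = d$tms_condition[1],
      current_weight = d$current_weight[1],
      dv_name = d$dv_name[1],
      diff = heavy_prev - light_prev,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Stimulation difference scores relative to the no-TMS baseline
#'
#' Pools cells over previous weight within each current weight, then
#' subtracts the no-stimulation value from the dynamic and static values for
#' each participant and current weight.
#'
#' @param cells an [cell_means()] data frame.
#' @return data frame with columns `participant`, `group`, `tms_condition`
#'   (`dynamic`/`static`), `current_weight`, `dv_name`, `diff`.
#' @export
tms_differences <- function(cells) {
  pooled <- stats::aggregate(value ~ participant + group + tms_condition +
                               current_weight + dv_name,
                             data = cells, FUN = mean)
  key <- interaction(pooled$participant, pooled$current_weight, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    d <- pooled[key == k, ]
    base <- d$value[d$tms_condition == "none"]
    if (length(base) != 1L) {
      message("skipping cells without a no-TMS baseline: ", k)
      next
    }
    for (cnd in c("dynamic", "static")) {
      v <- d$value[d$tms_condition == cnd]
      if (length(v) != 1L) next
      out[[length(out) + 1L]] <- data.frame(
        participant = d$participant[1], group = d$group[1],
        tms_condition = cnd, current_weight = d$current_weight[1],
        dv_name = d$dv_name[1], diff = v - base,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Percent perceptual bias from the previous weight
#'
#' Expresses the previous-weight bias of the raw reports as a percentage per
#' participant.  For current light objects:
#' `100 * (mean after light - mean after heavy) / mean after light`
#' (positive = perceived lighter after a heavy lift, the baseline being the
#' same-weight `LL` pair).  For current heavy objects the same numerator is
#' divided by the after-heavy (`HH`) baseline, so positive values mean
#' perceived heavier after a light lift.
#'
#' @param trials data frame with `participant`, `order_pair` and a raw
#'   estimate column.
#' @param dv name of the raw estimate column (default `"raw_estimate"`).
#' @param include logical vector of included trials (default: defined order
#'   pairs).
#' @return data frame with `participant`, `current_weight`, `percent_bias`.
#' @export
percent_bias <- function(trials, dv = "raw_estimate", include = NULL) {
  if (is.null(include)) include <- trials$order_pair %in% ll_order_pairs
  d <- trials[include & trials$order_pair %in% ll_order_pairs, ]
  out <- list()
  for (p in unique(d$participant)) {
    for (cw in c("light", "heavy")) {
      cc <- if (cw == "light") c("LL", "HL") else c("LH", "HH")
      after_light <- mean(d[[dv]][d$participant == p & d$order_pair == cc[1]])
      after_heavy <- mean(d[[dv]][d$participant == p & d$order_pair == cc[2]])
      denom <- if (cw == "light") after_light else after_heavy
      if (!is.finite(denom) || denom == 0) stop("zero or undefined baseline ",
                                                "mean for participant ", p)
      out[[length(out) + 1L]] <- data.frame(
        participant = p, current_weight = cw,
        percent_bias = 100 * (after_light - after_heavy) / denom,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
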
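#' Label trials with previous-by-current weight order pairs
#'
#' Trials in a lifting sequence are classified by the weights of the previous
#' and current object: `LL`, `HL`, `LH` or `HH` (previous weight first,
#' `L` = light, `H` = heavy).  A trial gets the label `undefined` when either
#' its own object or the preceding object is not one of the two analysis
#' weights -- i.e. the first trial, any dummy-weight trial, and the trial
#' immediately following a dummy.
#'
#' @param objects character vector of object labels; recognised analysis
#'   weights are `"light"` and `"heavy"`, anything else (e.g. `"medium"`,
#'   `"practice"`) breaks the pairing.
#' @return character vector the same length as `objects` with values in
#'   `c("LL", "HL", "LH", "HH", "undefined")`.
#' @examples
#' label_order_pairs(c("light", "light", "heavy"))   # undefined, LL, LH
#' label_order_pairs(c("heavy", "light", "light"))   # undefined, HL, LL
#' @export
label_order_pairs <- function(objects) {
  stopifnot(length(objects) >= 1L)
  objects <- as.character(objects)
  code <- c(light = "L", heavy = "H")
  cur <- code[objects]
  prev <- c(NA_character_, cur[-length(cur)])
  out <- ifelse(is.na(cur) | is.na(prev), "undefined", paste0(prev, cur))
  unname(out)
}

#' Object labels and condition labels used throughout the package
#' @keywords internal
ll_objects <- c("light", "heavy", "medium", "practice")
ll_conditions <- c("dynamic", "static", "none")
ll_order_pairs <- c("LL", "HL", "LH", "HH")

# number of medium-weight dummy trials for a given repetition count; 14 at
# the reference size of 10 reps/cell (10% of the session), scaled
# proportionally and kept >= 1
n_dummies_for <- function(n_reps_per_cell) {
  max(1L, as.integer(round(1.4 * n_reps_per_cell)))
}

#' Generate a pseudorandom lifting-session design
#'
#' Builds an ordered trial sequence for a single participant in which every
#' combination of order pair (`LL`, `HL`, `LH`, `HH`) and TMS condition
#' (`dynamic`, `static`, `none`) occurs exactly `n_reps_per_cell` times among
#' the analyzable trials.  Medium-weight dummy trials are interspersed to
#' break up the light/heavy alternation; a dummy is never first, never last
#' and never adjacent to another dummy, so each dummy invalidates exactly one
#' following trial.  Together with the first trial this yields, at the
#' reference size of 10 repetitions per cell, 149 trials total: 120
#' analyzable, 14 dummies and 29 non-analyzable.
#'
#' Dummy, post-dummy and first trials receive a uniformly random TMS
#' condition.  The sequence is found by constrained rejection sampling: the
#' required order-pair transitions are laid down as random walks over the
#' light/heavy states within the runs between dummies, retrying (up to
#' `max_retries` times) whenever a walk dead-ends.
#'
#' @param seed integer seed; the same seed always reproduces the same design.
#' @param n_reps_per_cell repetitions of each order-pair x condition cell
#'   among analyzable trials (default 10).
#' @param include_practice prepend 5 practice trials (2 with TMS: one
#'   dynamic, one static)?  Practice trials are flagged non-analyzable and do
#'   not count towards the session totals.
#' @param max_retries retry cap for the rejection sampler.
#' @return a `data.frame` of class `ll_session` with columns `index`,
#'   `object`, `tms_condition`, `order_pair`, `analyzable`, and attributes
#'   `seed` and `n_reps_per_cell`.  Practice trials, when requested, carry
#'   index 0 and are placed before trial 1.
#' @examples
#' d <- generate_session(seed = 1)
#' nrow(d)                  # 149
#' sum(d$analyzable)        # 120
#' sum(d$object == "medium")# 14
#' @export
generate_session <- function(seed, n_reps_per_cell = 10L,
                             include_practice = FALSE,
                             max_retries = 10000L) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(n_reps_per_cell), n_reps_per_cell >= 1L)
  n_reps_per_cell <- as.integer(n_reps_per_cell)
  n_pairs <- 12L * n_reps_per_cell          # analyzable transitions needed
  n_dummy <- n_dummies_for(n_reps_per_cell)
  n_runs <- n_dummy + 1L                    # dummies split the session

  set.seed(as.integer(seed))
  objseq <- NULL
  for (attempt in seq_len(max_retries)) {
    objseq <- try_build_sequence(n_pairs, n_runs)
    if (!is.null(objseq)) break
  }
  if (is.null(objseq)) {
    stop("could not satisfy session constraints after ", max_retries,
         " retries; the requested size may be unsatisfiable")
  }

  pairs <- label_order_pairs(objseq)
  analyzable <- pairs != "undefined"

  # conditions: exactly n_reps per (pair, condition) among analyzable trials;
  # everything else uniform at random
  cond <- character(length(objseq))
  for (p in ll_order_pairs) {
    idx <- which(pairs == p)
    cond[idx] <- sample(rep(ll_conditions, n_reps_per_cell))
  }
  n_rest <- sum(!analyzable)
  cond[!analyzable] <- sample(ll_conditions, n_rest, replace = TRUE)

  design <- data.frame(
    index = seq_along(objseq),
    object = objseq,
    tms_condition = cond,
    order_pair = pairs,
    analyzable = analyzable,
    stringsAsFactors = FALSE
  )

  if (include_practice) {
    pr_cond <- sample(c("dynamic", "static", "none", "none", "none"))
    practice <- data.frame(
      index = 0L, object = "practice", tms_condition = pr_cond,
      order_pair = "undefined", analyzable = FALSE,
      stringsAsFactors = FALSE
    )
    design <- rbind(practice, design)
  }

  attr(design, "seed") <- as.integer(seed)
  attr(design, "n_reps_per_cell") <- n_reps_per_cell
  class(design) <- c("ll_session", "data.frame")
  design
}

# One attempt at laying out the object sequence.  Returns the character
# vector of objects, or NULL on a dead end.
try_build_sequence <- function(n_pairs, n_runs) {
  # remaining transition counts, equal across the four pair types
  remaining <- stats::setNames(rep(n_pairs / 4L, 4L), ll_order_pairs)

  # split the transitions across runs, at least one per run
  if (n_runs > 1L) {
    extra <- stats::rmultinom(1L, n_pairs - n_runs, rep(1, n_runs))[, 1L]
    run_len <- extra + 1L
  } else {
    run_len <- n_pairs
  }

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    # start state weighted by remaining outgoing transitions
    w <- c(L = remaining[["LL"]] + remaining[["LH"]],
           H = remaining[["HH"]] + remaining[["HL"]])
    if (sum(w) == 0) return(NULL)
    state <- sample(names(w), 1L, prob = w)
    objs <- decode_state(state)
    for (k in seq_len(run_len[r])) {
      out_edges <- paste0(state, c("L", "H"))
      w <- remaining[out_edges]
      if (sum(w) == 0) return(NULL)       # dead end -> retry session
      edge <- sample(out_edges, 1L, prob = w)
      remaining[edge] <- remaining[edge] - 1L
      state <- substr(edge, 2L, 2L)
      objs <- c(objs, decode_state(state))
    }
    runs[[r]] <- objs
  }
  stopifnot(all(remaining == 0L))

  out <- runs[[1L]]
  for (r in seq_len(n_runs - 1L)) {
    out <- c(out, "medium", runs[[r + 1L]])
  }
  out
}

decode_state <- function(s) c(L = "light", H = "heavy")[[s]]

#' Summarise a session design
#' @param object an `ll_session`.
#' @param ... unused.
#' @export
summary.ll_session <- function(object, ...) {
  main <- object[object$object != "practice", ]
  cells <- table(main$order_pair[main$analyzable],
                 main$tms_condition[main$analyzable])
  structure(list(
    n_total = nrow(main),
    n_analyzable = sum(main$analyzable),
    n_dummy = sum(main$object == "medium"),
    n_extra = sum(!main$analyzable),
    cells = cells,
    seed = attr(object, "seed")
  ), class = "summary.ll_session")
}

#' @export
print.summary.ll_session <- function(x, ...) {
  cat(sprintf("Session design (seed %d): %d trials, %d analyzable, %d dummy, %d extra\n",
              x$seed, x$n_total, x$n_analyzable, x$n_dummy, x$n_extra))
  print(x$cells)
  invisible(x)
}

#' Write a session design to CSV
#' @param design an `ll_session`.
#' @param path output file.
#' @export
write_session <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
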
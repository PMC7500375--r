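#' Mixed-design repeated-measures ANOVA on participant cell means
#'
#' Analyses one dependent variable with the study's 2 (group, between) x 3
#' (TMS condition) x 2 (previous weight) x 2 (current weight) mixed ANOVA.
#' Within effects are tested with the univariate approach: each effect's
#' orthonormal contrast scores are formed per participant, sums of squares
#' are computed from (unweighted) group means, and each within effect and
#' its interaction with group share the contrast-by-subject error stratum.
#' For within effects with three or more levels, Mauchly's sphericity test
#' is run on the pooled within-group covariance of the contrast scores and a
#' Greenhouse-Geisser correction of the degrees of freedom is applied when
#' it rejects at `alpha`.  Sums of squares are Type III (identical to Type I
#' in the balanced design).
#'
#' @param cells an [cell_means()] data frame (one row per participant x
#'   order pair x TMS condition); may hold a single `dv_name` or be filtered
#'   via `dv`.
#' @param dv optional dependent-variable name to select from `cells`.
#' @param alpha significance level used for the sphericity gate (0.05).
#' @return object of class `ll_anova`: a list with `dv_name`, `effects`
#'   (data frame: `effect`, `F`, `df_num`, `df_den`, `p`, `pes` partial eta
#'   squared, `gg_applied`, `epsilon`, `mauchly_p`) and `n_per_group`.
#' @export
mixed_anova <- function(cells, dv = NULL, alpha = 0.05) {
  if (!is.null(dv)) cells <- cells[cells$dv_name == dv, ]
  if (!is.null(cells$dv_name) && length(unique(cells$dv_name)) != 1L) {
    stop("cells contain multiple dependent variables; pass dv = ")
  }
  wide <- cells_to_wide(cells)
  res <- mixed_anova_engine(wide$Y, wide$group, alpha)
  structure(list(dv_name = if (is.null(dv)) cells$dv_name[1] else dv,
                 effects = res,
                 n_per_group = table(wide$group)),
            class = "ll_anova")
}

# participants x 12 matrix, columns ordered condition (slowest) x previous x
# current (fastest), matching the kronecker contrast construction
cells_to_wide <- function(cells) {
  need <- c("participant", "group", "tms_condition", "prev_weight",
            "current_weight", "value")
  stopifnot(all(need %in% names(cells)))
  grid <- expand.grid(current_weight = c("light", "heavy"),
                      prev_weight = c("light", "heavy"),
                      tms_condition = ll_conditions,
                      stringsAsFactors = FALSE)
  pids <- unique(cells$participant)
  Y <- matrix(NA_real_, length(pids), nrow(grid))
  grp <- character(length(pids))
  key_cells <- paste(cells$tms_condition, cells$prev_weight,
                     cells$current_weight)
  key_grid <- paste(grid$tms_condition, grid$prev_weight,
                    grid$current_weight)
  for (i in seq_along(pids)) {
    d <- cells[cells$participant == pids[i], ]
    grp[i] <- d$group[1]
    m <- match(key_grid, key_cells[cells$participant == pids[i]])
    if (anyNA(m)) stop("incomplete cells for participant ", pids[i])
    Y[i, ] <- d$value[m]
  }
  list(Y = Y, group = grp, participants = pids)
}

# orthonormal contrast matrix (k x k-1) and unit mean vector (k x 1)
orth_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}
unit_vec <- function(k) matrix(rep(1 / sqrt(k), k), ncol = 1)

mixed_anova_engine <- function(Y, group, alpha = 0.05) {
  groups <- unique(group)
  G <- length(groups)
  N <- nrow(Y)
  n_g <- vapply(groups, function(g) sum(group == g), integer(1))
  h_eff <- G^2 / sum(1 / n_g)   # N when balanced

  within_factors <- list(tms_condition = 3L, prev_weight = 2L,
                         current_weight = 2L)
  fac_names <- names(within_factors)

  rows <- list()
  add_row <- function(effect, F, df1, df2, p, pes, gg, eps, mau) {
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, F = F, df_num = df1, df_den = df2, p = p, pes = pes,
      gg_applied = gg, epsilon = eps, mauchly_p = mau,
      stringsAsFactors = FALSE)
  }

  # between-participants effect on subject means (only with >= 2 groups)
  if (G >= 2L) {
    P <- rowMeans(Y)
    gm <- vapply(groups, function(g) mean(P[group == g]), numeric(1))
    grand_w <- sum(n_g * gm) / N
    ss_loc <- ncol(Y) * sum(n_g * (gm - grand_w)^2)
    ss_err <- ncol(Y) * sum((P - gm[match(group, groups)])^2)
    df1 <- G - 1; df2 <- N - G
    Fv <- (ss_loc / df1) / (ss_err / df2)
    add_row("group", Fv, df1, df2, stats::pf(Fv, df1, df2, lower.tail = FALSE),
            ss_loc / (ss_loc + ss_err), FALSE, NA_real_, NA_real_)
  }

  # every non-empty subset of within factors
  subsets <- unlist(lapply(seq_along(fac_names), function(m)
    utils::combn(fac_names, m, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    C <- Reduce(kronecker, lapply(fac_names, function(f) {
      k <- within_factors[[f]]
      if (f %in% S) orth_contrasts(k) else unit_vec(k)
    }))
    Sc <- Y %*% C
    d <- ncol(Sc)
    m_g <- t(vapply(groups, function(g)
      colMeans(Sc[group == g, , drop = FALSE]), numeric(d)))
    if (d == 1L) m_g <- matrix(m_g, ncol = 1L)
    resid <- Sc - m_g[match(group, groups), , drop = FALSE]
    ss_err <- sum(resid^2)
    df_err <- d * (N - G)

    # pooled within-group covariance -> sphericity diagnostics
    Sigma <- crossprod(resid) / (N - G)
    eps <- sum(diag(Sigma))^2 / (d * sum(Sigma^2))
    mau_p <- NA_real_
    if (d >= 2L && N - G > d) {
      detS <- det(Sigma)
      W <- detS / (mean(diag(Sigma)))^d
      if (W > 0) {
        chi <- -(N - G - (2 * d^2 + d + 2) / (6 * d)) * log(W)
        mau_p <- stats::pchisq(chi, d * (d + 1) / 2 - 1, lower.tail = FALSE)
      } else mau_p <- 0
    }
    gg <- isTRUE(d >= 2L && !is.na(mau_p) && mau_p < alpha)

    emit <- function(effect, ss_hyp, df_hyp) {
      Fv <- (ss_hyp / df_hyp) / (ss_err / df_err)
      df1 <- df_hyp; df2 <- df_err
      if (gg) { df1 <- df1 * eps; df2 <- df2 * eps }
      add_row(effect, Fv, df1, df2,
              stats::pf(Fv, df1, df2, lower.tail = FALSE),
              ss_hyp / (ss_hyp + ss_err), gg,
              if (d >= 2L) eps else NA_real_, mau_p)
    }

    m_un <- colMeans(m_g)                 # unweighted grand contrast mean
    emit(paste(S, collapse = ":"), h_eff * sum(m_un^2), d)

    if (G >= 2L) {
      grand_w <- colSums(m_g * n_g) / N
      ss_int <- sum(n_g * rowSums(sweep(m_g, 2, grand_w)^2))
      emit(paste(c("group", S), collapse = ":"), ss_int, d * (G - 1))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ll_anova <- function(x, ...) {
  cat("Mixed ANOVA on", x$dv_name, "(", paste(names(x$n_per_group),
      x$n_per_group, collapse = ", "), ")\n")
  e <- x$effects
  e$F <- round(e$F, 2)
  e$df_num <- round(e$df_num, 2)
  e$df_den <- round(e$df_den, 2)
  e$p <- signif(e$p, 3)
  e$pes <- round(e$pes, 2)
  print(e[, c("effect", "F", "df_num", "df_den", "p", "pes", "gg_applied")])
  invisible(x)
}

#' Location-split decision rule
#'
#' Implements the protocol step that follows the omnibus mixed ANOVA: if any
#' main effect of, or interaction with, the between-participants group
#' factor is significant at `alpha`, the analysis is split into separate
#' repeated-measures ANOVAs (3 x 2 x 2, no group factor) per group;
#' otherwise no split is performed.
#'
#' @param full an [mixed_anova()] result for the omnibus model.
#' @param cells the cell means that produced it.
#' @param alpha significance level (0.05).
#' @return named list of per-group `ll_anova` objects (empty when the rule
#'   does not trigger).
#' @export
split_anova_protocol <- function(full, cells, alpha = 0.05) {
  eff <- full$effects
  loc <- grepl("(^|:)group(:|$)", eff$effect)
  if (!any(eff$p[loc] < alpha)) return(list())
  out <- list()
  for (g in unique(cells$group)) {
    out[[g]] <- mixed_anova(cells[cells$group == g, ], alpha = alpha)
  }
  out
}

#' Bonferroni-corrected post hoc contrasts
#'
#' All pairwise contrasts of the cells of a (significant) effect.  Cells are
#' participant means collapsed over the factors not in `effect`.  Pairs of
#' cells at the same group level (or when `group` is not part of the effect)
#' are compared with paired t tests across participants; pairs differing in
#' group level with independent (Welch) t tests.  Raw p values are
#' multiplied by the number of contrasts in the family and capped at 1.
#'
#' @param cells an [cell_means()] data frame.
#' @param effect character vector of factor names defining the effect, from
#'   `c("group", "tms_condition", "prev_weight", "current_weight")`.
#' @return data frame: `contrast`, `estimate` (mean difference), `t`, `df`,
#'   `p_raw`, `p_bonferroni`.
#' @export
posthoc_bonferroni <- function(cells, effect) {
  facs <- intersect(c("group", "tms_condition", "prev_weight",
                      "current_weight"), effect)
  stopifnot(length(facs) >= 1L)
  within_facs <- setdiff(facs, "group")
  fml <- stats::reformulate(c("participant", "group", within_facs),
                            response = "value")
  agg <- stats::aggregate(fml, data = cells, FUN = mean)
  cell_lab <- if (length(within_facs)) {
    do.call(paste, c(agg[facs], sep = "."))
  } else as.character(agg$group)
  labs <- unique(cell_lab)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  grp_of <- function(lab) agg$group[cell_lab == lab][1]
  rows <- list()
  for (pr in pairs) {
    a <- agg[cell_lab == pr[1], ]
    b <- agg[cell_lab == pr[2], ]
    between <- ("group" %in% facs) && !identical(grp_of(pr[1]), grp_of(pr[2]))
    tt <- tryCatch({
      if (between) {
        stats::t.test(a$value, b$value)
      } else {
        a <- a[order(a$participant), ]
        b <- b[order(b$participant), ]
        stopifnot(identical(a$participant, b$participant))
        stats::t.test(a$value, b$value, paired = TRUE)
      }
    }, error = function(e) {
      # essentially-constant data: no evidence of a difference
      list(statistic = NA_real_, parameter = NA_real_, p.value = 1)
    })
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste(pr[1], "-", pr[2]),
      estimate = mean(a$value) - mean(b$value),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Linear mixed model relating force scaling to perception
#'
#' Fits the relation analyses: the dependent variable is a (z-scored)
#' perceptual quantity -- a previous-weight difference score, a TMS
#' difference score, or per-trial estimates -- and a force-rate covariate
#' enters as a fixed effect together with current weight, TMS condition,
#' group and all their interactions.  Participants contribute a random
#' intercept and a first-order autoregressive residual correlation over the
#' record order within participant (trial order for the trial-by-trial
#' variant; condition index for averaged difference scores, where the AR(1)
#' ordering is a convention since the records are not sequential).  Fitted
#' by maximum likelihood; fixed effects are tested with marginal
#' (Type III) F tests.
#'
#' @param records data frame with columns `participant`, `group`,
#'   `tms_condition`, `current_weight`, the response and the covariate.
#' @param response name of the dependent column.
#' @param covariate name of the force covariate column (e.g. a z-scored peak
#'   LFR difference); a zero-variance covariate is dropped with a flag.
#' @param label model label stored in the result.
#' @return object of class `ll_lmm`: list with `label`, `fixed_tests` (data
#'   frame: `term`, `df_num`, `df_den`, `F`, `p`), `covariate_estimate`
#'   (named vector of fixed-effect coefficients involving the covariate),
#'   `covariate_dropped`, `converged`, and the `nlme::lme` `fit`.
#' @export
lmm_relation <- function(records, response, covariate,
                         label = "relation") {
  stopifnot(all(c("participant", "group", "tms_condition", "current_weight",
                  response, covariate) %in% names(records)))
  if (length(unique(records$participant)) < 2L) {
    stop("need at least 2 participants")
  }
  d <- records
  d$.resp <- d[[response]]
  d$.cov <- d[[covariate]]
  d$participant <- factor(d$participant)
  d$group <- factor(d$group)
  d$tms_condition <- factor(d$tms_condition)
  d$current_weight <- factor(d$current_weight)
  dropped <- stats::var(d$.cov) < 1e-12 || !is.finite(stats::var(d$.cov))
  one_level <- function(f) length(unique(d[[f]])) < 2L
  terms <- c(if (!dropped) ".cov",
             if (!one_level("current_weight")) "current_weight",
             if (!one_level("tms_condition")) "tms_condition",
             if (!one_level("group")) "group")
  fixed <- stats::as.formula(paste(".resp ~", paste(terms, collapse = " * ")))
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | participant, data = d,
              correlation = nlme::corAR1(form = ~ 1 | participant),
              method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200)),
    error = function(e) stop("mixed model failed to fit: ",
                             conditionMessage(e), call. = FALSE))
  av <- stats::anova(fit, type = "marginal")
  tests <- data.frame(term = rownames(av), df_num = av$numDF,
                      df_den = av$denDF, F = av$`F-value`,
                      p = av$`p-value`, stringsAsFactors = FALSE)
  cf <- nlme::fixef(fit)
  cov_est <- cf[grepl("\\.cov", names(cf))]
  structure(list(label = label, fixed_tests = tests,
                 covariate_estimate = cov_est,
                 covariate_dropped = dropped, converged = TRUE, fit = fit),
            class = "ll_lmm")
}

#' @export
print.ll_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$label,
      if (x$covariate_dropped) "(covariate dropped: zero variance)", "\n")
  t <- x$fixed_tests
  t$F <- round(t$F, 2); t$p <- signif(t$p, 3)
  print(t)
  invisible(x)
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param x,y numeric vectors of per-participant values (n >= 4, finite,
#'   non-constant).
#' @return list of class `ll_corr`: `R`, `ci95` (length-2), `p`, `n`.
#' @export
pearson_ci <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(R = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
                 p = ct$p.value, n = length(x)), class = "ll_corr")
}

#' @export
print.ll_corr <- function(x, ...) {
  cat(sprintf("R = %.2f (%.2f to %.2f), p = %.3g, n = %d\n",
              x$R, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}
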
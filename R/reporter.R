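#' Reporter-gene induction factor
#'
#' Ratio of mean treated to mean control readout (optionally
#' protein-normalized), the promoter-activity statistic with the untreated
#' condition defined as 1. The SD is propagated from the spread of the
#' per-replicate treated/control-mean ratios.
#'
#' @param treated data.frame of treated wells with column `readout` (and
#'   `protein` if normalizing).
#' @param control data.frame of control wells, same columns.
#' @param normalize_protein divide each readout by its well's protein
#'   content before averaging.
#' @return list with `induction_factor` and `sd`.
#' @export
induction_factor <- function(treated, control, normalize_protein = FALSE) {
  stopifnot("readout" %in% names(treated), "readout" %in% names(control))
  tx <- treated$readout
  cx <- control$readout
  if (normalize_protein) {
    if (!"protein" %in% names(treated) || !"protein" %in% names(control)) {
      stop("protein column required when normalize_protein = TRUE")
    }
    tx <- tx / treated$protein
    cx <- cx / control$protein
  }
  cm <- mean(cx)
  if (cm <= 0) stop("control mean must be positive")
  ratios <- tx / cm
  list(induction_factor = mean(ratios),
       sd = if (length(ratios) > 1) stats::sd(ratios) else 0)
}

#' Percent transrepression of an induced reporter
#'
#' Fraction of the cytokine-induced reporter activity removed by a
#' compound, computed from induction factors. With baseline correction
#' (primary convention) the solvent level, defined as induction factor 1,
#' is subtracted first: `100 * (1 - (IF_compound - 1) / (IF_inducer - 1))`.
#' Without correction the raw ratio is used:
#' `100 * (1 - IF_compound / IF_inducer)`. Values outside `[0, 100]`
#' (over-repression below baseline, or enhancement) are reported as-is,
#' never clipped.
#'
#' @param if_tnf induction factor of the inducer-only condition (> 1).
#' @param if_compound induction factor of inducer + compound.
#' @param baseline_correct use the baseline-corrected convention (default).
#' @return percent repression (scalar, may lie outside `[0, 100]`).
#' @export
percent_transrepression <- function(if_tnf, if_compound,
                                    baseline_correct = TRUE) {
  if (if_tnf <= 1) stop("if_tnf must exceed 1: no induction to repress")
  if (baseline_correct) {
    100 * (1 - (if_compound - 1) / (if_tnf - 1))
  } else {
    100 * (1 - if_compound / if_tnf)
  }
}

#' Relative mRNA expression from qPCR triplicates (delta-delta-Ct)
#'
#' Takes the median of the Ct triplicates for the target and the
#' housekeeping gene per condition, forms delta-Ct = median(target) -
#' median(housekeeping), and reports `2^-(dCt - dCt_ref)` relative to the
#' reference condition. Amplification efficiency is assumed 100% (factor 2
#' per cycle).
#'
#' @param ct_target named list: condition -> numeric Ct replicates of the
#'   target gene.
#' @param ct_hkg named list: condition -> numeric Ct replicates of the
#'   housekeeping gene; same condition names.
#' @param ref_condition name of the reference condition (relative
#'   expression 1).
#' @return named numeric vector of relative expression per condition.
#' @export
qpcr_relative_expression <- function(ct_target, ct_hkg, ref_condition) {
  stopifnot(is.list(ct_target), is.list(ct_hkg),
            setequal(names(ct_target), names(ct_hkg)))
  if (!ref_condition %in% names(ct_target)) {
    stop("missing reference condition")
  }
  all_ct <- unlist(c(ct_target, ct_hkg))
  if (any(!is.finite(all_ct)) || any(all_ct <= 0) || any(all_ct >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  dct <- vapply(names(ct_target), function(cond) {
    stats::median(ct_target[[cond]]) - stats::median(ct_hkg[[cond]])
  }, numeric(1))
  2^-(dct - dct[[ref_condition]])
}

# pooled-MSE t statistics of every non-control group mean against the
# control mean (the many-to-one comparisons of a Dunnett-style test);
# codes are integer group codes 1..K, ctl the control code
.dunnett_t <- function(values, codes, n_per, ctl, df_w) {
  s <- rowsum(values, codes)
  m <- s / n_per
  msw <- (sum(values^2) - sum(s^2 / n_per)) / df_w
  oth <- setdiff(seq_along(n_per), ctl)
  t_stat <- (m[oth] - m[ctl]) / sqrt(msw * (1 / n_per[oth] + 1 / n_per[ctl]))
  list(t = t_stat, msw = msw, oth = oth)
}

#' One-way ANOVA with resampling many-to-one (max-t) comparisons
#'
#' Computes the one-way ANOVA F statistic across all groups, then compares
#' every treatment group against the control with pooled-variance t
#' statistics and adjusts them family-wise by a permutation max-|t|
#' procedure: group labels are permuted, the maximum absolute t over the
#' many-to-one comparisons is recorded each time, and each observed |t| is
#' referred to that null distribution. This mirrors the familywise control
#' of Dunnett's test without its multivariate-t tables.
#'
#' @param values numeric readouts.
#' @param group group label per value.
#' @param control control group label.
#' @param n_resample number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `F`, `df` (c(between, within)), `p_anova`, and
#'   `comparisons`: data.frame of `group`, `t`, `p_adjusted`.
#' @export
many_to_one_test <- function(values, group, control, n_resample = 999L,
                             seed = 1L) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  if (!control %in% group) stop("control group not present")
  gn <- table(group)
  if (length(gn) < 2) stop("need at least two groups")
  if (any(gn < 2)) stop("every group needs n >= 2")
  levels <- names(gn)
  codes <- match(group, levels)
  n_per <- as.vector(gn)
  ctl <- match(control, levels)
  df_w <- length(values) - length(levels)
  gm <- tapply(values, group, mean)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  dfb <- length(gn) - 1
  obs <- .dunnett_t(values, codes, n_per, ctl, df_w)
  if (obs$msw == 0) {
    if (ssb == 0) stop("all values identical: test degenerate")
    stop("zero within-group variance everywhere: test degenerate")
  }
  f_stat <- (ssb / dfb) / obs$msw
  p_anova <- stats::pf(f_stat, dfb, df_w, lower.tail = FALSE)
  withr::with_seed(seed, {
    max_null <- vapply(seq_len(n_resample), function(i) {
      max(abs(.dunnett_t(sample(values), codes, n_per, ctl, df_w)$t))
    }, numeric(1))
  })
  p_adj <- vapply(abs(obs$t), function(tt) {
    (1 + sum(max_null >= tt)) / (n_resample + 1)
  }, numeric(1))
  list(
    F = unname(f_stat), df = c(between = dfb, within = df_w),
    p_anova = unname(p_anova),
    comparisons = data.frame(group = levels[obs$oth], t = unname(obs$t),
                             p_adjusted = unname(p_adj))
  )
}
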
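# Epistatic coefficient, growth-curve AUC machinery and the hypothesis
# tests used for assay comparisons.

#' Epistatic coefficient between two defense systems
#'
#' Quantifies the interaction strength between two co-encoded systems from
#' efficiency-of-plating values:
#' \deqn{\varepsilon = |log10 EOP_{A+B}| - |log10 EOP_A| - |log10 EOP_B|}
#' For EOPs at most 1 this equals `log10(eop_a * eop_b / eop_both)`:
#' positive when joint protection is super-multiplicative (synergy), zero
#' when exactly multiplicative. The coefficient is set to 0 (`zeroed`)
#' when the mean EOP of the wild-type strain for the phage is at or above
#' `zero_threshold` — no meaningful protection to decompose; the would-be
#' value is kept in `rawEpsilon`.
#'
#' Censored EOPs may be substituted by their bounds: flag them via
#' `censored` and the result records the direction in which the true
#' coefficient lies (`bound = "ge"` when the combined EOP was an upper
#' bound, `"le"` when a single-system EOP was).
#'
#' @param eop_both,eop_a,eop_b Positive EOPs for the double- and
#'   single-system strains.
#' @param wt_mean_eop Mean EOP of the wild-type (both systems) strain for
#'   this phage, used by the zeroing rule.
#' @param zero_threshold Zeroing threshold (default 1e-2).
#' @param censored Logical length-3 vector (`both`, `a`, `b`): which EOPs
#'   are censored upper bounds.
#' @return An [EpistasisResult-class].
#' @examples
#' epistaticCoefficient(1e-6, 1e-2, 1e-1, wt_mean_eop = 1e-6)  # epsilon 3
#' epistaticCoefficient(1e-3, 1e-2, 1e-1, wt_mean_eop = 1e-3)  # epsilon 0
#' @export
epistaticCoefficient <- function(eop_both, eop_a, eop_b, wt_mean_eop,
                                 zero_threshold = 1e-2,
                                 censored = c(both = FALSE, a = FALSE,
                                              b = FALSE)) {
  vals <- c(both = eop_both, a = eop_a, b = eop_b)
  if (any(is.na(vals)) || any(vals <= 0))
    .stopf("epistaticCoefficient: all EOPs must be positive (got %s)",
           paste(format(vals), collapse = ", "))
  if (is.na(wt_mean_eop) || wt_mean_eop <= 0)
    .stopf("epistaticCoefficient: wt_mean_eop must be positive")
  raw <- abs(log10(eop_both)) - abs(log10(eop_a)) - abs(log10(eop_b))
  zeroed <- wt_mean_eop >= zero_threshold
  bound <- "none"
  censored <- rep_len(as.logical(censored), 3L)
  if (censored[1] && !any(censored[2:3])) bound <- "ge"
  else if (!censored[1] && any(censored[2:3])) bound <- "le"
  else if (censored[1] && any(censored[2:3])) bound <- "unknown"
  new("EpistasisResult", epsilon = if (zeroed) 0 else raw,
      rawEpsilon = raw, zeroed = zeroed, components = vals,
      wtMeanEOP = wt_mean_eop, bound = bound)
}

#' Subtract the starting optical density from a growth curve
#'
#' Each point has the first point's value removed, so curves start at 0
#' and the AUC measures growth above the inoculum. Idempotent.
#'
#' @param curve Numeric OD600 series, or a matrix with one column per well
#'   (first row is the start).
#' @return Same shape as the input.
#' @examples
#' baselineSubtract(c(0.1, 0.2, 0.4))  # 0 0.1 0.3
#' @export
baselineSubtract <- function(curve) {
  if (is.matrix(curve)) return(sweep(curve, 2, curve[1, ], "-"))
  if (!length(curve)) .stopf("baselineSubtract: empty series")
  curve - curve[1]
}

#' Area under a growth curve
#'
#' Composite trapezoid rule over the full time range, reported in
#' OD600·hour. The input is expected to be baseline-subtracted (see
#' [baselineSubtract()]); pass `baseline = TRUE` to have it applied here.
#'
#' @param curve Numeric series (or matrix, one column per well).
#' @param time_min Strictly increasing sampling times in minutes.
#' @param baseline Apply baseline subtraction before integrating.
#' @return AUC in OD600·hour (vector for matrix input).
#' @examples
#' areaUnderCurve(seq(0, 1, length.out = 7), seq(0, 60, by = 10))  # 0.5
#' @export
areaUnderCurve <- function(curve, time_min, baseline = FALSE) {
  if (any(diff(time_min) <= 0))
    .stopf("areaUnderCurve: time grid must be strictly increasing")
  if (is.matrix(curve)) {
    if (nrow(curve) != length(time_min))
      .stopf("areaUnderCurve: %d rows vs %d time points",
             nrow(curve), length(time_min))
    if (baseline) curve <- baselineSubtract(curve)
    return(apply(curve, 2, function(y) .trapz(time_min / 60, y)))
  }
  if (length(curve) != length(time_min))
    .stopf("areaUnderCurve: series length %d vs %d time points",
           length(curve), length(time_min))
  if (baseline) curve <- baselineSubtract(curve)
  .trapz(time_min / 60, curve)
}

#' Call synergy from growth-curve AUCs
#'
#' Two systems are synergistic when the strain carrying both grows
#' strictly better than the additive expectation: `aucBoth > aucA + aucB`.
#' Equality is not synergy. All AUCs must come from the same time grid and
#' multiplicity of infection.
#'
#' @param auc_both,auc_a,auc_b AUCs in OD600·hour.
#' @return An [AUCSynergyCall-class].
#' @examples
#' isSynergy(callAucSynergy(10, 3, 4))  # TRUE
#' isSynergy(callAucSynergy(7, 3, 4))   # FALSE: tie is not synergy
#' @export
callAucSynergy <- function(auc_both, auc_a, auc_b) {
  expected <- auc_a + auc_b
  new("AUCSynergyCall", aucBoth = auc_both, aucA = auc_a, aucB = auc_b,
      expectedAdditive = expected, synergy = auc_both > expected)
}

#' Normalize reporter-dye fluorescence to culture density
#'
#' Divides the fluorescence series (propidium iodide, resazurin) pointwise
#' by OD600, with the denominator floored at `floor_od` to avoid blow-ups
#' when lysis drives the density toward zero; floored points are flagged.
#'
#' @param rlu Fluorescence series (relative light units).
#' @param od OD600 series of the same length.
#' @param floor_od Denominator floor (default 0.01 OD).
#' @return A `data.frame` with columns `value` (RLU/OD600) and `flagged`
#'   (`TRUE` where the floor was applied).
#' @export
normalizeReporter <- function(rlu, od, floor_od = 0.01) {
  if (length(rlu) != length(od))
    .stopf("normalizeReporter: series lengths differ (%d vs %d)",
           length(rlu), length(od))
  flagged <- od < floor_od
  data.frame(value = rlu / pmax(od, floor_od), flagged = flagged)
}

#' Pointwise mean and confidence band across replicate curves
#'
#' At each time point, the replicate mean and a symmetric Student-t
#' interval with n-1 degrees of freedom (the 95 percent band drawn around
#' mean growth curves).
#'
#' @param replicates Numeric matrix, time points by replicates (at least
#'   two columns, shared time grid).
#' @param level Confidence level (default 0.95).
#' @return A `data.frame` with columns `mean`, `lower`, `upper`.
#' @examples
#' m <- cbind(c(0.1, 0.2), c(0.2, 0.3), c(0.3, 0.4))
#' replicateBand(t(m))  # 2 replicates per time point
#' @export
replicateBand <- function(replicates, level = 0.95) {
  replicates <- as.matrix(replicates)
  n <- ncol(replicates)
  if (n < 2)
    .stopf("replicateBand: need >= 2 replicates; plot the raw curve instead")
  m <- rowMeans(replicates)
  s <- apply(replicates, 1, sd)
  half <- qt((1 + level) / 2, df = n - 1) * s / sqrt(n)
  data.frame(mean = m, lower = m - half, upper = m + half)
}

#' One-sided Welch t-test (alternative: greater)
#'
#' Unpaired, unequal-variance t-test of `mean(x) > mean(y)`. Normality of
#' each sample is checked first (Shapiro-Wilk) and reported alongside; a
#' warning is emitted when a sample looks non-normal, but the test is
#' never silently switched.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @return A list with `statistic`, `p_value` and `normality_p` (named
#'   length-2 vector; `NA` for samples too small for Shapiro-Wilk).
#' @export
oneSidedGreaterTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    .stopf("oneSidedGreaterTest: each sample needs n >= 2")
  tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
  swp <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 2) return(NA_real_)
    shapiro.test(v)$p.value
  }
  np <- c(x = swp(x), y = swp(y))
  if (any(!is.na(np) & np < 0.05))
    .warnf("normality check failed (Shapiro-Wilk p = %s); t-test reported anyway",
           paste(format(np, digits = 3), collapse = ", "))
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       normality_p = np)
}

#' One-way ANOVA with all-versus-control multiple comparisons
#'
#' Fits a one-way ANOVA across the groups, then compares every group to
#' the named control with family-wise error control: Dunnett's procedure
#' (via \pkg{multcomp}) by default, or per-comparison Welch t-tests with
#' Holm adjustment (`method = "holm"`).
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param control Name of the control group.
#' @param method `"dunnett"` or `"holm"`.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05, on adjusted p-values).
#' @return A list with `f_statistic`, `p_value` (overall ANOVA) and
#'   `comparisons`, a `data.frame` of per-group estimates, adjusted
#'   p-values and significance flags.
#' @export
anovaMultcomp <- function(values, groups, control,
                          method = c("dunnett", "holm"), alpha = 0.05) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2)
    .stopf("anovaMultcomp: need at least two groups")
  if (!control %in% groups)
    .stopf("anovaMultcomp: control group '%s' not found", control)
  if (any(table(groups) < 2))
    .stopf("anovaMultcomp: every group needs n >= 2")
  g <- stats::relevel(factor(groups), ref = control)
  dat <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = dat)
  atab <- summary(fit)[[1]]
  fstat <- atab[["F value"]][1]
  pval <- atab[["Pr(>F)"]][1]
  others <- setdiff(levels(g), control)
  if (method == "dunnett") {
    mc <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(mc)
    est <- unname(sm$test$coefficients)
    padj <- unname(sm$test$pvalues)
  } else {
    est <- padj <- numeric(length(others))
    praw <- numeric(length(others))
    for (i in seq_along(others)) {
      xi <- values[groups == others[i]]
      yi <- values[groups == control]
      est[i] <- mean(xi) - mean(yi)
      praw[i] <- t.test(xi, yi)$p.value
    }
    padj <- p.adjust(praw, method = "holm")
  }
  comparisons <- data.frame(group = others, estimate = est, p_adj = padj,
                            significant = padj < alpha,
                            stringsAsFactors = FALSE)
  list(f_statistic = fstat, p_value = pval, comparisons = comparisons)
}
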
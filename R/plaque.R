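# Titer, EOP, plaque-size fold change and the protection classifiers.

#' Estimate a phage titer from one serial-dilution series
#'
#' Takes the assay rows for a single phage x strain x replicate and
#' quantifies the titer from the most dilute spot whose plaque count falls
#' inside the countable window. Lytic phages that clear the lawn without
#' distinct plaques (`lysis_halo`) are quantified from the most dilute
#' halo-positive spot with the count treated as at least one. A series
#' with no plaques at any dilution is censored below the detection limit
#' `1 / (spot_volume_ml * max(dilution_factor))` — the titer that would
#' have produced about one plaque in the least-diluted spot.
#'
#' @param rows `data.frame` in [readAssayTable()] layout, one phage x
#'   strain x replicate.
#' @param countable_window Plaque counts accepted for quantification
#'   (default 3 to 100). Counts outside the window are used only as a
#'   fallback when no spot is countable.
#' @return A [TiterEstimate-class].
#' @examples
#' rows <- data.frame(dilution_factor = c(1e-6, 1e-7, 1e-8),
#'                    spot_volume_ml = 0.003,
#'                    plaque_count = c(30L, 3L, 0L), lysis_halo = FALSE)
#' estimateTiter(rows)  # 30 / (0.003 * 1e-6) = 1e10 PFU/ml
#' @export
estimateTiter <- function(rows, countable_window = c(3, 100)) {
  if (is.null(rows) || nrow(rows) == 0)
    .stopf("estimateTiter: empty dilution series")
  if (!"lysis_halo" %in% names(rows)) rows$lysis_halo <- FALSE
  dup <- split(seq_len(nrow(rows)), rows$dilution_factor)
  for (idx in dup) {
    if (length(idx) > 1) {
      cnts <- rows$plaque_count[idx]
      if (length(unique(cnts[!is.na(cnts)])) > 1)
        .stopf("conflicting duplicate dilutions at factor %g",
               rows$dilution_factor[idx[1]])
    }
  }
  cnt <- rows$plaque_count
  halo <- rows$lysis_halo
  countable <- !halo & !is.na(cnt) &
    cnt >= countable_window[1] & cnt <= countable_window[2]
  if (any(countable)) {
    i <- which(countable)[which.min(rows$dilution_factor[countable])]
    return(TiterEstimate(
      value = cnt[i] / (rows$spot_volume_ml[i] * rows$dilution_factor[i])))
  }
  if (any(halo)) {
    i <- which(halo)[which.min(rows$dilution_factor[halo])]
    return(TiterEstimate(
      value = 1 / (rows$spot_volume_ml[i] * rows$dilution_factor[i]),
      lysisHalo = TRUE))
  }
  nonzero <- !is.na(cnt) & cnt > 0
  if (!any(nonzero)) {
    i <- which.max(rows$dilution_factor)
    return(TiterEstimate(
      censored = TRUE,
      lod = 1 / (rows$spot_volume_ml[i] * rows$dilution_factor[i])))
  }
  # counts exist but none in the window: fall back to the most dilute
  # nonzero spot (e.g. overgrown plates at every countable dilution)
  i <- which(nonzero)[which.min(rows$dilution_factor[nonzero])]
  TiterEstimate(
    value = cnt[i] / (rows$spot_volume_ml[i] * rows$dilution_factor[i]))
}

#' Efficiency of plating relative to a reference strain
#'
#' `EOP = test titer / reference titer`; `log-protection = -log10(EOP)` is
#' the orders-of-magnitude reduction in titer conferred by the test
#' strain's defenses. A censored test titer propagates as an upper bound
#' on the EOP (`lod / reference`), making log-protection a lower bound.
#'
#' @param test,reference [TiterEstimate-class] objects; the reference must
#'   be uncensored.
#' @param sfc Optional plaque size fold change to attach
#'   (see [sizeFoldChange()]).
#' @return An [EOPResult-class].
#' @examples
#' efficiencyOfPlating(TiterEstimate(1e4), TiterEstimate(1e8))
#' @export
efficiencyOfPlating <- function(test, reference, sfc = NA_real_) {
  stopifnot(is(test, "TiterEstimate"), is(reference, "TiterEstimate"))
  if (reference@censored)
    .stopf("reference titer is censored: no valid EOP denominator")
  if (test@censored) {
    e <- test@lod / reference@value
    return(new("EOPResult", eop = e, censored = TRUE,
               logProtection = -log10(e), sfc = as.numeric(sfc),
               lysisHaloQuantified = reference@lysisHalo))
  }
  e <- test@value / reference@value
  new("EOPResult", eop = e, censored = FALSE, logProtection = -log10(e),
      sfc = as.numeric(sfc),
      lysisHaloQuantified = test@lysisHalo || reference@lysisHalo)
}

#' Plaque size fold change
#'
#' Ratio of mean plaque radius on the test strain to that on the reference
#' strain (typically three plaques each). With `use_area = TRUE` the ratio
#' of mean plaque areas (`radius^2`) is used instead.
#'
#' @param test_radii_mm,reference_radii_mm Non-empty vectors of positive
#'   plaque radii in mm.
#' @param use_area Compare areas instead of radii.
#' @return A positive scalar; 1 means equal plaque size.
#' @examples
#' sizeFoldChange(c(0.4, 0.5, 0.6), c(1, 1, 1))  # 0.5
#' @export
sizeFoldChange <- function(test_radii_mm, reference_radii_mm,
                           use_area = FALSE) {
  if (!length(test_radii_mm) || !length(reference_radii_mm))
    .stopf("sizeFoldChange: both radius lists must be non-empty")
  if (any(test_radii_mm <= 0) || any(reference_radii_mm <= 0))
    .stopf("sizeFoldChange: radii must be positive")
  if (use_area)
    mean(test_radii_mm^2) / mean(reference_radii_mm^2)
  else
    mean(test_radii_mm) / mean(reference_radii_mm)
}

#' Classify protection from log-protection
#'
#' A strain is called protected when the titer reduction strictly exceeds
#' ten-fold, i.e. log-protection > 1. A censored lower bound above the
#' threshold is conclusive and also called protected; a censored bound at
#' or below the threshold cannot demonstrate protection and returns
#' `FALSE`.
#'
#' @param x An [EOPResult-class], or a numeric log-protection value.
#' @param threshold Strict log10 threshold (default 1).
#' @return Logical.
#' @examples
#' classifyProtection(1.0)  # FALSE: strictly greater than required
#' classifyProtection(1.3)  # TRUE
#' @export
classifyProtection <- function(x, threshold = 1) {
  lp <- if (is(x, "EOPResult")) x@logProtection else as.numeric(x)
  lp > threshold
}

#' Classify at-least-modest protection from EOP and SFC
#'
#' True when either the efficiency of plating is below `eop_threshold`
#' (default 0.01) **or** the plaque size fold change is below
#' `sfc_threshold` (default 0.5) — a disjunction, so strains that only
#' shrink plaques still qualify.
#'
#' @param eop Efficiency of plating (`NA` if unavailable).
#' @param sfc Size fold change (`NA` if unavailable).
#' @param eop_threshold,sfc_threshold Strict upper thresholds.
#' @return Logical; error if both inputs are `NA`.
#' @examples
#' classifyModestProtection(eop = 0.005, sfc = 1.0)  # TRUE (EOP branch)
#' classifyModestProtection(eop = 0.02, sfc = 0.6)   # FALSE
#' @export
classifyModestProtection <- function(eop = NA_real_, sfc = NA_real_,
                                     eop_threshold = 0.01,
                                     sfc_threshold = 0.5) {
  if (is.na(eop) && is.na(sfc))
    .stopf("classifyModestProtection: need at least one of eop, sfc")
  (!is.na(eop) && eop < eop_threshold) ||
    (!is.na(sfc) && sfc < sfc_threshold)
}

#' Per-phage EOP/SFC summary against a reference strain
#'
#' For every phage x strain combination, computes per-replicate titers and
#' EOPs against the same replicate of `reference_strain`, then aggregates
#' (geometric mean for EOP, respecting its log scale; arithmetic mean for
#' SFC) and applies both protection classifiers. If any replicate EOP is
#' censored the aggregated EOP is flagged as an upper bound.
#'
#' @param assay Assay `data.frame` from [readAssayTable()].
#' @param reference_strain Name of the reference (fully susceptible)
#'   strain present in `assay`.
#' @param countable_window Passed to [estimateTiter()].
#' @return A `data.frame` with one row per phage x non-reference strain:
#'   `phage`, `strain`, `eop`, `eop_censored`, `sfc`, `log_protection`,
#'   `protected`, `modest_protection`.
#' @export
eopTable <- function(assay, reference_strain,
                     countable_window = c(3, 100)) {
  if (!reference_strain %in% assay$strain)
    .stopf("reference strain '%s' not present in assay table",
           reference_strain)
  has_radii <- "plaque_radii_mm" %in% names(assay)
  phages <- unique(assay$phage)
  strains <- setdiff(unique(assay$strain), reference_strain)
  out <- list()
  for (ph in phages) {
    for (st in strains) {
      eops <- numeric(0); cens <- logical(0); sfcs <- numeric(0)
      reps <- sort(unique(assay$replicate[assay$phage == ph &
                                            assay$strain == st]))
      for (r in reps) {
        t_rows <- assay[assay$phage == ph & assay$strain == st &
                          assay$replicate == r, , drop = FALSE]
        r_rows <- assay[assay$phage == ph &
                          assay$strain == reference_strain &
                          assay$replicate == r, , drop = FALSE]
        if (!nrow(t_rows) || !nrow(r_rows)) next
        tt <- estimateTiter(t_rows, countable_window)
        rt <- estimateTiter(r_rows, countable_window)
        if (rt@censored) next  # reference below LOD: no denominator
        res <- efficiencyOfPlating(tt, rt)
        eops <- c(eops, res@eop); cens <- c(cens, res@censored)
        if (has_radii) {
          t_rad <- unlist(t_rows$plaque_radii_mm)
          r_rad <- unlist(r_rows$plaque_radii_mm)
          if (length(t_rad) && length(r_rad))
            sfcs <- c(sfcs, sizeFoldChange(t_rad, r_rad))
        }
      }
      if (!length(eops)) next
      eop_mean <- .geomMean(eops)
      sfc_mean <- if (length(sfcs)) mean(sfcs) else NA_real_
      lp <- -log10(eop_mean)
      out[[length(out) + 1L]] <- data.frame(
        phage = ph, strain = st, eop = eop_mean,
        eop_censored = any(cens), sfc = sfc_mean, log_protection = lp,
        protected = classifyProtection(lp),
        modest_protection = classifyModestProtection(eop_mean, sfc_mean),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(phage = character(0), strain = character(0),
                      eop = numeric(0), eop_censored = logical(0),
                      sfc = numeric(0), log_protection = numeric(0),
                      protected = logical(0),
                      modest_protection = logical(0)))
  do.call(rbind, out)
}
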
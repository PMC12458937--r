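# S4 result containers and the growth-curve data object.

#' TiterEstimate: a phage titer from one dilution series
#'
#' Result of [estimateTiter()]. When no plaques are observed at any dilution
#' the titer is censored below the limit of detection (LOD) and `value` is
#' `NA`; otherwise `value` is the point estimate in PFU/ml.
#'
#' @slot value Titer in PFU/ml (`NA` when censored).
#' @slot censored `TRUE` when the titer is below the detection limit.
#' @slot lod Limit of detection in PFU/ml (reporting bound when censored).
#' @slot lysisHalo `TRUE` when the titer was quantified from a lysis halo
#'   rather than countable plaques (count treated as at least one).
#' @exportClass TiterEstimate
setClass("TiterEstimate",
         representation(value = "numeric", censored = "logical",
                        lod = "numeric", lysisHalo = "logical"),
         prototype(value = NA_real_, censored = FALSE, lod = NA_real_,
                   lysisHalo = FALSE))

setValidity("TiterEstimate", function(object) {
  if (object@censored) {
    if (!is.na(object@value)) return("censored titer must have NA value")
    if (is.na(object@lod) || object@lod <= 0)
      return("censored titer requires a positive lod")
  } else if (is.na(object@value) || object@value <= 0) {
    return("uncensored titer must be a positive value")
  }
  TRUE
})

#' @rdname TiterEstimate-class
#' @param value,censored,lod,lysisHalo see slot documentation.
#' @return A `TiterEstimate` object.
#' @export
TiterEstimate <- function(value = NA_real_, censored = FALSE,
                          lod = NA_real_, lysisHalo = FALSE) {
  new("TiterEstimate", value = as.numeric(value), censored = censored,
      lod = as.numeric(lod), lysisHalo = lysisHalo)
}

#' EOPResult: efficiency of plating relative to a reference strain
#'
#' Result of [efficiencyOfPlating()]. `eop` is the ratio of test to
#' reference titer; when the test titer is censored, `eop` holds the upper
#' bound `lod/reference` and `censored` is `TRUE`, in which case
#' `logProtection` is a lower bound.
#'
#' @slot eop Efficiency of plating (upper bound when censored).
#' @slot censored `TRUE` when the EOP is an upper bound.
#' @slot logProtection `-log10(eop)`; lower bound when censored.
#' @slot sfc Plaque size fold change, `NA` when radii were not measured.
#' @slot lysisHaloQuantified `TRUE` when either titer came from a lysis halo.
#' @exportClass EOPResult
setClass("EOPResult",
         representation(eop = "numeric", censored = "logical",
                        logProtection = "numeric", sfc = "numeric",
                        lysisHaloQuantified = "logical"),
         prototype(sfc = NA_real_, censored = FALSE,
                   lysisHaloQuantified = FALSE))

setValidity("EOPResult", function(object) {
  if (is.na(object@eop) || object@eop <= 0) return("eop must be positive")
  if (abs(object@logProtection + log10(object@eop)) > 1e-9)
    return("logProtection must equal -log10(eop)")
  if (!is.na(object@sfc) && object@sfc <= 0) return("sfc must be positive")
  TRUE
})

#' EpistasisResult: interaction strength between two defense systems
#'
#' Result of [epistaticCoefficient()]. The coefficient is
#' `|log10 EOP(both)| - |log10 EOP(A)| - |log10 EOP(B)|`; it is forced to
#' zero (and `zeroed` set) when the mean wild-type EOP for the phage is at
#' or above the no-protection threshold, with the would-be value retained
#' in `rawEpsilon` for diagnostics.
#'
#' @slot epsilon The reported coefficient (0 when zeroed).
#' @slot rawEpsilon The coefficient before the zeroing rule.
#' @slot zeroed `TRUE` when the zeroing rule applied.
#' @slot components Named numeric: the three input EOPs.
#' @slot wtMeanEOP Mean EOP of the strain carrying both systems' wild type.
#' @slot bound `"none"`, `"ge"` (epsilon is a lower bound) or `"le"`
#'   (upper bound), set when censored EOP bounds entered the formula.
#' @exportClass EpistasisResult
setClass("EpistasisResult",
         representation(epsilon = "numeric", rawEpsilon = "numeric",
                        zeroed = "logical", components = "numeric",
                        wtMeanEOP = "numeric", bound = "character"),
         prototype(bound = "none"))

#' AUCSynergyCall: additive-expectation synergy test on growth-curve AUCs
#'
#' Result of [callAucSynergy()]. Two systems are called synergistic when
#' the AUC of the strain carrying both strictly exceeds the sum of the
#' single-system AUCs (the expected additive value).
#'
#' @slot aucBoth,aucA,aucB Areas under the baseline-subtracted growth
#'   curves, in OD600·hour.
#' @slot expectedAdditive `aucA + aucB`.
#' @slot synergy `TRUE` iff `aucBoth > expectedAdditive` (strict).
#' @exportClass AUCSynergyCall
setClass("AUCSynergyCall",
         representation(aucBoth = "numeric", aucA = "numeric",
                        aucB = "numeric", expectedAdditive = "numeric",
                        synergy = "logical"))

#' FamilyAssignment: protein-family clustering result
#'
#' Result of [clusterProteinFamilies()]. Greedy incremental clusters:
#' every member belongs to exactly one family, each family is named after
#' its founding representative's rank, and every non-representative member
#' aligns to its representative at or above the identity and mutual
#' coverage thresholds.
#'
#' @slot members Named character: member id -> family id.
#' @slot representatives Named character: family id -> representative id.
#' @slot parameters Named numeric: identity and coverage thresholds used.
#' @exportClass FamilyAssignment
setClass("FamilyAssignment",
         representation(members = "character", representatives = "character",
                        parameters = "numeric"))

setValidity("FamilyAssignment", function(object) {
  if (is.null(names(object@members))) return("members must be named")
  if (!all(object@members %in% names(object@representatives)))
    return("every member family must have a representative")
  reps <- object@representatives
  if (!all(object@members[reps] == names(reps)))
    return("each representative must belong to its own family")
  TRUE
})

#' GrowthCurveSet: plate-reader time series for one experiment
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding
#' replicate OD600 (and optionally fluorescence) series on a shared time
#' grid. Rows are time points (`timeMin(x)` in minutes, strictly
#' increasing); columns are wells with `colData` columns `strain`, `phage`,
#' `moi`, `dye` and `replicate`.
#'
#' @exportClass GrowthCurveSet
setClass("GrowthCurveSet", contains = "SummarizedExperiment")

setValidity("GrowthCurveSet", function(object) {
  if (!"od600" %in% assayNames(object)) return("assay 'od600' is required")
  tm <- rowData(object)$time_min
  if (is.null(tm)) return("rowData must carry 'time_min'")
  if (length(tm) > 1 && any(diff(tm) <= 0))
    return("time_min must be strictly increasing")
  needed <- c("strain", "phage", "moi", "dye", "replicate")
  missing <- setdiff(needed, colnames(colData(object)))
  if (length(missing))
    return(paste("colData lacks:", paste(missing, collapse = ", ")))
  TRUE
})

#' Construct a GrowthCurveSet
#'
#' @param od600 Numeric matrix, time points by wells.
#' @param time_min Strictly increasing time grid in minutes.
#' @param colData A `data.frame`/`DataFrame` with one row per well and
#'   columns `strain`, `phage`, `moi`, `dye`, `replicate`.
#' @param fluorescence Optional matrix of the same shape as `od600`
#'   (relative light units).
#' @return A [GrowthCurveSet-class] object.
#' @examples
#' tm <- seq(0, 90, by = 10)
#' od <- matrix(rep(seq(0.1, 1, length.out = 10), 3), ncol = 3)
#' cd <- data.frame(strain = "wt", phage = "none", moi = 0, dye = "none",
#'                  replicate = 1:3)
#' gcs <- GrowthCurveSet(od, tm, cd)
#' @export
GrowthCurveSet <- function(od600, time_min, colData, fluorescence = NULL) {
  od600 <- as.matrix(od600)
  if (nrow(od600) != length(time_min))
    .stopf("od600 has %d rows but time grid has %d points",
           nrow(od600), length(time_min))
  assays <- list(od600 = od600)
  if (!is.null(fluorescence)) {
    fluorescence <- as.matrix(fluorescence)
    if (!identical(dim(fluorescence), dim(od600)))
      .stopf("fluorescence and od600 dimensions differ")
    assays$fluorescence <- fluorescence
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(time_min = as.numeric(time_min)),
    colData = DataFrame(colData))
  new("GrowthCurveSet", se)
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "TiterEstimate", function(object) {
  if (object@censored) {
    cat(sprintf("TiterEstimate: censored, < %.4g PFU/ml (LOD)\n", object@lod))
  } else {
    cat(sprintf("TiterEstimate: %.4g PFU/ml%s\n", object@value,
                if (object@lysisHalo) " (lysis halo, >= bound)" else ""))
  }
})

setMethod("show", "EOPResult", function(object) {
  cat(sprintf("EOPResult: EOP %s%.4g, log-protection %s%.3f%s\n",
              if (object@censored) "< " else "", object@eop,
              if (object@censored) "> " else "", object@logProtection,
              if (is.na(object@sfc)) "" else sprintf(", SFC %.3f", object@sfc)))
})

setMethod("show", "EpistasisResult", function(object) {
  cat(sprintf(
    "EpistasisResult: epsilon %s%.4f%s (raw %.4f, WT mean EOP %.3g)\n",
    switch(object@bound, ge = ">= ", le = "<= ", ""),
    object@epsilon, if (object@zeroed) " [zeroed]" else "",
    object@rawEpsilon, object@wtMeanEOP))
})

setMethod("show", "AUCSynergyCall", function(object) {
  cat(sprintf(
    "AUCSynergyCall: both %.3f vs additive %.3f OD·h -> %s\n",
    object@aucBoth, object@expectedAdditive,
    if (object@synergy) "SYNERGY" else "no synergy"))
})

setMethod("show", "FamilyAssignment", function(object) {
  cat(sprintf("FamilyAssignment: %d members in %d families (identity >= %.2f, coverage >= %.2f)\n",
              length(object@members), length(object@representatives),
              object@parameters[["identity"]], object@parameters[["coverage"]]))
})

# ---- accessors --------------------------------------------------------------

#' @describeIn TiterEstimate-class the titer point estimate (PFU/ml).
#' @param object,x an object of the documented class.
#' @export
setGeneric("titerValue", function(object) standardGeneric("titerValue"))
#' @rdname TiterEstimate-class
#' @export
setMethod("titerValue", "TiterEstimate", function(object) object@value)

#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))
#' @describeIn TiterEstimate-class whether the estimate is below the LOD.
#' @export
setMethod("isCensored", "TiterEstimate", function(object) object@censored)
#' @describeIn EOPResult-class whether the EOP is an upper bound.
#' @export
setMethod("isCensored", "EOPResult", function(object) object@censored)

#' @describeIn TiterEstimate-class the limit of detection (PFU/ml).
#' @export
setGeneric("titerLOD", function(object) standardGeneric("titerLOD"))
#' @rdname TiterEstimate-class
#' @export
setMethod("titerLOD", "TiterEstimate", function(object) object@lod)

#' @describeIn EOPResult-class the efficiency of plating.
#' @export
setGeneric("eop", function(object) standardGeneric("eop"))
#' @rdname EOPResult-class
#' @export
setMethod("eop", "EOPResult", function(object) object@eop)

#' @describeIn EOPResult-class `-log10(EOP)`, the orders of magnitude of
#'   titer reduction.
#' @export
setGeneric("logProtection", function(object) standardGeneric("logProtection"))
#' @rdname EOPResult-class
#' @export
setMethod("logProtection", "EOPResult", function(object) object@logProtection)

#' @describeIn EpistasisResult-class the (possibly zeroed) coefficient.
#' @export
setGeneric("epsilon", function(object) standardGeneric("epsilon"))
#' @rdname EpistasisResult-class
#' @export
setMethod("epsilon", "EpistasisResult", function(object) object@epsilon)

#' @describeIn EpistasisResult-class whether the zeroing rule applied.
#' @export
setGeneric("isZeroed", function(object) standardGeneric("isZeroed"))
#' @rdname EpistasisResult-class
#' @export
setMethod("isZeroed", "EpistasisResult", function(object) object@zeroed)

#' @describeIn AUCSynergyCall-class the boolean synergy call.
#' @export
setGeneric("isSynergy", function(object) standardGeneric("isSynergy"))
#' @rdname AUCSynergyCall-class
#' @export
setMethod("isSynergy", "AUCSynergyCall", function(object) object@synergy)

#' @describeIn AUCSynergyCall-class the additive expectation `aucA + aucB`.
#' @export
setGeneric("expectedAdditive",
           function(object) standardGeneric("expectedAdditive"))
#' @rdname AUCSynergyCall-class
#' @export
setMethod("expectedAdditive", "AUCSynergyCall",
          function(object) object@expectedAdditive)

#' @describeIn FamilyAssignment-class named vector member id -> family id.
#' @export
setGeneric("familyOf", function(object) standardGeneric("familyOf"))
#' @rdname FamilyAssignment-class
#' @export
setMethod("familyOf", "FamilyAssignment", function(object) object@members)

#' @describeIn FamilyAssignment-class named vector family id ->
#'   representative member id.
#' @export
setGeneric("representatives",
           function(object) standardGeneric("representatives"))
#' @rdname FamilyAssignment-class
#' @export
setMethod("representatives", "FamilyAssignment",
          function(object) object@representatives)

#' @describeIn GrowthCurveSet-class the shared time grid in minutes.
#' @export
setGeneric("timeMin", function(x) standardGeneric("timeMin"))
#' @rdname GrowthCurveSet-class
#' @export
setMethod("timeMin", "GrowthCurveSet",
          function(x) rowData(x)$time_min)

#' @describeIn GrowthCurveSet-class the OD600 matrix (time by well).
#' @export
setGeneric("od600", function(x) standardGeneric("od600"))
#' @rdname GrowthCurveSet-class
#' @export
setMethod("od600", "GrowthCurveSet", function(x) assay(x, "od600"))

#' @describeIn GrowthCurveSet-class the fluorescence matrix or `NULL`.
#' @export
setGeneric("fluorescenceRLU", function(x) standardGeneric("fluorescenceRLU"))
#' @rdname GrowthCurveSet-class
#' @export
setMethod("fluorescenceRLU", "GrowthCurveSet", function(x) {
  if ("fluorescence" %in% assayNames(x)) assay(x, "fluorescence") else NULL
})
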
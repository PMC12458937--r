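#' Default analysis thresholds
#'
#' All thresholds used across DefenseKit, overridable individually or from
#' a YAML file ([readDefenseConfig()]). Defaults are the values used
#' throughout the package's analyses.
#'
#' @param ... Named overrides of individual defaults.
#' @return A named list of thresholds:
#' \describe{
#'   \item{countable_window}{plaque counts accepted for titer quantification
#'     (default 3 to 100).}
#'   \item{protection_log10}{log10 titer-reduction threshold above which a
#'     strain is called protected (strict; default 1, i.e. >10-fold).}
#'   \item{eop_modest, sfc_modest}{"at least modest protection" thresholds:
#'     EOP < 0.01 or SFC < 0.5.}
#'   \item{epsilon_wt_threshold}{the epistatic coefficient is zeroed when
#'     the mean wild-type EOP is at or above this (default 1e-2).}
#'   \item{sfc_use_area}{compute SFC as an area rather than radius ratio.}
#'   \item{od_floor}{OD600 floor for reporter normalization (default 0.01).}
#'   \item{identity_threshold, coverage_threshold}{protein-family clustering
#'     cutoffs (default 0.90 identity over 0.80 mutual coverage).}
#'   \item{gap_opening, gap_extension}{global-alignment gap penalties
#'     (BLOSUM62; default 11/1).}
#'   \item{max_content_diff}{maximum gene-content differences when grouping
#'     islands (default 3).}
#'   \item{min_flank_orfs}{minimum ORFs between an island and a contig end
#'     (default 10).}
#'   \item{neighborhood_flank}{genes extracted on each side of an anchor
#'     (default 50).}
#'   \item{dr_min_len, dr_max_len, dr_max_mismatch}{direct-repeat length
#'     range (16-20 nt) and mismatch tolerance (1).}
#'   \item{max_span}{maximum element span in nt (default 200000).}
#'   \item{anchor_tail, anchor_ext}{the tRNA anchor window: last
#'     `anchor_tail` nt of the gene plus `anchor_ext` nt past its 3' end
#'     (default 25 + 5).}
#'   \item{multcomp_method}{"dunnett" or "holm" for [anovaMultcomp()].}
#' }
#' @examples
#' cfg <- defenseConfig(max_span = 1e5)
#' cfg$max_span
#' @export
defenseConfig <- function(...) {
  defaults <- list(
    countable_window = c(3, 100),
    protection_log10 = 1,
    eop_modest = 0.01,
    sfc_modest = 0.5,
    epsilon_wt_threshold = 1e-2,
    sfc_use_area = FALSE,
    od_floor = 0.01,
    identity_threshold = 0.90,
    coverage_threshold = 0.80,
    gap_opening = 11,
    gap_extension = 1,
    max_content_diff = 3,
    min_flank_orfs = 10,
    neighborhood_flank = 50,
    dr_min_len = 16,
    dr_max_len = 20,
    dr_max_mismatch = 1,
    max_span = 200000,
    anchor_tail = 25,
    anchor_ext = 5,
    multcomp_method = "dunnett"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    .stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  modifyList(defaults, overrides)
}

#' Read thresholds from a YAML configuration file
#'
#' Keys absent from the file keep their [defenseConfig()] defaults.
#'
#' @param path Path to a YAML file with a flat mapping of threshold names.
#' @return A configuration list as from [defenseConfig()].
#' @export
readDefenseConfig <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(defenseConfig, vals)
}
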
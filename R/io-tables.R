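# Delimited-table I/O for plaque assays and BED export of element calls.
# Tables are UTF-8, first row a header, comma or tab auto-detected.

.ASSAY_REQUIRED <- c("phage", "strain", "replicate", "dilution_factor",
                     "spot_volume_ml", "plaque_count")

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a plaque-assay table
#'
#' Long-format delimited text (comma or tab, auto-detected) with one row
#' per spotted dilution. Required columns: `phage`, `strain`, `replicate`,
#' `dilution_factor` (a fraction, at most 1), `spot_volume_ml` and
#' `plaque_count`. Optional columns: `lysis_halo` (logical; lawn-clearing
#' spots without countable plaques) and `plaque_radii_mm` (semicolon-
#' separated radii, parsed into a list column). Zero counts are data
#' (phage below detection), not missing values, and are preserved.
#'
#' @param path Path to the delimited file.
#' @return A `data.frame` with typed columns as above.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("phage,strain,replicate,dilution_factor,spot_volume_ml,plaque_count",
#'              "p1,wt,1,1e-6,0.003,30",
#'              "p1,wt,1,1e-7,0.003,3",
#'              "p1,wt,1,1e-8,0.003,0"), f)
#' readAssayTable(f)
#' @export
readAssayTable <- function(path) {
  if (!file.exists(path)) .stopf("assay table not found: %s", path)
  df <- read.table(path, header = TRUE, sep = .detectSep(path),
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(.ASSAY_REQUIRED, names(df))
  if (length(missing))
    .stopf("assay table '%s' lacks required column(s): %s",
           path, paste(missing, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df$dilution_factor <- as.numeric(df$dilution_factor)
  df$spot_volume_ml <- as.numeric(df$spot_volume_ml)
  df$plaque_count <- suppressWarnings(as.integer(df$plaque_count))
  if (!"lysis_halo" %in% names(df)) df$lysis_halo <- FALSE
  df$lysis_halo <- as.logical(df$lysis_halo)
  df$lysis_halo[is.na(df$lysis_halo)] <- FALSE
  if ("plaque_radii_mm" %in% names(df)) {
    df$plaque_radii_mm <- lapply(df$plaque_radii_mm, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(as.character(s), ";")[[1]])
    })
  }
  bad <- which(!df$lysis_halo &
                 (is.na(df$plaque_count) | df$plaque_count < 0))
  bad <- c(bad, which(is.na(df$dilution_factor) | df$dilution_factor <= 0 |
                        df$dilution_factor > 1))
  bad <- c(bad, which(is.na(df$spot_volume_ml) | df$spot_volume_ml <= 0))
  bad <- sort(unique(bad))
  if (length(bad))
    .stopf("invalid assay rows (negative/missing counts, dilution outside (0,1], or bad volume): rows %s",
           paste(bad, collapse = ", "))
  if ("replicate" %in% names(df) && any(df$replicate < 1))
    .stopf("replicate numbers must be >= 1")
  # dilution series should be non-increasing within each phage x strain x rep
  key <- paste(df$phage, df$strain, df$replicate, sep = "\r")
  unordered <- vapply(split(df$dilution_factor, key),
                      function(d) any(diff(d) > 0), logical(1))
  if (any(unordered))
    .warnf("dilution series not in non-increasing order for: %s",
           paste(gsub("\r", "/", names(unordered)[unordered]), collapse = "; "))
  df
}

#' Write a plaque-assay table
#'
#' Inverse of [readAssayTable()]; the round trip preserves all values.
#'
#' @param df Assay `data.frame`.
#' @param path Output path.
#' @param sep Field separator (`","` or `"\t"`).
#' @return Invisibly, `path`.
#' @export
writeAssayTable <- function(df, path, sep = ",") {
  out <- df
  if ("plaque_radii_mm" %in% names(out) && is.list(out$plaque_radii_mm)) {
    out$plaque_radii_mm <- vapply(out$plaque_radii_mm, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = ";"),
      character(1))
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write element calls as BED6
#'
#' One line per element: chrom, 0-based half-open span, element id, the
#' repeat mismatch count as score, and the anchoring tRNA's strand. An
#' empty call set produces an empty file (no header line).
#'
#' @param calls `GRanges` of element calls from [callElements()].
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
writeElementsBed <- function(calls, path) {
  if (!length(calls)) { file.create(path); return(invisible(path)) }
  z <- coords0(calls)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   z$seqnames, z$start, z$end,
                   mcols(calls)$element_id, mcols(calls)$mismatches,
                   z$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of element spans
#'
#' Minimal BED6 reader for round-tripping [writeElementsBed()] output.
#'
#' @param path BED file path.
#' @return `GRanges` with `element_id` and `mismatches` metadata columns.
#' @export
readElementsBed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  if (file.size(path) == 0)
    return(GRanges(element_id = character(0), mismatches = integer(0)))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"))
  GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand,
          element_id = df$name, mismatches = as.integer(df$score))
}
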
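# Internal helpers shared across modules.

#' Structured filter logging
#'
#' Every threshold application in the package reports what it did through
#' this hook: operation name, threshold value, rows in, rows out. Silent by
#' default; set `options(DefenseKit.verbose = TRUE)` to see the log lines.
#' @noRd
.dkLog <- function(op, threshold, n_in, n_out) {
  if (isTRUE(getOption("DefenseKit.verbose", FALSE))) {
    message(sprintf("[DefenseKit] op=%s threshold=%s n_in=%d n_out=%d",
                    op, paste(format(threshold), collapse = ","),
                    as.integer(n_in), as.integer(n_out)))
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# geometric mean of strictly positive values
.geomMean <- function(x) exp(mean(log(x)))

# composite trapezoid rule; t and y same length, t strictly increasing
.trapz <- function(t, y) {
  if (length(t) != length(y))
    .stopf("time and value vectors differ in length (%d vs %d)",
           length(t), length(y))
  if (length(t) < 2) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Zero-based half-open coordinates of a GRanges
#'
#' DefenseKit stores genomic features as `GRanges` (1-based, closed, the
#' Bioconductor convention). BED output and some downstream consumers use
#' 0-based half-open spans; this accessor performs the conversion.
#'
#' @param x A `GRanges` object.
#' @return A `data.frame` with columns `seqnames`, `start` (0-based),
#'   `end` (half-open, equal to the 1-based closed end) and `strand`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr", IRanges::IRanges(101, 200))
#' coords0(gr)  # start 100, end 200
#' @export
coords0 <- function(x) {
  stopifnot(is(x, "GRanges"))
  data.frame(seqnames = as.character(seqnames(x)),
             start = start(x) - 1L, end = end(x),
             strand = as.character(strand(x)),
             stringsAsFactors = FALSE)
}

# Hamming distance between two equal-length sequences given as single
# strings; 'N' never matches anything, including another 'N'.
.hamming <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    .stopf("sequences differ in length (%d vs %d)", length(ca), length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

# derive a reproducible sub-stream seed from a master seed and a fixed
# generator label, so adding one generator never perturbs the others
.substreamSeed <- function(seed, label) {
  offsets <- c(plaque = 1L, growth = 2L, genome = 3L, islands = 4L)
  if (!label %in% names(offsets)) .stopf("unknown generator label '%s'", label)
  (as.integer(seed) %% 268435456L) * 8L + offsets[[label]]
}
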
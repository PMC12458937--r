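# Detection of tRNA-anchored integrated mobile elements bounded by short
# direct repeats, element calling and keyword-based mobility
# classification.

# fast Hamming between two equal-width DNA character strings; N never
# matches anything (including another N)
.hammingDNA <- function(a, b) .hamming(a, b)

# plus-strand scan of one tRNA: the anchor window is the last
# `anchor_tail` nt of the gene plus `anchor_ext` nt past its 3' end; each
# k-mer starting in the window is searched downstream (up to max_span past
# the 3' end) for same-strand occurrences within the mismatch budget.
.scanPlus <- function(seq_string, trna_start, trna_end, trna_id,
                      min_len, max_len, max_mismatch, max_span,
                      anchor_tail, anchor_ext) {
  L <- nchar(seq_string)
  subject <- DNAString(seq_string)
  ws <- max(1L, trna_end - anchor_tail + 1L)
  we <- min(L, trna_end + anchor_ext)
  scan_from <- trna_end + 1L
  scan_to <- min(L, trna_end + max_span)
  hits <- list()
  if (scan_from > scan_to) return(hits)
  region <- subseq(subject, scan_from, scan_to)
  for (k in min_len:max_len) {
    for (s in ws:we) {
      if (s + k - 1L > L) next
      anchor_seq <- substr(seq_string, s, s + k - 1L)
      if (grepl("N", anchor_seq, fixed = TRUE)) next
      m <- matchPattern(DNAString(anchor_seq), region,
                        max.mismatch = max_mismatch, with.indels = FALSE)
      if (!length(m)) next
      d_abs <- start(m) + scan_from - 1L
      for (d in d_abs) {
        if (d < s + k) next  # distal copy must not overlap the anchor copy
        distal_seq <- substr(seq_string, d, d + k - 1L)
        mm <- .hammingDNA(anchor_seq, distal_seq)
        if (mm > max_mismatch) next
        hits[[length(hits) + 1L]] <- data.frame(
          trna_id = trna_id, anchor_start = s, anchor_end = s + k - 1L,
          distal_start = d, distal_end = d + k - 1L,
          length = k, mismatches = mm,
          anchor_seq = anchor_seq, distal_seq = distal_seq,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits
}

# keep the dominant hit among nested/overlapping candidates at one tRNA:
# two hits conflict when both their anchor spans and their distal spans
# overlap; precedence is fewest mismatches, then longest, then smallest
# distal start. Mismatch count outranks length because otherwise an exact
# k-mer repeat is always absorbed into a (k+1)-mer that spends the
# mismatch budget on the extension base, and the true repeat length could
# never be reported.
.collapseHits <- function(df) {
  if (nrow(df) < 2) return(df)
  ord <- order(df$mismatches, -df$length, df$distal_start)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (df$trna_id[i] == df$trna_id[j] &&
          df$anchor_start[i] <= df$anchor_end[j] &&
          df$anchor_end[i] >= df$anchor_start[j] &&
          df$distal_start[i] <= df$distal_end[j] &&
          df$distal_end[i] >= df$distal_start[j]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$trna_id, df$distal_start), , drop = FALSE]
}

#' Find tRNA-anchored direct repeats
#'
#' Scans a genome for pairs of short direct repeats that mark integrated
#' mobile elements: one copy overlapping the 3' end of a tRNA/tmRNA gene
#' (the integration attachment site), the second at the distal element
#' boundary, 16-20 nt long with at most one mismatch (Hamming;
#' substitutions only), within `max_span` of the tRNA in the tRNA's
#' reading direction. Minus-strand tRNAs are handled by scanning the
#' reverse complement and mapping coordinates back. Nested/overlapping
#' candidates are collapsed, keeping the fewest-mismatch, then longest,
#' then nearest hit. `N` bases never match.
#'
#' @param genome A `DNAString`, single-sequence `DNAStringSet`, or
#'   character string (uppercase ACGT, N allowed).
#' @param trnas `GRanges` of tRNA/tmRNA genes with a `gene_id` column;
#'   must lie within the genome.
#' @param min_len,max_len Repeat length range (default 16-20 nt).
#' @param max_mismatch Mismatch budget (default 1).
#' @param max_span Maximum distance scanned past the tRNA 3' end
#'   (default 200 kb).
#' @param anchor_tail,anchor_ext Anchor window definition: last
#'   `anchor_tail` nt of the tRNA plus `anchor_ext` nt past its 3' end.
#' @return A `data.frame` of repeat hits: `trna_id`, `strand`,
#'   `anchor_start/end`, `distal_start/end` (1-based closed genome
#'   coordinates), `length`, `mismatches`, and the two repeat sequences
#'   read in the tRNA's direction.
#' @export
findTrnaAnchoredRepeats <- function(genome, trnas, min_len = 16,
                                    max_len = 20, max_mismatch = 1,
                                    max_span = 200000, anchor_tail = 25,
                                    anchor_ext = 5) {
  if (is(genome, "DNAStringSet")) {
    if (length(genome) != 1)
      .stopf("findTrnaAnchoredRepeats: expected a single replicon")
    genome <- genome[[1]]
  }
  if (is.character(genome)) genome <- DNAString(genome)
  seq_plus <- as.character(genome)
  L <- nchar(seq_plus)
  if (any(start(trnas) < 1) || any(end(trnas) > L))
    .stopf("tRNA coordinates outside genome bounds (length %d)", L)
  seq_minus <- as.character(reverseComplement(genome))

  empty <- data.frame(trna_id = character(0), strand = character(0),
                      anchor_start = integer(0), anchor_end = integer(0),
                      distal_start = integer(0), distal_end = integer(0),
                      length = integer(0), mismatches = integer(0),
                      anchor_seq = character(0), distal_seq = character(0),
                      stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_along(trnas)) {
    id <- mcols(trnas)$gene_id[i]
    st <- as.character(strand(trnas))[i]
    if (st == "-") {
      # map to the reverse complement, scan as plus, map back
      ts <- L - end(trnas)[i] + 1L
      te <- L - start(trnas)[i] + 1L
      hits <- .scanPlus(seq_minus, ts, te, id, min_len, max_len,
                        max_mismatch, max_span, anchor_tail, anchor_ext)
      hits <- lapply(hits, function(h) {
        transform(h,
                  anchor_start = L - h$anchor_end + 1L,
                  anchor_end = L - h$anchor_start + 1L,
                  distal_start = L - h$distal_end + 1L,
                  distal_end = L - h$distal_start + 1L)
      })
    } else {
      hits <- .scanPlus(seq_plus, start(trnas)[i], end(trnas)[i], id,
                        min_len, max_len, max_mismatch, max_span,
                        anchor_tail, anchor_ext)
    }
    if (length(hits)) {
      df <- do.call(rbind, hits)
      df$strand <- st
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  df <- .collapseHits(df)
  rownames(df) <- NULL
  df[, names(empty)]
}

#' Call integrated elements from repeat hits
#'
#' One element per retained repeat hit: the element span lies strictly
#' between (excluding) the two repeat copies, in genome orientation; cargo
#' genes are the genes fully contained in the span. When several hits
#' share a tRNA, a non-overlapping subset is retained greedily, longest
#' span first.
#'
#' @param hits Repeat hits from [findTrnaAnchoredRepeats()].
#' @param genes `GRanges` of genes on the same replicon (as from
#'   [readAnnotations()]); used for cargo assignment.
#' @param replicon Replicon name for the output ranges (defaults to the
#'   genes' seqlevel, or "genome").
#' @return A `GRanges` of element calls with metadata columns
#'   `element_id`, `trna_id`, repeat coordinates and sequences,
#'   `mismatches`, `cargo` (a character `;`-joined gene-id list),
#'   `n_cargo` and `mobility` (initialized `"unclassified"`); strand is
#'   the anchoring tRNA's strand.
#' @export
callElements <- function(hits, genes, replicon = NULL) {
  if (is.null(replicon)) {
    replicon <- if (!is.null(genes) && length(seqlevels(genes)))
      seqlevels(genes)[1] else "genome"
  }
  mk <- function(df) {
    if (!nrow(df)) {
      return(GRanges(element_id = character(0), trna_id = character(0),
                     mismatches = integer(0)))
    }
    span_start <- pmin(df$anchor_end, df$distal_end) + 1L
    span_end <- pmax(df$anchor_start, df$distal_start) - 1L
    gr <- GRanges(replicon, IRanges(span_start, span_end),
                  strand = df$strand)
    cargo <- character(nrow(df)); n_cargo <- integer(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (!is.null(genes) && length(genes)) {
        inside <- start(genes) >= span_start[i] & end(genes) <= span_end[i]
        ids <- mcols(genes)$gene_id[inside]
        ids <- ids[order(start(genes)[inside])]
        cargo[i] <- paste(ids, collapse = ";")
        n_cargo[i] <- length(ids)
      } else {
        cargo[i] <- ""; n_cargo[i] <- 0L
      }
    }
    mcols(gr) <- DataFrame(
      element_id = sprintf("%s_elem%02d", df$trna_id,
                           stats::ave(seq_len(nrow(df)), df$trna_id,
                                      FUN = seq_along)),
      trna_id = df$trna_id,
      anchor_start = df$anchor_start, anchor_end = df$anchor_end,
      distal_start = df$distal_start, distal_end = df$distal_end,
      repeat_length = df$length, mismatches = df$mismatches,
      anchor_seq = df$anchor_seq, distal_seq = df$distal_seq,
      cargo = cargo, n_cargo = n_cargo,
      mobility = rep("unclassified", nrow(df)))
    gr
  }
  if (!nrow(hits)) return(mk(hits))
  # greedy non-overlapping subset per tRNA, longest element span first
  hits$._span <- pmax(hits$anchor_start, hits$distal_start) -
    pmin(hits$anchor_end, hits$distal_end) - 1L
  keep <- logical(nrow(hits))
  for (id in unique(hits$trna_id)) {
    idx <- which(hits$trna_id == id)
    idx <- idx[order(-hits$._span[idx])]
    taken <- list()
    for (i in idx) {
      s <- pmin(hits$anchor_end[i], hits$distal_end[i]) + 1L
      e <- pmax(hits$anchor_start[i], hits$distal_start[i]) - 1L
      clash <- any(vapply(taken, function(t) s <= t[2] && e >= t[1],
                          logical(1)))
      if (!clash) { keep[i] <- TRUE; taken[[length(taken) + 1L]] <- c(s, e) }
    }
  }
  df <- hits[keep, , drop = FALSE]
  df <- df[order(df$trna_id, df$distal_start), , drop = FALSE]
  df$._span <- NULL
  mk(df)
}

#' Default keyword vocabulary for mobility classification
#'
#' Case-insensitive regular expressions matched against cargo gene product
#' annotations. The `rep` patterns are word-bounded so that "Rep"
#' does not match "repressor" or "repair".
#'
#' @return Named list of regex vectors: `integrase`, `excisionase`, `rep`.
#' @export
defaultMarkerVocab <- function() {
  list(integrase = c("integrase", "recombinase",
                     "tyrosine recombinase", "serine recombinase"),
       excisionase = c("excisionase", "alpa"),
       rep = c("\\brep\\b", "rolling circle", "rolling-circle",
               "replication initiator"))
}

#' Classify element mobility from cargo annotations
#'
#' An element is `predicted_active` when its cargo encodes an intact
#' (non-pseudo) integrase/recombinase **and** either an excisionase or a
#' rolling-circle replication initiator — the machinery of an element
#' that can still excise and replicate. It is `immobilized` when its only
#' integrase matches are pseudogenes/fragments, or when it has no
#' integrase at all (the vestige pattern of a stranded element). An intact
#' integrase without excisionase/Rep support stays `unclassified`.
#' Matching is case-insensitive keyword search over product strings, not a
#' profile/HMM search; the vocabulary is user-extensible.
#'
#' @param calls Element calls from [callElements()].
#' @param genes `GRanges` of genes with `gene_id`, `product`, `is_pseudo`.
#' @param marker_vocab Vocabulary as from [defaultMarkerVocab()].
#' @return `calls` with the `mobility` column set and an added `evidence`
#'   column (`;`-joined `gene_id:category` matches).
#' @export
classifyMobility <- function(calls, genes,
                             marker_vocab = defaultMarkerVocab()) {
  if (!length(calls)) return(calls)
  prod <- tolower(mcols(genes)$product)
  pseudo <- mcols(genes)$is_pseudo
  gid <- mcols(genes)$gene_id
  match_cat <- function(category) {
    pat <- paste(marker_vocab[[category]], collapse = "|")
    grepl(pat, prod, ignore.case = TRUE)
  }
  m_int <- match_cat("integrase")
  m_exc <- match_cat("excisionase")
  m_rep <- match_cat("rep")
  mobility <- character(length(calls))
  evidence <- character(length(calls))
  for (i in seq_along(calls)) {
    ids <- strsplit(mcols(calls)$cargo[i], ";", fixed = TRUE)[[1]]
    j <- match(ids[nzchar(ids)], gid)
    j <- j[!is.na(j)]
    intact_int <- any(m_int[j] & !pseudo[j])
    pseudo_int <- any(m_int[j] & pseudo[j])
    helper <- any(m_exc[j]) || any(m_rep[j])
    mobility[i] <- if (intact_int && helper) "predicted_active"
      else if (!intact_int) "immobilized"
      else "unclassified"
    ev <- c(if (any(m_int[j])) paste0(gid[j][m_int[j]], ":integrase",
                                      ifelse(pseudo[j][m_int[j]],
                                             "(pseudo)", "")),
            if (any(m_exc[j])) paste0(gid[j][m_exc[j]], ":excisionase"),
            if (any(m_rep[j])) paste0(gid[j][m_rep[j]], ":rep"))
    evidence[i] <- paste(ev, collapse = ";")
  }
  mcols(calls)$mobility <- mobility
  mcols(calls)$evidence <- evidence
  calls
}
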
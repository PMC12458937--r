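# Readers and writers for annotated genomes (GenBank flat files, GFF3 +
# FASTA). Features are returned as GRanges (1-based closed coordinates, the
# Bioconductor convention); BED export and coords0() expose 0-based
# half-open spans.

.GENE_FEATURE_TYPES <- c("CDS", "tRNA", "tmRNA", "rRNA", "ncRNA")

#' Read gene annotations from GenBank or GFF3(+FASTA)
#'
#' Parses gene-level features into a `GRanges` with metadata columns
#' `gene_id`, `type`, `product` and `is_pseudo`, sorted by start position.
#' Compound (join/order) locations are collapsed to their min-start /
#' max-end envelope with a warning: only gene order and span matter
#' downstream. When sequence is available (GenBank ORIGIN block, or the
#' `fasta` companion file for GFF3) it is attached as
#' `metadata(x)$sequence` (a `DNAStringSet`) and used to set `seqlengths`.
#'
#' @param path GenBank flat file (`.gb`/`.gbk`/`.gbff`) or GFF3 file.
#' @param fasta Optional FASTA path with the replicon sequence(s)
#'   (GFF3 input only).
#' @param format `"auto"` (by extension/content), `"genbank"` or `"gff3"`.
#' @param feature_types Feature keys retained as genes.
#' @param require_sequence Error if no sequence can be attached.
#' @return A `GRanges`; one range per gene, metadata columns as above.
#' @examples
#' gb <- system.file("extdata", "mini.gbk", package = "DefenseKit")
#' genes <- readAnnotations(gb)
#' coords0(genes)
#' @export
readAnnotations <- function(path, fasta = NULL,
                            format = c("auto", "genbank", "gff3"),
                            feature_types = .GENE_FEATURE_TYPES,
                            require_sequence = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3"
    else if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank"
    else if (startsWith(readLines(path, n = 1), "##gff")) "gff3"
    else "genbank"
  }
  res <- switch(format,
                genbank = .readGenBank(path, feature_types),
                gff3 = .readGFF3(path, fasta, feature_types))
  gr <- res$genes
  seqs <- res$sequence
  if (require_sequence && is.null(seqs))
    .stopf("sequence required but none found for '%s' (no ORIGIN block / no FASTA)",
           path)
  if (!is.null(seqs)) {
    sl <- setNames(width(seqs), names(seqs))
    common <- intersect(seqlevels(gr), names(sl))
    seqlengths(gr)[common] <- sl[common]
    bad <- end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
    if (any(bad, na.rm = TRUE))
      .stopf("feature(s) extend past replicon end: %s",
             paste(mcols(gr)$gene_id[which(bad)], collapse = ", "))
    metadata(gr)$sequence <- seqs
  }
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  dup <- duplicated(paste(seqnames(gr), mcols(gr)$gene_id))
  if (any(dup))
    .stopf("duplicate gene_id within replicon: %s",
           paste(unique(mcols(gr)$gene_id[dup]), collapse = ", "))
  gr
}

# ---- GenBank flat file ------------------------------------------------------

.readGenBank <- function(path, feature_types) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i))
    .stopf("malformed GenBank file '%s': no LOCUS line", path)
  toks <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]]
  replicon <- toks[1]
  rep_len <- suppressWarnings(as.integer(toks[2]))

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_i <- if (length(origin_i)) origin_i[1] - 1L else length(lines)
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):end_i]
    # a feature starts at indent 5 with a key; qualifiers are deeper
    starts <- grep("^ {5}\\S", block)
    for (ii in seq_along(starts)) {
      from <- starts[ii]
      to <- if (ii < length(starts)) starts[ii + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1])
      loc <- sub("^ {5}\\S+\\s*", "", chunk[1])
      qi <- grep("^\\s+/", chunk)
      # location may continue over lines before the first qualifier
      if (length(chunk) > 1) {
        loc_end <- if (length(qi)) qi[1] - 1L else length(chunk)
        if (loc_end > 1)
          loc <- paste0(loc, paste(trimws(chunk[2:loc_end]), collapse = ""))
      }
      quals <- .parseQualifiers(chunk[if (length(qi)) qi[1]:length(chunk) else 0])
      feats[[length(feats) + 1L]] <-
        list(key = key, location = loc, qualifiers = quals,
             line = feat_i[1] + from)
    }
  }
  feats <- Filter(function(f) f$key %in% feature_types, feats)
  gr <- .featuresToGRanges(feats, replicon, path)

  seqs <- NULL
  if (length(origin_i)) {
    seq_lines <- lines[(origin_i[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nzchar(seq)) {
      if (!is.na(rep_len) && nchar(seq) != rep_len)
        .warnf("ORIGIN length %d differs from LOCUS length %d",
               nchar(seq), rep_len)
      seqs <- DNAStringSet(setNames(seq, replicon))
    }
  }
  list(genes = gr, sequence = seqs)
}

.parseQualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  # rejoin continued values (lines not starting a new qualifier)
  out <- character(0)
  for (ln in txt) {
    if (startsWith(ln, "/")) out <- c(out, ln)
    else if (length(out)) out[length(out)] <- paste(out[length(out)], ln)
  }
  quals <- list()
  for (q in out) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)(?:="?([^"]*)"?)?$', q))[[1]]
    if (length(m) >= 2)
      quals[[m[2]]] <- if (length(m) >= 3 && nzchar(m[3])) m[3] else TRUE
  }
  quals
}

.featuresToGRanges <- function(feats, replicon, path) {
  n <- length(feats)
  start <- end <- integer(n); strand <- character(n)
  gene_id <- product <- type <- character(n); pseudo <- logical(n)
  auto <- 0L
  for (i in seq_len(n)) {
    f <- feats[[i]]
    loc <- f$location
    minus <- grepl("complement", loc, fixed = TRUE)
    compound <- grepl("join|order", loc)
    nums <- suppressWarnings(
      as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
    if (!length(nums) || anyNA(nums))
      .stopf("malformed location '%s' for %s feature near line %d of '%s'",
             loc, f$key, f$line, path)
    if (compound)
      .warnf("compound location '%s' (%s) collapsed to its envelope",
             loc, f$key)
    start[i] <- min(nums); end[i] <- max(nums)
    strand[i] <- if (minus) "-" else "+"
    q <- f$qualifiers
    id <- q$locus_tag
    if (is.null(id)) id <- q$gene
    if (is.null(id)) { auto <- auto + 1L; id <- sprintf("feature_%04d", auto) }
    gene_id[i] <- id
    product[i] <- if (!is.null(q$product)) q$product else ""
    pseudo[i] <- isTRUE(q$pseudo) || !is.null(q$pseudogene)
    type[i] <- f$key
  }
  # identical locus_tag on gene + CDS pairs etc. would duplicate ids; the
  # retained feature_types rarely collide, but guard by keeping first
  gr <- GRanges(replicon, IRanges(start, end), strand = strand,
                gene_id = gene_id, type = type, product = product,
                is_pseudo = pseudo)
  gr[!duplicated(gene_id)]
}

# ---- GFF3 -------------------------------------------------------------------

.readGFF3 <- function(path, fasta, feature_types) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    .stopf("GFF3 input requires the rtracklayer package")
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   .stopf("malformed GFF3 file '%s': %s", path,
                          conditionMessage(e)))
  keep <- as.character(gr$type) %in% c(feature_types, "pseudogene")
  gr <- gr[keep]
  mc <- mcols(gr)
  id <- if (!is.null(mc$locus_tag)) as.character(mc$locus_tag)
        else rep(NA_character_, length(gr))
  if (!is.null(mc$ID)) id[is.na(id)] <- as.character(mc$ID)[is.na(id)]
  miss <- is.na(id)
  id[miss] <- sprintf("feature_%04d", seq_len(sum(miss)))
  product <- if (!is.null(mc$product)) as.character(mc$product)
             else rep("", length(gr))
  product[is.na(product)] <- ""
  pseudo <- as.character(mc$type) == "pseudogene"
  if (!is.null(mc$pseudo))
    pseudo <- pseudo | (!is.na(mc$pseudo) & tolower(as.character(mc$pseudo)) %in%
                          c("true", "1", "yes"))
  type <- as.character(mc$type)
  out <- granges(gr)
  mcols(out) <- DataFrame(gene_id = id, type = type, product = product,
                          is_pseudo = pseudo)
  # multi-row features (multi-exon CDS sharing an ID) -> envelope
  key <- paste(seqnames(out), out$gene_id)
  if (anyDuplicated(key)) {
    .warnf("multi-row feature(s) collapsed to their envelope: %s",
           paste(unique(out$gene_id[duplicated(key)]), collapse = ", "))
    sp <- split(seq_along(out), key)
    idx <- vapply(sp, `[`, integer(1), 1L)
    env_start <- vapply(sp, function(j) min(start(out)[j]), integer(1))
    env_end <- vapply(sp, function(j) max(end(out)[j]), integer(1))
    out2 <- GRanges(seqnames(out)[idx], IRanges(env_start, env_end),
                    strand = strand(out)[idx])
    mcols(out2) <- mcols(out)[idx, , drop = FALSE]
    out <- out2
  }
  seqs <- NULL
  if (!is.null(fasta)) seqs <- readDNAStringSet(fasta)
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  list(genes = out, sequence = seqs)
}

#' Write gene annotations as GFF3
#'
#' Writes the `GRanges` produced by [readAnnotations()] (or the simulators)
#' back to GFF3; with `sequence` also writes a companion FASTA. Reading the
#' pair back reproduces the table (round trip).
#'
#' @param genes `GRanges` with `gene_id`, `type`, `product`, `is_pseudo`.
#' @param path Output GFF3 path.
#' @param sequence Optional `DNAStringSet`; written to `fasta_path`.
#' @param fasta_path Companion FASTA path (default: `path` with `.fna`).
#' @return Invisibly, `path`.
#' @export
writeAnnotationsGFF3 <- function(genes, path, sequence = NULL,
                                 fasta_path = sub("\\.gff3?$", ".fna", path)) {
  esc <- function(x) gsub(";", "%3B", gsub("=", "%3D", gsub("%", "%25", x)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  sl <- seqlengths(genes)
  for (sn in seqlevels(genes)) {
    if (!is.na(sl[sn]))
      writeLines(sprintf("##sequence-region %s 1 %d", sn, sl[sn]), con)
  }
  if (length(genes)) {
    mc <- mcols(genes)
    attrs <- sprintf("ID=%s;locus_tag=%s;product=%s%s",
                     esc(mc$gene_id), esc(mc$gene_id), esc(mc$product),
                     ifelse(mc$is_pseudo, ";pseudo=true", ""))
    writeLines(sprintf("%s\tDefenseKit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(seqnames(genes)), mc$type,
                       start(genes), end(genes),
                       as.character(strand(genes)), attrs), con)
  }
  if (!is.null(sequence)) writeXStringSet(sequence, fasta_path)
  invisible(path)
}
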
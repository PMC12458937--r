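# Direct-repeat scanner, element calling and mobility classification.

test_that("a planted repeat is recovered at its exact coordinates", {
  for (mm in 0:1) {
    sim <- simulateGenomeWithElements(simConfig(
      seed = 50 + mm,
      genome = list(length = 40000L, elements = list(
        list(dr_length = 18L, dr_mismatches = mm, span = 9000L,
             n_cargo = 5L, markers = c("integrase", "rep"))))))
    tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
    hits <- findTrnaAnchoredRepeats(sim$sequence, tr)
    truth <- sim$truth$elements
    expect_equal(nrow(hits), 1)
    expect_equal(hits$anchor_start, truth$anchor_start)
    expect_equal(hits$distal_start, truth$distal_start)
    expect_equal(hits$length, truth$dr_length)
    expect_equal(hits$mismatches, truth$mismatches)
  }
})

test_that("repeats beyond the mismatch budget or length range are not called", {
  sim <- simulateGenomeWithElements(simConfig(
    seed = 60,
    genome = list(length = 120000L, scan_max_span = 20000L,
                  elements = list(), n_decoys = 4L)))
  tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
  hits <- findTrnaAnchoredRepeats(sim$sequence, tr, max_span = 20000)
  expect_equal(nrow(hits), 0)  # short, far, 2-mismatch, non-anchored
  expect_setequal(sim$truth$decoys$type,
                  c("short", "far", "mm2", "no_trna"))
})

test_that("a repeat-free random genome yields no hits (oracle-confirmed)", {
  set.seed(71)
  g <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  tr <- GenomicRanges::GRanges("chr", IRanges::IRanges(3000, 3075),
                               strand = "+", gene_id = "t1",
                               type = "tRNA", product = "tRNA",
                               is_pseudo = FALSE)
  hits <- findTrnaAnchoredRepeats(g, tr)
  ora <- oracle_scan(g, data.frame(trna_id = "t1", start = 3000,
                                   end = 3075))
  expect_equal(nrow(ora), 0)
  expect_equal(nrow(hits), 0)
})

test_that("scanner equals the brute-force substring-pair oracle", {
  for (s in 1:6) {
    sim <- simulateGenomeWithElements(simConfig(
      seed = 400 + s,
      genome = list(length = 45000L, scan_max_span = 10000L,
                    elements = list(
                      list(dr_length = 16L + (s %% 5), dr_mismatches = s %% 2,
                           span = 6000L, n_cargo = 2L,
                           markers = "integrase")),
                    n_decoys = s %% 3)))
    seq_string <- as.character(sim$sequence[[1]])
    tdf <- trna_df(sim$genes)
    tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
    hits <- findTrnaAnchoredRepeats(sim$sequence, tr, max_span = 10000)
    ora <- oracle_scan(seq_string, tdf, max_span = 10000)
    cols <- c("trna_id", "anchor_start", "anchor_end", "distal_start",
              "distal_end", "length", "mismatches")
    expect_equal(hits[, cols], ora[, cols], ignore_attr = TRUE)
  }
})

test_that("reported mismatches equal the recomputed Hamming distance", {
  sim <- simulateGenomeWithElements(simConfig(
    seed = 80, genome = list(length = 40000L, elements = list(
      list(dr_length = 20L, dr_mismatches = 1L, span = 8000L,
           n_cargo = 3L, markers = "integrase")))))
  tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
  hits <- findTrnaAnchoredRepeats(sim$sequence, tr)
  for (i in seq_len(nrow(hits))) {
    a <- strsplit(hits$anchor_seq[i], "")[[1]]
    b <- strsplit(hits$distal_seq[i], "")[[1]]
    expect_equal(sum(a != b), hits$mismatches[i])
  }
})

test_that("the scan is strand symmetric under reverse complement", {
  sim <- simulateGenomeWithElements(simConfig(
    seed = 90, genome = list(length = 35000L, elements = list(
      list(dr_length = 18L, dr_mismatches = 0L, span = 7000L,
           n_cargo = 2L, markers = "integrase")))))
  L <- Biostrings::width(sim$sequence)[1]
  tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
  fwd <- findTrnaAnchoredRepeats(sim$sequence, tr)

  rc <- Biostrings::reverseComplement(sim$sequence[[1]])
  tr_rc <- GenomicRanges::GRanges(
    "sim_replicon",
    IRanges::IRanges(L - GenomicRanges::end(tr) + 1,
                     L - GenomicRanges::start(tr) + 1),
    strand = "-", gene_id = tr$gene_id, type = "tRNA",
    product = "tRNA", is_pseudo = FALSE)
  rev <- findTrnaAnchoredRepeats(rc, tr_rc)
  # mapping back: position p on the rc genome is L - p + 1 on the original
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(L - rev$anchor_end + 1, fwd$anchor_start)
  expect_equal(L - rev$distal_end + 1, fwd$distal_start)
  expect_equal(rev$mismatches, fwd$mismatches)
})

test_that("element calls exclude the repeats and collect cargo", {
  sim <- simulateGenomeWithElements(simConfig(
    seed = 100, genome = list(length = 60000L, elements = list(
      list(dr_length = 18L, dr_mismatches = 0L, span = 12000L,
           n_cargo = 12L, markers = c("integrase", "excisionase"))))))
  tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
  hits <- findTrnaAnchoredRepeats(sim$sequence, tr)
  calls <- callElements(hits, sim$genes)
  truth <- sim$truth$elements
  expect_equal(length(calls), 1)
  expect_equal(GenomicRanges::start(calls), truth$span_start)
  expect_equal(GenomicRanges::end(calls), truth$span_end)
  expect_equal(calls$n_cargo, 12L)
  # the repeats themselves lie outside the span
  expect_gt(GenomicRanges::start(calls), calls$anchor_end)
  expect_lt(GenomicRanges::end(calls), calls$distal_start)
})

test_that("cargo-free hits are kept; overlapping spans resolve to longest", {
  hits <- data.frame(
    trna_id = c("t1", "t1"), strand = "+",
    anchor_start = c(100, 100), anchor_end = c(117, 117),
    distal_start = c(5000, 9000), distal_end = c(5017, 9017),
    length = 18L, mismatches = 0L,
    anchor_seq = "ACGTACGTACGTACGTAC", distal_seq = "ACGTACGTACGTACGTAC",
    stringsAsFactors = FALSE)
  calls <- callElements(hits, NULL, replicon = "chr")
  expect_equal(length(calls), 1)          # overlapping spans: longer kept
  expect_equal(GenomicRanges::end(calls), 8999)
  expect_equal(calls$n_cargo, 0L)         # empty cargo is not dropped
  expect_equal(calls$cargo, "")
})

test_that("mobility classification follows the marker rule table", {
  mkgenes <- function(products, pseudo) {
    GenomicRanges::GRanges(
      "chr", IRanges::IRanges(seq(1000, by = 1000,
                                  length.out = length(products)),
                              width = 600),
      strand = "+", gene_id = sprintf("g%d", seq_along(products)),
      type = "CDS", product = products, is_pseudo = pseudo)
  }
  call1 <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(500, 5000), strand = "+",
    element_id = "e1", trna_id = "t1", anchor_start = 1L, anchor_end = 18L,
    distal_start = 5001L, distal_end = 5018L, repeat_length = 18L,
    mismatches = 0L, anchor_seq = "x", distal_seq = "x",
    cargo = "g1;g2", n_cargo = 2L, mobility = "unclassified")

  g_active <- mkgenes(c("site-specific integrase",
                        "AlpA family excisionase"), c(FALSE, FALSE))
  expect_equal(classifyMobility(call1, g_active)$mobility,
               "predicted_active")

  g_pseudo <- mkgenes(c("integrase", "AlpA family excisionase"),
                      c(TRUE, FALSE))
  expect_equal(classifyMobility(call1, g_pseudo)$mobility, "immobilized")

  g_lone <- mkgenes(c("tyrosine recombinase", "hypothetical protein"),
                    c(FALSE, FALSE))
  expect_equal(classifyMobility(call1, g_lone)$mobility, "unclassified")

  # "Rep" is word-bounded: a repressor is not replication machinery
  g_repr <- mkgenes(c("site-specific integrase",
                      "transcriptional repressor"), c(FALSE, FALSE))
  expect_equal(classifyMobility(call1, g_repr)$mobility, "unclassified")
  g_rep <- mkgenes(c("site-specific integrase",
                     "rolling circle replication initiator Rep"),
                   c(FALSE, FALSE))
  expect_equal(classifyMobility(call1, g_rep)$mobility,
               "predicted_active")
})

test_that("element calls survive a BED round trip with 0-based spans", {
  sim <- simulateGenomeWithElements(simConfig(seed = 110))
  tr <- sim$genes[S4Vectors::mcols(sim$genes)$type == "tRNA"]
  calls <- callElements(findTrnaAnchoredRepeats(sim$sequence, tr),
                        sim$genes)
  bed <- tempfile(fileext = ".bed")
  writeElementsBed(calls, bed)
  back <- readElementsBed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(calls))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(calls))
  expect_equal(back$element_id, calls$element_id)
})

test_that("tRNAs outside the genome are rejected", {
  tr <- GenomicRanges::GRanges("chr", IRanges::IRanges(500, 600),
                               strand = "+", gene_id = "t", type = "tRNA",
                               product = "", is_pseudo = FALSE)
  expect_error(findTrnaAnchoredRepeats("ACGT", tr), "outside genome")
})
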
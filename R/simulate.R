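# Seeded synthetic-data generators with machine-readable ground truth.
# Every generator is a pure function of its configuration (seed included):
# one pseudorandom sub-stream per generator, derived from the master seed
# by a fixed label, so adding a generator never perturbs the others.

#' Simulation configuration
#'
#' Builds the configuration consumed by the four generators, merging
#' overrides into defaults that mirror the assay designs the package
#' analyzes: ten-fold dilution series spotted at 3 ul, triplicate growth
#' curves sampled every 10 min for 540 min at MOIs 0.1/1/10, genomes
#' carrying tRNA-integrated elements flanked by 16-20 nt direct repeats,
#' and island tables with planted content families.
#'
#' @param seed Master seed (integer).
#' @param plaque,growth,genome,islands Named lists of overrides for the
#'   respective generator; see Details.
#'
#' @details Generator parameters and defaults:
#' \describe{
#'   \item{plaque}{`true_titers` (named, PFU/ml; default two phages at
#'     1e9 and 2e8), `true_eops` (matrix phage x strain; default a
#'     reference strain at 1 and a defended strain at 1e-4 / 5e-2),
#'     `dilutions` (default `10^-(0:7)`), `spot_volume_ml` (0.003),
#'     `replicates` (3).}
#'   \item{growth}{logistic growth rate `r` (1.5 /h), carrying capacity
#'     `K` (1.0 OD600), adsorption rate `a` (8e-9 ml/(PFU·h)), burst size
#'     `burst` (5, an effective per-lysis yield), lysis rate `delta`
#'     (0.7 /h), defense efficacies `e_A` (0.75) and `e_B` (0.35),
#'     interaction `gamma` (1 = multiplicative/additive; >1 =
#'     synergistic), `mois` (0.1, 1, 10), `sample_every_min` (10),
#'     `duration_min` (540), `noise_sd` (0.02 OD), `replicates` (3),
#'     `od0` (0.05), `cells_per_od` (8e8), `step_min` (0.5; fixed-step
#'     4th-order integration), `strains` (control, sysA, sysB, both).}
#'   \item{genome}{`length` (60000 nt), `replicon_id`, `elements` (list;
#'     each with `dr_length` 18, `dr_mismatches` 0, `span` 12000 nt,
#'     `n_cargo` 6, `markers`, `strand`), `n_decoys` (0; decoys cycle
#'     through short / far / two-mismatch / non-tRNA violations),
#'     `scan_max_span` (200000; the far decoy is planted just beyond it),
#'     `trna_length` (76), `margin` (1500 nt between planted features).}
#'   \item{islands}{`n_families` (5), `islands_per_family` (4),
#'     `content_size` (10), `perturbations_per_island` (1; each
#'     perturbation adds or removes one content element),
#'     `protein_length` (120 aa), `mutation_rate` (0.01, capped at 2% so
#'     same-family ORFs stay >= 95% identical pairwise), `pool_extra` (20 spare
#'     families for additions).}
#' }
#' @return A list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, growth = list(gamma = 2))
#' cfg$growth$gamma
#' @export
simConfig <- function(seed = 1L, plaque = list(), growth = list(),
                      genome = list(), islands = list()) {
  def_plaque <- list(
    true_titers = c(phage_1 = 1e9, phage_2 = 2e8),
    true_eops = matrix(c(1, 1e-4, 1, 5e-2), nrow = 2, byrow = TRUE,
                       dimnames = list(c("phage_1", "phage_2"),
                                       c("reference", "defended"))),
    dilutions = 10^-(0:7),
    spot_volume_ml = 0.003,
    replicates = 3L)
  def_growth <- list(
    r = 1.5, K = 1.0, a = 8e-9, burst = 5, delta = 0.7,
    e_A = 0.75, e_B = 0.35, gamma = 1,
    mois = c(0.1, 1, 10), sample_every_min = 10, duration_min = 540,
    noise_sd = 0.02, replicates = 3L, od0 = 0.05, cells_per_od = 8e8,
    step_min = 0.5, strains = c("control", "sysA", "sysB", "both"))
  def_genome <- list(
    length = 60000L, replicon_id = "sim_replicon",
    elements = list(list(dr_length = 18L, dr_mismatches = 0L,
                         span = 12000L, n_cargo = 6L,
                         markers = c("integrase", "excisionase"))),
    n_decoys = 0L, scan_max_span = 200000L, trna_length = 76L,
    margin = 1500L)
  def_islands <- list(
    n_families = 5L, islands_per_family = 4L, content_size = 10L,
    perturbations_per_island = 1L, protein_length = 120L,
    mutation_rate = 0.01, pool_extra = 20L)
  cfg <- list(seed = as.integer(seed),
              plaque = modifyList(def_plaque, plaque),
              growth = modifyList(def_growth, growth),
              genome = modifyList(def_genome, genome),
              islands = modifyList(def_islands, islands))
  # 'elements' is an unnamed list of element descriptions: replace it
  # wholesale (modifyList cannot merge unnamed lists), filling each
  # element's missing fields from the default element
  if (!is.null(genome$elements)) {
    def_el <- def_genome$elements[[1]]
    cfg$genome$elements <- lapply(genome$elements, function(el)
      modifyList(def_el, el))
  }
  .validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

.validateSimConfig <- function(cfg) {
  p <- cfg$plaque; g <- cfg$growth; gn <- cfg$genome; isl <- cfg$islands
  if (any(p$true_titers <= 0)) .stopf("true_titers must be positive")
  if (any(p$true_eops <= 0)) .stopf("true_eops must be positive")
  if (any(p$dilutions <= 0 | p$dilutions > 1))
    .stopf("dilutions must lie in (0, 1]")
  if (p$spot_volume_ml <= 0) .stopf("spot_volume_ml must be positive")
  if (any(c(g$r, g$K, g$a, g$burst, g$delta, g$step_min) <= 0))
    .stopf("growth rates and sizes must be positive")
  if (g$e_A < 0 || g$e_A > 1 || g$e_B < 0 || g$e_B > 1)
    .stopf("defense efficacies must lie in [0, 1]")
  if (g$gamma < 0) .stopf("gamma must be non-negative")
  for (el in gn$elements) {
    if (el$dr_length < 10 || el$dr_length > 30)
      .stopf("dr_length %d outside the supported range [10, 30]",
             el$dr_length)
    if (el$span <= 0 || el$n_cargo < 0)
      .stopf("element span must be positive and n_cargo non-negative")
  }
  if (isl$perturbations_per_island >= isl$content_size)
    .stopf("perturbations_per_island must be < content_size")
  invisible(TRUE)
}

#' Simulate a plaque-assay dilution series
#'
#' Spot counts are Poisson with mean
#' `true_titer x true_eop x dilution x spot_volume`, the sampling model of
#' plating a well-mixed lysate. The truth record retains the exact titers
#' and EOPs for recovery scoring.
#'
#' @param config A [simConfig()] object.
#' @return A list: `assay` (a [readAssayTable()]-layout `data.frame`) and
#'   `truth` (`true_titers`, `true_eops`).
#' @examples
#' sim <- simulatePlaqueAssay(simConfig(seed = 7))
#' head(sim$assay)
#' @export
simulatePlaqueAssay <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  p <- config$plaque
  set.seed(.substreamSeed(config$seed, "plaque"))
  phages <- names(p$true_titers)
  strains <- colnames(p$true_eops)
  rows <- expand.grid(dilution_factor = p$dilutions,
                      replicate = seq_len(p$replicates),
                      strain = strains, phage = phages,
                      stringsAsFactors = FALSE)
  lambda <- p$true_titers[rows$phage] *
    p$true_eops[cbind(rows$phage, rows$strain)] *
    rows$dilution_factor * p$spot_volume_ml
  rows$spot_volume_ml <- p$spot_volume_ml
  rows$plaque_count <- rpois(nrow(rows), lambda)
  rows$lysis_halo <- FALSE
  rows <- rows[, c("phage", "strain", "replicate", "dilution_factor",
                   "spot_volume_ml", "plaque_count", "lysis_halo")]
  # most concentrated spot first within each series, as plated
  rows <- rows[order(rows$phage, rows$strain, rows$replicate,
                     -rows$dilution_factor), ]
  rownames(rows) <- NULL
  list(assay = rows,
       truth = list(true_titers = p$true_titers,
                    true_eops = p$true_eops))
}

# susceptible-infected-phage ODE right-hand side; state in cells/ml and
# PFU/ml, time in hours
.sipDeriv <- function(t, y, parms) {
  S <- max(y[1], 0); I <- max(y[2], 0); P <- max(y[3], 0)
  with(parms, {
    inf <- a_eff * P * S
    list(c(r * S * (1 - (S + I) / Kc) - inf,
           inf - delta * I,
           burst * delta * I - inf))
  })
}

.strainAeff <- function(g, strain) {
  switch(strain,
         control = g$a,
         sysA = g$a * (1 - g$e_A),
         sysB = g$a * (1 - g$e_B),
         both = g$a * (1 - g$e_A) * (1 - g$e_B) / g$gamma,
         .stopf("unknown strain '%s'", strain))
}

#' Simulate phage-infection growth curves
#'
#' Deterministic susceptible-infected-phage (SIP) dynamics per condition
#' — logistic host growth, mass-action adsorption, delayed lysis with
#' burst — integrated with a fixed-step 4th-order scheme at
#' `step_min`-minute steps, plus i.i.d. Gaussian measurement noise per
#' sample; replicates differ only in their noise draw. Defense systems
#' scale the adsorption rate: `a(1-e_A)` and `a(1-e_B)` for the
#' single-system strains and `a(1-e_A)(1-e_B)/gamma` for the strain
#' carrying both, so `gamma = 1` encodes exactly multiplicative
#' (additive-expectation) protection and `gamma > 1` super-multiplicative
#' (synergistic) protection — the generator's ground truth for the AUC
#' synergy caller.
#'
#' @param config A [simConfig()] object.
#' @return A list: `curves` (a [GrowthCurveSet-class]) and `truth`
#'   (`gamma`, per-strain effective adsorption rates, and the noiseless
#'   OD matrix `od_clean` with columns matching `curves`).
#' @examples
#' sim <- simulateGrowth(simConfig(seed = 3, growth = list(
#'   mois = 1, strains = c("control", "both"), duration_min = 120)))
#' dim(od600(sim$curves))
#' @export
simulateGrowth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  g <- config$growth
  set.seed(.substreamSeed(config$seed, "growth"))
  t_ode <- seq(0, g$duration_min / 60, by = g$step_min / 60)
  keep <- seq(1, length(t_ode), by = round(g$sample_every_min / g$step_min))
  time_min <- t_ode[keep] * 60
  Kc <- g$K * g$cells_per_od
  S0 <- g$od0 * g$cells_per_od
  conds <- expand.grid(strain = g$strains, moi = g$mois,
                       stringsAsFactors = FALSE)
  clean <- matrix(NA_real_, nrow = length(keep),
                  ncol = nrow(conds))
  a_eff <- setNames(vapply(g$strains, function(s) .strainAeff(g, s),
                           numeric(1)), g$strains)
  for (ci in seq_len(nrow(conds))) {
    parms <- list(r = g$r, Kc = Kc, a_eff = a_eff[[conds$strain[ci]]],
                  delta = g$delta, burst = g$burst)
    y0 <- c(S = S0, I = 0, P = conds$moi[ci] * S0)
    sol <- deSolve::ode(y0, t_ode, .sipDeriv, parms, method = "rk4")
    if (min(sol[, -1]) < -1e-6 * Kc)
      .warnf("negative population clipped at 0 (strain %s, MOI %g)",
             conds$strain[ci], conds$moi[ci])
    sol[, -1][sol[, -1] < 0] <- 0
    clean[, ci] <- (sol[keep, "S"] + sol[keep, "I"]) / g$cells_per_od
  }
  # replicates: same deterministic curve, independent noise
  nrep <- g$replicates
  od <- matrix(NA_real_, nrow = length(keep), ncol = nrow(conds) * nrep)
  cd <- data.frame(strain = rep(conds$strain, each = nrep),
                   phage = "sim_phage",
                   moi = rep(conds$moi, each = nrep),
                   dye = "none",
                   replicate = rep(seq_len(nrep), times = nrow(conds)),
                   stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(conds))) {
    for (r in seq_len(nrep)) {
      col <- (ci - 1L) * nrep + r
      od[, col] <- clean[, ci] +
        rnorm(length(keep), sd = g$noise_sd)
    }
  }
  colnames(od) <- sprintf("%s_moi%g_rep%d", cd$strain, cd$moi,
                          cd$replicate)
  clean_rep <- clean[, rep(seq_len(nrow(conds)), each = nrep),
                     drop = FALSE]
  colnames(clean_rep) <- colnames(od)
  gcs <- GrowthCurveSet(od, time_min, cd)
  list(curves = gcs,
       truth = list(gamma = g$gamma, a_eff = a_eff,
                    od_clean = clean_rep))
}

# ---- genomes with planted elements -----------------------------------------

.MARKER_PRODUCTS <- c(
  integrase = "site-specific integrase",
  pseudo_integrase = "integrase",
  excisionase = "AlpA family excisionase",
  rep = "rolling circle replication initiator Rep",
  none = "hypothetical protein")

.randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plant `mm` substitutions into a copy of the repeat sequence `s`.
# Substitutions go into the repeat interior — inside every 16-nt
# sub-window and at least 3 nt from either end — so the planted repeat
# length stays well-defined: no exact sub-repeat or extension of a
# different length can outrank the planted one in the scanner's
# mismatch-first collapse.
.mutateDNA <- function(s, mm) {
  if (mm == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  k <- length(ch)
  lo <- max(3L, k - 15L); hi <- min(k - 2L, 16L)
  pos <- sample(lo:hi, mm)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# make a planted repeat pair maximal: force the two bases flanking the
# distal copy on each side to mismatch their anchor-side counterparts, so
# the scanner cannot extend (or, for sub-threshold decoys, stretch) the
# repeat using coincidentally matching neighbours
.breakFlanks <- function(seq_ch, anchor, distal, width = 2L) {
  for (off in seq_len(width)) {
    seq_ch[distal[1] - off] <-
      sample(setdiff(c("A", "C", "G", "T"), seq_ch[anchor[1] - off]), 1)
    seq_ch[distal[2] + off] <-
      sample(setdiff(c("A", "C", "G", "T"), seq_ch[anchor[2] + off]), 1)
  }
  seq_ch
}

.truthMobility <- function(markers) {
  has_int <- "integrase" %in% markers
  has_pseudo_int <- "pseudo_integrase" %in% markers
  helper <- any(c("excisionase", "rep") %in% markers)
  if (has_int && helper) "predicted_active"
  else if (!has_int) "immobilized"   # pseudo-only or no integrase
  else "unclassified"
}

#' Simulate a genome carrying tRNA-integrated elements
#'
#' Builds a uniform-random background sequence, plants tRNA genes whose 3'
#' ends carry the anchor copy of a direct repeat, places the distal copy
#' (with the configured number of substitutions) at the far element
#' boundary, fills the element with cargo genes whose product strings
#' exercise the mobility classifier, and optionally plants decoy repeats
#' that each violate exactly one detection constraint (too short, beyond
#' the scan span, two mismatches, or not tRNA-anchored). After assembly
#' the generator verifies that no unplanned repeat is detectable under the
#' default scanner thresholds and regenerates (bounded retries, with a
#' warning) on collision, so planted repeats are guaranteed unique.
#'
#' @param config A [simConfig()] object.
#' @return A list: `sequence` (`DNAStringSet`), `genes` (`GRanges` of
#'   tRNAs and cargo genes with products), and `truth` (per-element
#'   coordinates, repeat descriptions, cargo ids, expected mobility;
#'   per-decoy type and coordinates; tRNA table).
#' @export
simulateGenomeWithElements <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  gn <- config$genome
  for (attempt in seq_len(10L)) {
    set.seed(.substreamSeed(config$seed, "genome") + (attempt - 1L) * 7919L)
    out <- .buildGenome(gn)
    if (.genomeClean(out, gn)) {
      if (attempt > 1)
        .warnf("planted-feature collision: regenerated genome (%d attempts)",
               attempt)
      return(out)
    }
  }
  .stopf("could not generate a collision-free genome in 10 attempts")
}

.buildGenome <- function(gn) {
  L <- gn$length
  seq_ch <- strsplit(.randomDNA(L), "")[[1]]
  cursor <- gn$margin
  trnas <- list(); genes <- list(); truth_el <- list(); truth_dec <- list()
  n_tr <- 0L
  place_trna <- function(cursor) {
    s <- cursor; e <- cursor + gn$trna_length - 1L
    if (e > L - gn$margin) .stopf("genome too short for planted features")
    list(start = s, end = e)
  }
  decoy_types <- c("short", "far", "mm2", "no_trna")

  for (el in gn$elements) {
    tr <- place_trna(cursor)
    n_tr <- n_tr + 1L
    tid <- sprintf("trna_%02d", n_tr)
    trnas[[tid]] <- c(tr$start, tr$end, 1L)  # strand + ; flipped later if set
    k <- el$dr_length
    anchor <- c(tr$end - k + 1L, tr$end)
    dstart <- tr$end + el$span + 1L
    distal <- c(dstart, dstart + k - 1L)
    if (distal[2] > L - gn$margin) .stopf("genome too short for element span")
    seq_ch[distal[1]:distal[2]] <-
      strsplit(.mutateDNA(paste(seq_ch[anchor[1]:anchor[2]],
                                collapse = ""), el$dr_mismatches), "")[[1]]
    seq_ch <- .breakFlanks(seq_ch, anchor, distal)
    # cargo genes inside the span (between the repeats)
    span <- c(tr$end + 1L, dstart - 1L)
    markers <- rep_len(c(el$markers,
                         rep("none", max(0, el$n_cargo - length(el$markers)))),
                       max(el$n_cargo, length(el$markers)))[seq_len(el$n_cargo)]
    gene_len <- 600L; gap <- 120L
    need <- el$n_cargo * (gene_len + gap) + 400L
    if (need > el$span)
      .stopf("element span %d too small for %d cargo genes", el$span,
             el$n_cargo)
    gpos <- span[1] + 200L
    cargo_ids <- character(el$n_cargo)
    for (j in seq_len(el$n_cargo)) {
      gid <- sprintf("%s_cargo%02d", tid, j)
      cargo_ids[j] <- gid
      genes[[gid]] <- list(start = gpos, end = gpos + gene_len - 1L,
                           strand = "+", type = "CDS",
                           product = .MARKER_PRODUCTS[[markers[j]]],
                           is_pseudo = markers[j] == "pseudo_integrase")
      gpos <- gpos + gene_len + gap
    }
    truth_el[[length(truth_el) + 1L]] <- data.frame(
      trna_id = tid,
      anchor_start = anchor[1], anchor_end = anchor[2],
      distal_start = distal[1], distal_end = distal[2],
      span_start = span[1], span_end = span[2],
      dr_length = k, mismatches = el$dr_mismatches,
      n_cargo = el$n_cargo,
      mobility = .truthMobility(markers),
      stringsAsFactors = FALSE)
    cursor <- distal[2] + gn$margin
  }

  n_dec <- gn$n_decoys
  for (d in seq_len(n_dec)) {
    typ <- decoy_types[(d - 1L) %% length(decoy_types) + 1L]
    if (typ == "no_trna") {
      # a same-strand repeat pair nowhere near a tRNA anchor window
      k <- 18L
      s1 <- cursor; s2 <- cursor + 6000L
      if (s2 + k - 1L > L - gn$margin) .stopf("genome too short for decoys")
      seq_ch[s2:(s2 + k - 1L)] <- seq_ch[s1:(s1 + k - 1L)]
      truth_dec[[length(truth_dec) + 1L]] <- data.frame(
        type = typ, anchor_start = s1, distal_start = s2, dr_length = k,
        mismatches = 0L, stringsAsFactors = FALSE)
      cursor <- s2 + k + gn$margin
      next
    }
    tr <- place_trna(cursor)
    n_tr <- n_tr + 1L
    tid <- sprintf("trna_%02d", n_tr)
    trnas[[tid]] <- c(tr$start, tr$end, 1L)
    k <- switch(typ, short = 14L, far = 18L, mm2 = 18L)
    mm <- if (typ == "mm2") 2L else 0L
    span <- switch(typ, short = 8000L, mm2 = 8000L,
                   far = gn$scan_max_span + 5000L)
    anchor <- c(tr$end - k + 1L, tr$end)
    dstart <- tr$end + span + 1L
    if (dstart + k - 1L > L - gn$margin)
      .stopf("genome too short for decoy type '%s'", typ)
    seq_ch[dstart:(dstart + k - 1L)] <-
      strsplit(.mutateDNA(paste(seq_ch[anchor[1]:anchor[2]],
                                collapse = ""), mm), "")[[1]]
    seq_ch <- .breakFlanks(seq_ch, anchor, c(dstart, dstart + k - 1L))
    truth_dec[[length(truth_dec) + 1L]] <- data.frame(
      type = typ, anchor_start = anchor[1], distal_start = dstart,
      dr_length = k, mismatches = mm, trna_id = tid,
      stringsAsFactors = FALSE)
    cursor <- dstart + k + gn$margin
  }

  genome <- DNAStringSet(setNames(paste(seq_ch, collapse = ""),
                                  gn$replicon_id))
  gr_list <- c(
    lapply(names(trnas), function(id) {
      v <- trnas[[id]]
      GRanges(gn$replicon_id, IRanges(v[1], v[2]), strand = "+",
              gene_id = id, type = "tRNA", product = "tRNA",
              is_pseudo = FALSE)
    }),
    lapply(names(genes), function(id) {
      g <- genes[[id]]
      GRanges(gn$replicon_id, IRanges(g$start, g$end), strand = g$strand,
              gene_id = id, type = g$type, product = g$product,
              is_pseudo = g$is_pseudo)
    }))
  gr <- if (length(gr_list)) sort(do.call(c, gr_list))
        else GRanges(seqnames = character(0), gene_id = character(0),
                     type = character(0), product = character(0),
                     is_pseudo = logical(0))
  GenomeInfoDb::seqlevels(gr) <- gn$replicon_id
  seqlengths(gr) <- setNames(L, gn$replicon_id)
  metadata(gr)$sequence <- genome
  list(sequence = genome, genes = gr,
       truth = list(
         elements = if (length(truth_el)) do.call(rbind, truth_el)
                    else NULL,
         decoys = if (length(truth_dec))
           do.call(function(...) rbind(..., make.row.names = FALSE),
                   lapply(truth_dec, function(x) {
                     x$trna_id <- x$trna_id %||% NA_character_; x
                   })) else NULL,
         trnas = data.frame(
           trna_id = names(trnas),
           start = vapply(trnas, function(v) as.numeric(v[1]), numeric(1)),
           end = vapply(trnas, function(v) as.numeric(v[2]), numeric(1)),
           stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# certify that the assembled genome contains no detectable repeat beyond
# the planted ones under the default scanner thresholds
.genomeClean <- function(out, gn) {
  trnas <- out$genes[mcols(out$genes)$type == "tRNA"]
  hits <- findTrnaAnchoredRepeats(out$sequence, trnas,
                                  max_span = gn$scan_max_span)
  expected <- out$truth$elements
  exp_starts <- if (is.null(expected)) integer(0)
                else expected$distal_start[
                  expected$dr_length >= 16 & expected$dr_length <= 20 &
                    expected$mismatches <= 1 &
                    (expected$span_end - expected$span_start + 1) +
                      expected$dr_length <= gn$scan_max_span]
  if (nrow(hits) != length(exp_starts)) return(FALSE)
  all(sort(hits$distal_start) == sort(exp_starts))
}

#' Write a simulated genome as FASTA + GFF3
#'
#' Convenience writer so simulated genomes can exercise the file readers.
#'
#' @param sim Output of [simulateGenomeWithElements()].
#' @param dir Output directory (created if needed).
#' @return Named character vector with the `fasta` and `gff3` paths.
#' @export
writeGenomeSim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fna")
  gff <- file.path(dir, "genome.gff3")
  writeXStringSet(sim$sequence, fasta)
  writeAnnotationsGFF3(sim$genes, gff)
  c(fasta = fasta, gff3 = gff)
}

# ---- island tables ----------------------------------------------------------

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")

.randomProtein <- function(n) paste(sample(.AA20, n, replace = TRUE),
                                    collapse = "")

.mutateProtein <- function(s, n_mut) {
  if (n_mut == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(.AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate a defense-island table with planted families
#'
#' Generates island families sharing a core gene-content set; each island
#' perturbs its family core by adding or removing single elements (one
#' content difference per perturbation, so islands of one family stay
#' within pairwise distance `2 * perturbations`). ORF protein sequences
#' are emitted such that same-family ORFs are at least 95 percent
#' identical while cross-family ORFs are unrelated random sequences,
#' matching the identity structure the family clustering assumes.
#'
#' @param config A [simConfig()] object.
#' @return A list: `islands` (`data.frame` with `island_id`,
#'   `orfs_from_contig_end` and the list column `content` of true family
#'   labels), `proteins` (`AAStringSet`, one entry per island ORF, named
#'   `islandid|familyid`), `orfs` (`data.frame` mapping ORF ids to island
#'   and planted family), and `truth` (`planted_family` per island).
#' @export
simulateIslandTable <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config$islands
  set.seed(.substreamSeed(config$seed, "islands"))
  nf <- cfg$n_families; cs <- cfg$content_size
  all_ids <- sprintf("OF%03d", seq_len(nf * cs + cfg$pool_extra))
  cores <- lapply(seq_len(nf), function(f)
    all_ids[((f - 1) * cs + 1):(f * cs)])
  pool <- all_ids[(nf * cs + 1):length(all_ids)]
  refs <- setNames(vapply(all_ids, function(i)
    .randomProtein(cfg$protein_length), character(1)), all_ids)
  # each member deviates from the family reference by at most 2% so any
  # two same-family members stay >= 95% identical pairwise
  max_mut <- floor(0.02 * cfg$protein_length)

  islands <- list(); prot_id <- character(0); prot_seq <- character(0)
  orf_rows <- list()
  planted <- character(0)
  n_isl <- 0L
  for (f in seq_len(nf)) {
    for (k in seq_len(cfg$islands_per_family)) {
      n_isl <- n_isl + 1L
      iid <- sprintf("isl_%03d", n_isl)
      content <- cores[[f]]
      for (p in seq_len(cfg$perturbations_per_island)) {
        if (runif(1) < 0.5 && length(content) > 1) {
          content <- content[-sample(length(content), 1)]
        } else {
          add <- setdiff(pool, content)
          content <- c(content, sample(add, 1))
        }
      }
      for (of in content) {
        oid <- paste0(iid, "|", of)
        n_mut <- min(rbinom(1, cfg$protein_length, cfg$mutation_rate),
                     max_mut)
        prot_id <- c(prot_id, oid)
        prot_seq <- c(prot_seq, .mutateProtein(refs[[of]], n_mut))
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          orf_id = oid, island_id = iid, planted_family = of,
          stringsAsFactors = FALSE)
      }
      islands[[length(islands) + 1L]] <- data.frame(
        island_id = iid, orfs_from_contig_end = 50L,
        stringsAsFactors = FALSE)
      islands[[length(islands)]]$content <- I(list(content))
      planted[iid] <- sprintf("famtruth_%02d", f)
    }
  }
  isl_df <- do.call(rbind, islands)
  rownames(isl_df) <- NULL
  list(islands = isl_df,
       proteins = AAStringSet(setNames(prot_seq, prot_id)),
       orfs = do.call(rbind, orf_rows),
       truth = list(planted_family = planted))
}
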
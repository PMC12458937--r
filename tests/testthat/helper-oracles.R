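# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package
# internals beyond standard library calls.

# --- direct-repeat scan oracle ----------------------------------------------
# Exhaustive enumeration of all constrained substring pairs for
# plus-strand tRNAs: every k-mer (k in [min_len, max_len]) starting in the
# anchor window is compared, position by position, against every
# downstream offset within max_span. N never matches. The collapse rule
# (fewest mismatches, then longest, then smallest distal start; conflict =
# same tRNA and both anchor and distal spans overlap) is re-implemented
# here from its definition.
oracle_scan <- function(seq_string, trnas, min_len = 16, max_len = 20,
                        max_mismatch = 1, max_span = 200000,
                        anchor_tail = 25, anchor_ext = 5) {
  ch <- strsplit(toupper(seq_string), "")[[1]]
  L <- length(ch)
  isN <- ch == "N"
  rows <- list()
  for (t in seq_len(nrow(trnas))) {
    e <- trnas$end[t]
    ws <- max(1L, e - anchor_tail + 1L)
    we <- min(L, e + anchor_ext)
    scan_to <- min(L, e + max_span)
    for (k in min_len:max_len) {
      d_first <- e + 1L
      d_last <- scan_to - k + 1L
      if (d_last < d_first) next
      ds <- d_first:d_last
      for (s in ws:we) {
        if (s + k - 1L > L) next
        ok_ds <- ds[ds >= s + k]   # distal copy must clear the anchor copy
        if (!length(ok_ds)) next
        mm <- integer(length(ok_ds))
        for (j in seq_len(k)) {
          a <- ch[s + j - 1L]
          b <- ch[ok_ds + j - 1L]
          mm <- mm + as.integer(b != a | b == "N" | a == "N")
        }
        hit <- which(mm <= max_mismatch)
        for (h in hit) {
          d <- ok_ds[h]
          rows[[length(rows) + 1L]] <- data.frame(
            trna_id = trnas$trna_id[t], anchor_start = s,
            anchor_end = s + k - 1L, distal_start = d,
            distal_end = d + k - 1L, length = k, mismatches = mm[h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(trna_id = character(0), anchor_start = integer(0),
                      anchor_end = integer(0), distal_start = integer(0),
                      distal_end = integer(0), length = integer(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, rows)
  # independent collapse
  df <- df[order(df$mismatches, -df$length, df$distal_start), ,
           drop = FALSE]
  kept <- df[0, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    conflict <- FALSE
    if (nrow(kept)) {
      same <- kept$trna_id == df$trna_id[i]
      a_ov <- kept$anchor_start <= df$anchor_end[i] &
        kept$anchor_end >= df$anchor_start[i]
      d_ov <- kept$distal_start <= df$distal_end[i] &
        kept$distal_end >= df$distal_start[i]
      conflict <- any(same & a_ov & d_ov)
    }
    if (!conflict) kept <- rbind(kept, df[i, , drop = FALSE])
  }
  kept <- kept[order(kept$trna_id, kept$distal_start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# --- greedy clustering oracle ------------------------------------------------
# All-pairs alignment statistics first, then the same greedy order
# (longest first, ties by id) applied over the precomputed matrix. The
# identity/coverage arithmetic is recomputed here from the aligned
# strings.
oracle_cluster <- function(seqs, identity_threshold = 0.9,
                           coverage_threshold = 0.8) {
  seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  ord <- order(-Biostrings::width(seqs), ids)
  pass <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { pass[i, j] <- TRUE; next }
    aln <- Biostrings::pairwiseAlignment(
      seqs[[i]], seqs[[j]], type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    both <- which(p != "-" & s != "-")
    if (!length(both)) next
    core <- both[1]:both[length(both)]
    idy <- sum(p[core] == s[core] & p[core] != "-") / length(core)
    covp <- sum(p[core] != "-") / length(seqs[[i]])
    covs <- sum(s[core] != "-") / length(seqs[[j]])
    pass[i, j] <- idy >= identity_threshold &&
      covp >= coverage_threshold && covs >= coverage_threshold
  }
  reps <- integer(0)
  fam <- setNames(integer(n), ids)
  for (i in ord) {
    hit <- NA_integer_
    for (r in seq_along(reps)) {
      if (pass[i, reps[r]]) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, i); hit <- length(reps) }
    fam[ids[i]] <- hit
  }
  fam
}

# --- connected-components oracle --------------------------------------------
# Exhaustive transitive closure by boolean matrix powering.
oracle_components <- function(contents, max_diff = 3) {
  n <- length(contents)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- length(setdiff(contents[[i]], contents[[j]])) +
      length(setdiff(contents[[j]], contents[[i]]))
    adj[i, j] <- d <= max_diff
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ] > 0] <- cid
    }
  }
  comp
}

# two labelings describe the same partition?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ta <- as.integer(factor(a, levels = unique(a)))
  tb <- as.integer(factor(b, levels = unique(b)))
  all(outer(ta, ta, "==") == outer(tb, tb, "=="))
}

# adjusted Rand index via mclust (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# recover island families end-to-end from a simulateIslandTable() output
recover_island_families <- function(sim) {
  fa <- clusterProteinFamilies(sim$proteins)
  fam <- familyOf(fa)
  content_by_island <- split(unname(fam[sim$orfs$orf_id]),
                             sim$orfs$island_id)
  isl <- data.frame(island_id = names(content_by_island),
                    stringsAsFactors = FALSE)
  isl$content <- I(lapply(content_by_island, unique))
  grp <- groupIslandFamilies(isl, max_diff = 3)
  m <- grp$membership
  setNames(m$family_id, m$island_id)
}

# tRNA table (plus strand) from a simulated gene GRanges
trna_df <- function(gr) {
  tr <- gr[S4Vectors::mcols(gr)$type == "tRNA"]
  data.frame(trna_id = tr$gene_id, start = GenomicRanges::start(tr),
             end = GenomicRanges::end(tr), stringsAsFactors = FALSE)
}

# AUC-synergy dataset: simulate one growth dataset at the given gamma and
# return the synergy call at MOI 1
auc_synergy_call <- function(seed, gamma) {
  cfg <- simConfig(seed = seed, growth = list(
    gamma = gamma, mois = 1, strains = c("sysA", "sysB", "both")))
  sim <- simulateGrowth(cfg)
  aucs <- areaUnderCurve(od600(sim$curves), timeMin(sim$curves),
                         baseline = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(sim$curves))
  m <- tapply(aucs, cd$strain, mean)
  isSynergy(callAucSynergy(m[["both"]], m[["sysA"]], m[["sysB"]]))
}
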
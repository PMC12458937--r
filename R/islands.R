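# Defense-island deduplication: greedy protein-family clustering of
# flanking ORFs, contig-edge filtering, neighborhood extraction and
# single-linkage grouping of islands by shared gene content.

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X")

# identity and mutual coverage from one global alignment; terminal-gap
# columns are trimmed (a shorter sequence aligned end-to-end inside a
# longer one has identity over the aligned core and coverage < 1 on the
# longer partner), internal gaps count as mismatch columns
.alignmentStats <- function(p_chars, s_chars, len_p, len_s) {
  non_gap <- which(p_chars != "-" & s_chars != "-")
  if (!length(non_gap))
    return(list(identity = 0, cov_p = 0, cov_s = 0))
  core <- non_gap[1]:non_gap[length(non_gap)]
  pc <- p_chars[core]; sc <- s_chars[core]
  matches <- sum(pc == sc & pc != "-")
  list(identity = matches / length(core),
       cov_p = sum(pc != "-") / len_p,
       cov_s = sum(sc != "-") / len_s)
}

.alignPair <- function(a, b, gap_opening, gap_extension) {
  aln <- pairwiseAlignment(a, b, type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = gap_opening,
                           gapExtension = gap_extension)
  p <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  .alignmentStats(p, s, length(a), length(b))
}

#' Greedy protein-family clustering by identity and coverage
#'
#' CD-HIT-style greedy incremental clustering of amino-acid sequences.
#' Sequences are processed longest first (ties broken by id,
#' lexicographically); each joins the earliest-founded family whose
#' representative it matches at `identity_threshold` or better over an
#' alignment covering at least `coverage_threshold` of **both** sequences,
#' otherwise it founds a new family. Identity is computed from a global
#' alignment (BLOSUM62, configurable gap penalties) over the aligned core
#' (terminal gaps trimmed; internal gaps count as columns).
#'
#' @param sequences Named `AAStringSet` or named character vector of
#'   protein sequences (standard 20 amino acids plus X).
#' @param identity_threshold Minimum identity (default 0.90).
#' @param coverage_threshold Minimum coverage of both sequences
#'   (default 0.80).
#' @param gap_opening,gap_extension Gap penalties (default 11 / 1).
#' @return A [FamilyAssignment-class].
#' @examples
#' seqs <- c(a = paste(rep("MKLV", 25), collapse = ""),
#'           b = paste(rep("MKLV", 25), collapse = ""))
#' familyOf(clusterProteinFamilies(seqs))
#' @export
clusterProteinFamilies <- function(sequences, identity_threshold = 0.90,
                                   coverage_threshold = 0.80,
                                   gap_opening = 11, gap_extension = 1) {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  if (!length(sequences))
    .stopf("clusterProteinFamilies: empty input")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    .stopf("clusterProteinFamilies: sequences must be named")
  chars <- strsplit(as.character(sequences), "")
  bad <- vapply(chars, function(x) any(!x %in% .AA_ALPHABET), logical(1))
  if (any(bad))
    .stopf("non-amino-acid characters in: %s",
           paste(names(sequences)[bad], collapse = ", "))
  ord <- order(-width(sequences), names(sequences))
  sequences <- sequences[ord]

  reps <- character(0)        # representative ids, founding order
  fam_of <- character(0)      # member -> family id
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    assigned <- NA_character_
    for (j in seq_along(reps)) {
      st <- .alignPair(sequences[[i]], sequences[[reps[j]]],
                       gap_opening, gap_extension)
      if (st$identity >= identity_threshold &&
          st$cov_p >= coverage_threshold &&
          st$cov_s >= coverage_threshold) {
        assigned <- sprintf("F%04d", j)
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- sprintf("F%04d", length(reps))
    }
    fam_of[id] <- assigned
  }
  representatives <- setNames(reps, sprintf("F%04d", seq_along(reps)))
  .dkLog("clusterProteinFamilies",
         c(identity_threshold, coverage_threshold),
         length(sequences), length(reps))
  new("FamilyAssignment", members = fam_of,
      representatives = representatives,
      parameters = c(identity = identity_threshold,
                     coverage = coverage_threshold))
}

#' Drop defense islands too close to a contig end
#'
#' Islands within `min_flank_orfs` ORFs of either contig end are excluded:
#' their neighborhood (and possibly the island itself) may be truncated by
#' the assembly, which would fake unique gene content.
#'
#' @param islands `data.frame` with a column `orfs_from_contig_end`
#'   (distance, in ORFs, to the nearer contig end).
#' @param min_flank_orfs Minimum distance kept (default 10; "at least",
#'   so an island exactly at the threshold is retained).
#' @return The filtered `data.frame`.
#' @export
filterContigEdgeIslands <- function(islands, min_flank_orfs = 10) {
  stopifnot(is.data.frame(islands),
            "orfs_from_contig_end" %in% names(islands))
  keep <- islands$orfs_from_contig_end >= min_flank_orfs
  .dkLog("filterContigEdgeIslands", min_flank_orfs, nrow(islands),
         sum(keep))
  islands[keep, , drop = FALSE]
}

#' Extract the gene neighborhood around an anchor gene
#'
#' Up to `flank` genes on each side of the anchor, in gene (table) order,
#' with signed offsets relative to the anchor. For a minus-strand anchor
#' the order and offset signs are reversed so that reading the result
#' left to right follows the anchor's 5' to 3' direction. Flanks
#' truncated by a contig end are simply shorter.
#'
#' @param gene_table `GRanges` of genes with a `gene_id` column (as from
#'   [readAnnotations()]).
#' @param anchor_gene_id Id of the anchor gene.
#' @param flank Genes to take on each side (default 50).
#' @return A `GRanges` ordered by offset, with an added integer `offset`
#'   column (0 = anchor; negative = upstream of the anchor 5' end).
#' @export
extractNeighborhood <- function(gene_table, anchor_gene_id, flank = 50) {
  stopifnot(is(gene_table, "GRanges"))
  gene_table <- gene_table[order(as.character(seqnames(gene_table)),
                                 start(gene_table))]
  hit <- which(mcols(gene_table)$gene_id == anchor_gene_id)
  if (!length(hit))
    .stopf("anchor gene '%s' not found", anchor_gene_id)
  i <- hit[1]
  same <- which(as.character(seqnames(gene_table)) ==
                  as.character(seqnames(gene_table))[i])
  lo <- max(min(same), i - flank)
  hi <- min(max(same), i + flank)
  idx <- lo:hi
  offsets <- idx - i
  if (as.character(strand(gene_table))[i] == "-") {
    idx <- rev(idx)
    offsets <- -rev(offsets)
  }
  out <- gene_table[idx]
  mcols(out)$offset <- offsets
  out
}

# symmetric difference size between two character sets
.setDiffSize <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Group defense islands by shared gene content
#'
#' Islands are compared by the symmetric difference of their gene-content
#' sets (defense genes plus adjacent-ORF families, combined; presence /
#' absence, copy number ignored). Islands differing by at most `max_diff`
#' elements are linked, and island families are the connected components
#' of that graph (single linkage): grouping, not pairwise-complete
#' clustering, so chains merge. Family ids are deterministic — the
#' smallest member island id.
#'
#' @param islands `data.frame` with columns `island_id` and a list column
#'   `content` (character vectors: defense gene families plus context ORF
#'   families), or separate list columns `defense_genes` and
#'   `context_families` which are combined.
#' @param max_diff Maximum content differences linking two islands
#'   (default 3).
#' @return A list with `membership` (`data.frame`: `island_id`,
#'   `family_id`) and `families` (per family: `family_id`, `members`,
#'   `consensus` — the content elements shared by all members).
#' @export
groupIslandFamilies <- function(islands, max_diff = 3) {
  stopifnot(is.data.frame(islands), "island_id" %in% names(islands))
  if ("content" %in% names(islands)) {
    content <- islands$content
  } else if (all(c("defense_genes", "context_families") %in%
                 names(islands))) {
    content <- mapply(function(a, b) unique(c(a, b)),
                      islands$defense_genes, islands$context_families,
                      SIMPLIFY = FALSE)
  } else {
    .stopf("islands need a 'content' list column (or 'defense_genes' + 'context_families')")
  }
  n <- nrow(islands)
  ids <- as.character(islands$island_id)
  if (n == 0)
    return(list(membership = data.frame(island_id = character(0),
                                        family_id = character(0)),
                families = list()))
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    link <- vapply(seq_len(nrow(pairs)), function(k) {
      .setDiffSize(content[[pairs[k, 1]]], content[[pairs[k, 2]]]) <=
        max_diff
    }, logical(1))
    edges <- pairs[link, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  fam_id <- vapply(seq_len(max(comp)), function(k)
    min(ids[comp == k]), character(1))
  membership <- data.frame(island_id = ids, family_id = fam_id[comp],
                           stringsAsFactors = FALSE)
  families <- lapply(sort(unique(fam_id)), function(f) {
    members <- ids[membership$family_id == f]
    cons <- Reduce(intersect, content[match(members, ids)])
    list(family_id = f, members = members, consensus = cons)
  })
  .dkLog("groupIslandFamilies", max_diff, n, length(families))
  list(membership = membership, families = families)
}
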
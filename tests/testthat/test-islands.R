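# Protein-family clustering, contig-edge filter, neighborhoods and
# island grouping.

mkprot <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

mutate_at <- function(s, k, seed) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos)
    ch[p] <- sample(setdiff(c("A","C","D","E","F","G","H","I","K","L"),
                            ch[p]), 1)
  paste(ch, collapse = "")
}

test_that("identity and coverage thresholds separate families", {
  base <- mkprot(100, 1)
  # identical pair: one family
  fa <- clusterProteinFamilies(c(s1 = base, s2 = base))
  expect_equal(length(representatives(fa)), 1)
  expect_equal(unname(familyOf(fa)[["s1"]]), unname(familyOf(fa)[["s2"]]))

  # 15 of 100 positions differ: 85% identity, below the 90% threshold
  fa2 <- clusterProteinFamilies(c(s1 = base,
                                  s2 = mutate_at(base, 15, 2)))
  expect_equal(length(representatives(fa2)), 2)

  # 5 differences: 95% identity, same family
  fa3 <- clusterProteinFamilies(c(s1 = base,
                                  s2 = mutate_at(base, 5, 3)))
  expect_equal(length(representatives(fa3)), 1)

  # a perfect 70-aa prefix: identity 1.0 on the aligned core, but only
  # 70% coverage of the long sequence -> separate families
  fa4 <- clusterProteinFamilies(c(long = base,
                                  short = substr(base, 1, 70)))
  expect_equal(length(representatives(fa4)), 2)

  expect_error(clusterProteinFamilies(character(0)), "empty|named")
  expect_error(clusterProteinFamilies(c(a = "MKLB")), "non-amino-acid.*a")
})

test_that("representatives found their own families deterministically", {
  seqs <- c(b = mkprot(80, 4), a = mkprot(80, 5),
            c = paste0(mkprot(80, 4), "AAAA"))
  fa <- clusterProteinFamilies(seqs)
  reps <- representatives(fa)
  expect_true(all(familyOf(fa)[reps] == names(reps)))
  fa2 <- clusterProteinFamilies(seqs)
  expect_identical(familyOf(fa), familyOf(fa2))
})

test_that("greedy clustering equals the all-pairs brute-force oracle", {
  # three planted families plus singletons, up to 30 sequences
  set.seed(9)
  seqs <- character(0)
  for (f in 1:3) {
    ref <- mkprot(120, 100 + f)
    for (m in 1:5)
      seqs[sprintf("f%d_m%d", f, m)] <- mutate_at(ref, sample(0:4, 1),
                                                  200 + 10 * f + m)
  }
  for (s in 1:6) seqs[sprintf("solo%d", s)] <- mkprot(90 + s, 300 + s)
  fam_pkg <- familyOf(clusterProteinFamilies(seqs))
  fam_ora <- oracle_cluster(seqs)
  expect_true(same_partition(fam_pkg[names(seqs)],
                             fam_ora[names(seqs)]))
})

test_that("contig-edge filter keeps islands at or beyond the threshold", {
  isl <- data.frame(island_id = c("i1", "i2", "i3"),
                    orfs_from_contig_end = c(5, 10, 200))
  kept <- filterContigEdgeIslands(isl)
  expect_setequal(kept$island_id, c("i2", "i3"))  # "at least 10": i2 stays
})

test_that("neighborhood extraction truncates at contig ends and respects strand", {
  gr <- GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(seq(1, 991, by = 100), width = 50),
    strand = "+", gene_id = sprintf("g%02d", 1:10))
  nb <- extractNeighborhood(gr, "g03", flank = 50)
  expect_equal(length(nb), 10)  # 2 upstream + anchor + 7 downstream
  expect_equal(range(nb$offset), c(-2, 7))
  expect_equal(nb$gene_id[nb$offset == 0], "g03")

  nb0 <- extractNeighborhood(gr, "g03", flank = 0)
  expect_equal(nb0$gene_id, "g03")

  # minus-strand anchor: reversed order, negated offsets
  grm <- gr
  GenomicRanges::strand(grm)[3] <- "-"
  nbm <- extractNeighborhood(grm, "g03", flank = 50)
  expect_equal(nbm$gene_id, rev(nb$gene_id))
  expect_equal(nbm$offset, -rev(nb$offset))

  expect_error(extractNeighborhood(gr, "nope"), "not found")
})

test_that("island grouping is single-linkage over content differences", {
  mk <- function(...) I(list(...))
  isl <- data.frame(island_id = c("a", "b", "c"))
  isl$content <- mk(c("f1", "f2", "f3"), c("f1", "f2", "f3"),
                    c("f1", "f2", "f3"))
  g <- groupIslandFamilies(isl)
  expect_equal(length(g$families), 1)

  # exactly 3 differences still link ("up to three")
  isl2 <- data.frame(island_id = c("a", "b"))
  isl2$content <- mk(c("f1", "f2", "f3", "f4"),
                     c("f1", "f2", "f3", "f5", "f6"))
  expect_equal(length(groupIslandFamilies(isl2)$families), 1)
  # 4 differences do not
  isl3 <- data.frame(island_id = c("a", "b"))
  isl3$content <- mk(c("f1", "f2", "f3", "f4"),
                     c("f1", "f2", "f5", "f6"))
  expect_equal(length(groupIslandFamilies(isl3)$families), 2)

  # chain a-b (d=3), b-c (d=3), a-c (d=6): one family via the chain
  isl4 <- data.frame(island_id = c("a", "b", "c"))
  isl4$content <- mk(c("x1", "x2", "x3", "x4", "x5", "x6"),
                     c("x1", "x2", "x3", "x4", "y5", "y6", "x5"),
                     c("x1", "x2", "x3", "x4", "y5", "y6", "z7"))
  g4 <- groupIslandFamilies(isl4)
  expect_equal(length(g4$families), 1)
  expect_equal(g4$membership$family_id, rep("a", 3))
})

test_that("grouping matches the transitive-closure oracle on random sets", {
  set.seed(31)
  pool <- sprintf("f%02d", 1:25)
  for (rep in 1:10) {
    contents <- lapply(1:8, function(i) sample(pool, sample(4:9, 1)))
    isl <- data.frame(island_id = sprintf("i%02d", 1:8))
    isl$content <- I(contents)
    g <- groupIslandFamilies(isl)
    comp <- oracle_components(contents, 3)
    expect_true(same_partition(g$membership$family_id, comp))
    # partition: disjoint and covering
    expect_setequal(g$membership$island_id, isl$island_id)
    expect_equal(anyDuplicated(g$membership$island_id), 0)
    # monotone: families at max_diff k refine those at k+1
    g4 <- groupIslandFamilies(isl, max_diff = 4)
    m3 <- setNames(g$membership$family_id, g$membership$island_id)
    m4 <- setNames(g4$membership$family_id, g4$membership$island_id)
    for (f in unique(m3)) {
      expect_equal(length(unique(m4[names(m3)[m3 == f]])), 1)
    }
  }
})

test_that("planted island families are recovered exactly", {
  for (pert in 0:1) {
    sim <- simulateIslandTable(simConfig(
      seed = 40 + pert,
      islands = list(n_families = 4, islands_per_family = 3,
                     content_size = 8, perturbations_per_island = pert,
                     protein_length = 100)))
    rec <- recover_island_families(sim)
    planted <- sim$truth$planted_family[names(rec)]
    expect_equal(ari(rec, planted), 1.0)
  }
})
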
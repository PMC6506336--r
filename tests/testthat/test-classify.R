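rec1 <- function(chrom, pos, ref, alt, vaf = 0.5, sample = "s") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vaf = vaf,
             sample = sample, stringsAsFactors = FALSE)
}

test_that("substitution classification follows the pyrimidine convention", {
  g <- tiny_genome("TACGA")
  # ref triplet ACG, C>T
  expect_equal(as.vector(classify_sbs(rec1("chr1", 3, "C", "T"), g)),
               "A[C>T]G")
  g2 <- tiny_genome("ATGCA")
  # ref triplet TGC, G>A -> reverse complement GCA -> C>T at GpCpA
  expect_equal(as.vector(classify_sbs(rec1("chr1", 3, "G", "A"), g2)),
               "G[C>T]A")
})

test_that("exhaustive enumeration of contexts yields 96 channels, each hit by
           a strand-collapsed pair", {
  bases <- c("A", "C", "G", "T")
  tri64 <- character(0)
  for (f in bases) for (c in bases) for (t in bases)
    tri64 <- c(tri64, paste0(f, c, t))
  seq <- paste(tri64, collapse = "")
  g <- tiny_genome(seq)
  centers <- seq(2, by = 3, length.out = 64)
  hits <- character(0)
  for (i in seq_along(centers)) {
    ref <- substr(tri64[i], 2, 2)
    for (alt in setdiff(bases, ref)) {
      ch <- classify_sbs(rec1("chr1", centers[i], ref, alt), g)
      hits <- c(hits, as.vector(ch))
    }
  }
  expect_length(hits, 192)
  expect_equal(sort(unique(hits)), sort(sbs96_channels()))
  # strand-collapse involution: every channel is produced exactly twice
  expect_true(all(table(hits) == 2))
})

test_that("classification excludes edge positions and flags ref mismatches", {
  g <- tiny_genome("ACGTA")
  ch <- classify_sbs(rec1("chr1", 1, "A", "G"), g)
  expect_true(is.na(ch[1]))
  expect_equal(attr(ch, "excluded"), 1L)
  expect_error(classify_sbs(rec1("chr1", 3, "T", "A"), g), "mismatch")
})

test_that("doublet detection merges pairs and excludes longer runs", {
  g <- NULL
  base <- rec1("chr1", c(100L, 101L), c("C", "C"), c("T", "T"))
  dd <- detect_doublets(base)
  expect_equal(nrow(dd$doublets), 1)
  expect_equal(dd$doublets$ref_dinuc, "CC")
  expect_equal(dd$doublets$alt_dinuc, "TT")
  expect_equal(nrow(dd$singles), 0)

  gap <- rec1("chr1", c(100L, 102L), c("C", "C"), c("T", "T"))
  dd <- detect_doublets(gap)
  expect_equal(nrow(dd$doublets), 0)
  expect_equal(nrow(dd$singles), 2)

  run <- rec1("chr1", c(100L, 101L, 102L), c("C", "C", "C"), c("T", "T", "T"))
  dd <- detect_doublets(run)
  expect_equal(nrow(dd$doublets), 0)
  expect_equal(nrow(dd$singles), 0)
  expect_equal(nrow(dd$excluded), 3)
})

test_that("doublet detection conserves counts over all placements on a 5-bp
           contig", {
  # every subset of positions 1..5 as substitution positions
  for (k in 1:5) {
    combos <- utils::combn(1:5, k, simplify = FALSE)
    for (pos in combos) {
      rec <- rec1("chr1", as.integer(pos), rep("C", k), rep("T", k))
      dd <- detect_doublets(rec)
      expect_equal(nrow(dd$singles) + 2 * nrow(dd$doublets) +
                     nrow(dd$excluded), k)
      # no adjacent pair survives among singles
      if (nrow(dd$singles) > 1)
        expect_true(all(diff(sort(dd$singles$pos)) > 1))
    }
  }
})

test_that("indel classification matches the worked examples", {
  # deletion of one C inside CCCCC -> C deletion at a >=5 tract
  g <- tiny_genome("ATCCCCCATAT")
  del <- rec1("chr1", 3, "CC", "C")  # anchored: deletes one C of the run
  expect_equal(as.vector(classify_indel(del, g)), "del:1bp:C:5+")

  # insertion of one T after GG next to a single T -> shortest occupied bin
  g2 <- tiny_genome("AGGTCAGAT")
  ins <- rec1("chr1", 3, "G", "GT")  # inserts T between GG and T
  expect_equal(as.vector(classify_indel(ins, g2)), "ins:1bp:T:1-2")

  # T insertion with no matching neighbour -> bin 0
  ins0 <- rec1("chr1", 5, "C", "CT")  # between C and A
  expect_equal(as.vector(classify_indel(ins0, g2)), "ins:1bp:T:0")

  # deletion of ACG with flanking AC, no flanking repeat -> microhomology
  g3 <- tiny_genome("TTACGACTT")
  mh <- rec1("chr1", 2, "TACG", "T")
  expect_equal(as.vector(classify_indel(mh, g3)), "del:MH")
  expect_equal(sigscreen:::mh_length("TTACGACTT", 3, 5, "ACG"), 2)
})

test_that("indel classification is invariant to left/right normalization", {
  g <- tiny_genome("ATCCCCCATAT")
  left <- rec1("chr1", 2, "TC", "T")    # delete first C of the run
  right <- rec1("chr1", 7, "CA", "A")   # delete last C (unanchored dialect)
  mid <- rec1("chr1", 4, "CC", "C")
  expect_equal(as.vector(classify_indel(left, g)),
               as.vector(classify_indel(mid, g)))
  expect_equal(as.vector(classify_indel(right, g)),
               as.vector(classify_indel(mid, g)))

  # multi-bp: deletion of one AC in ACACAC however it is represented
  g2 <- tiny_genome("TTACACACGT")
  d1 <- rec1("chr1", 2, "TAC", "T")
  d2 <- rec1("chr1", 6, "CAC", "C")
  expect_equal(as.vector(classify_indel(d1, g2)), "del:2bp:rep")
  expect_equal(as.vector(classify_indel(d1, g2)),
               as.vector(classify_indel(d2, g2)))
})

test_that("indels at contig edges and complex events are excluded, counted", {
  g <- tiny_genome("CCCTTAAG")
  edge <- rec1("chr1", 7, "AG", "A")   # deletion touches last base
  ch <- classify_indel(edge, g)
  expect_true(is.na(ch[1]))
  expect_equal(attr(ch, "excluded"), 1L)
  complex <- rec1("chr1", 2, "CCT", "CAA")
  expect_true(is.na(classify_indel(complex, g)[1]))
})

test_that("profiles conserve record counts", {
  g <- fx_genome()
  set.seed(42)
  m <- sample_mutations(g, default_background_sbs(), 300, sample = "s")
  p <- build_profile(m, "SBS96", g, sample = "s")
  expect_equal(sum(p) + attr(p, "excluded"), nrow(m))
  expect_equal(attr(p, "scheme"), "SBS96")
  # 3 mutations all one channel
  g2 <- tiny_genome("TACGATTACGATT")
  recs <- rec1("chr1", c(3L, 9L), c("C", "C"), c("T", "T"))
  p2 <- build_profile(recs, "SBS96", g2)
  expect_equal(sum(p2), 2)
  expect_equal(unname(p2["A[C>T]G"]), 2)
  # empty input -> zero vector
  p0 <- build_profile(recs[0, ], "SBS96", g2)
  expect_equal(sum(p0), 0)
  expect_length(p0, 96)
})
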
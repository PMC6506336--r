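# a hand-built genome with known gene geometry:
#   chr1: 1..40 gene on +, 61..100 gene on -, 45..55 genes on both strands
topo_genome <- function() {
  set.seed(71)
  seq <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  genes <- data.frame(chrom = "chr1",
                      start = c(1L, 61L, 45L, 45L),
                      end = c(40L, 100L, 55L, 55L),
                      strand = c("+", "-", "+", "-"))
  toy_genome(c(chr1 = seq), genes = genes)
}

rec_at <- function(g, pos, alt_of = NULL) {
  ref <- genome_base_chr(g, pos)
  alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1))
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt, vaf = 0.5,
             sample = "s", stringsAsFactors = FALSE)
}

genome_base_chr <- function(g, pos) {
  vapply(pos, function(p) substr(g$sequences[["chr1"]], p, p), character(1))
}

test_that("transcriptional strand assignment follows the pyrimidine rule", {
  g <- topo_genome()
  seqc <- strsplit(g$sequences[["chr1"]], "")[[1]]
  pyr_pos <- which(seqc %in% c("C", "T"))
  p_plus <- pyr_pos[pyr_pos <= 40][1]          # pyrimidine in + gene
  p_minus <- pyr_pos[pyr_pos >= 61 & pyr_pos <= 100][1]  # in - gene
  r <- rec_at(g, c(p_plus, p_minus))
  st <- assign_tx_strand(r, g)
  # C/T on + strand inside a + gene: pyrimidine on the coding strand
  expect_equal(st[1], "non_transcribed")
  expect_equal(st[2], "transcribed")
  # both-strand overlap is ambiguous; outside genes intergenic
  r2 <- rec_at(g, c(50L, 42L))
  expect_equal(assign_tx_strand(r2, g), c("ambiguous", "intergenic"))
})

test_that("strand assignment is consistent under reverse complementation", {
  g <- topo_genome()
  L <- 100L
  rc_seq <- revcomp(g$sequences[["chr1"]])
  flip <- function(s) unname(c("+" = "-", "-" = "+")[s])
  pos <- c(5L, 20L, 35L, 70L, 90L)
  r <- rec_at(g, pos)
  r_rc <- r
  r_rc$pos <- L + 1L - r$pos
  r_rc$ref <- chartr("ACGT", "TGCA", r$ref)
  r_rc$alt <- chartr("ACGT", "TGCA", r$alt)
  a <- assign_tx_strand(r, g)

  # the same physical molecule written from the other strand (annotation
  # strands flipped along with the sequence): assignments are unchanged
  genes_flip <- data.frame(chrom = "chr1",
                           start = L + 1L - g$genes$end,
                           end = L + 1L - g$genes$start,
                           strand = flip(g$genes$strand))
  g_same <- toy_genome(c(chr1 = rc_seq), genes = genes_flip)
  expect_equal(assign_tx_strand(r_rc, g_same), a)

  # complementing sequence and records while keeping the annotation strands
  # flips transcribed <-> non_transcribed exactly
  genes_keep <- data.frame(chrom = "chr1",
                           start = L + 1L - g$genes$end,
                           end = L + 1L - g$genes$start,
                           strand = g$genes$strand)
  g_swap <- toy_genome(c(chr1 = rc_seq), genes = genes_keep)
  b <- assign_tx_strand(r_rc, g_swap)
  swap <- c(transcribed = "non_transcribed", non_transcribed = "transcribed",
            ambiguous = "ambiguous", intergenic = "intergenic")
  expect_equal(unname(swap[a]), b)
})

test_that("strand chi-square matches closed forms and skips sparse classes", {
  tal <- data.frame(mutation_class = c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"),
                    transcribed = c(50L, 90L, 2L, 30L, 40L, 60L),
                    non_transcribed = c(50L, 10L, 1L, 30L, 40L, 40L),
                    excluded_ambiguous = 0L, intergenic = 0L)
  st <- strand_asymmetry_test(tal)
  expect_equal(st$p[1], 1)                      # (50, 50)
  expect_equal(st$chisq[2], 64)                 # (90, 10)
  expect_equal(st$p[2], stats::pchisq(64, 1, lower.tail = FALSE))
  expect_lt(st$p[2], 1e-14)
  expect_false(st$tested[3])                    # < 5 genic mutations
  expect_true(is.na(st$q[3]))
  expect_equal(st$tier[2], "***")
  # conservation: strand counts plus exclusions account for all records
  g <- fx_genome()
  set.seed(72)
  m <- sample_mutations(g, default_background_sbs(), 400, sample = "s")
  tal2 <- strand_tally(m, g)
  expect_equal(sum(tal2$transcribed + tal2$non_transcribed +
                     tal2$excluded_ambiguous + tal2$intergenic), nrow(m))
})

test_that("an injected 9:1 transcriptional bias is strongly detected", {
  g <- fx_genome_cal()
  m <- sample_mutations(g, default_background_sbs(), 500, sample = "s",
                        strand_bias = 9, seed = 73)
  st <- strand_asymmetry_test(strand_tally(m, g))
  # the dominant class carries the signal
  top <- which.max(st$transcribed + st$non_transcribed)
  expect_lte(st$q[top], 0.001)
})

test_that("replication-timing analysis is self-consistent and detects an
           injected late-replication gradient", {
  g <- fx_genome_cal()
  sig <- default_background_sbs()
  m <- sample_mutations(g, sig, 600, sample = "s", seed = 74)
  rtd <- rtd_analysis(m, g, sig, n_sims = 60, seed = 75)
  expect_equal(sum(rtd$observed), sum(vapply(1:10, function(d)
    rtd$observed[d], numeric(1))))
  expect_equal(sum(round(rowSums(rtd$expected) / nrow(rtd$expected))),
               sum(rtd$observed))
  expect_false(rtd$different)

  m2 <- sample_mutations(g, sig, 600, sample = "s", rtd_gradient = 4,
                         seed = 76)
  rtd2 <- rtd_analysis(m2, g, sig, n_sims = 60, seed = 77)
  expect_true(rtd2$different)
})

test_that("CpG enrichment recovers extreme and null tables", {
  g <- fx_genome_cal()
  # all mutations at CpG-track G:C sites
  flat_cpg <- which(g$flat_cpg & (g$flat_base == 1L | g$flat_base == 2L))
  pos <- flat_cpg[seq(1, min(60, length(flat_cpg)))]
  ref <- c("A", "C", "G", "T")[g$flat_base[pos] + 1L]
  rec <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = "T",
                    vaf = 0.5, sample = "s")
  rec$alt[rec$ref == "T"] <- "A"
  ce <- cpg_enrichment(rec, g)
  expect_gt(ce$odds_ratio, 10)
  expect_lt(ce$p, 0.01)

  # identical margins -> OR 1, p 1 (constructed table through the same test)
  tab <- matrix(c(10, 90, 10, 90), 2)
  ft <- stats::fisher.test(tab)
  expect_equal(unname(ft$estimate), 1, tolerance = 1e-9)
  expect_equal(ft$p.value, 1)

  # uniform mutations over G:C sites: no enrichment signal in the median run
  set.seed(78)
  ps <- replicate(15, {
    gc_sites <- which(g$flat_base == 1L | g$flat_base == 2L)
    pos <- sample(gc_sites, 200)
    ref <- c("A", "C", "G", "T")[g$flat_base[pos] + 1L]
    rec <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = "A",
                      vaf = 0.5, sample = "s")
    rec$alt[rec$ref == "A"] <- "G"
    cpg_enrichment(rec, g)$p
  })
  expect_gt(stats::median(ps), 0.05)
})

test_that("strand asymmetry across deciles recovers flat and graded
           injections", {
  g <- fx_genome_cal()
  m <- sample_mutations(g, default_background_sbs(), 3000, sample = "s",
                        strand_bias = 4, seed = 79)
  res <- strand_asymmetry_by_rtd(m, g, NULL)
  # constant asymmetry across deciles: small gradient
  expect_lt(abs(res$gradient), 0.15)
  # per-decile counts conserve the overall tallies
  st <- assign_tx_strand(m, g)
  expect_equal(sum(res$per_decile$transcribed), sum(st == "transcribed"))
  expect_equal(sum(res$per_decile$non_transcribed),
               sum(st == "non_transcribed"))

  # hand-built catalog with asymmetry decreasing early -> late
  set.seed(80)
  plus_gene <- g$flat_gene == 1L; minus_gene <- g$flat_gene == 2L
  tx_type <- (plus_gene & !g$flat_pyr) | (minus_gene & g$flat_pyr)
  ntx_type <- (plus_gene & g$flat_pyr) | (minus_gene & !g$flat_pyr)
  pick <- function(type, d, k) {
    idx <- which(type & g$flat_decile == d & !is.na(g$ctx32$chr1))
    sample(idx, min(k, length(idx)))
  }
  rows <- list()
  for (d in 1:10) {
    frac_tx <- 0.85 - 0.06 * d          # 0.79 down to 0.25
    k_tx <- round(60 * frac_tx); k_ntx <- 60 - k_tx
    pos <- c(pick(tx_type, d, k_tx), pick(ntx_type, d, k_ntx))
    if (length(pos) == 0L) next
    ref <- c("A", "C", "G", "T")[g$flat_base[pos] + 1L]
    alt <- chartr("ACGT", "CAtg", ref)  # any different base
    alt <- toupper(alt)
    rows[[d]] <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                            vaf = 0.5, sample = "s")
  }
  graded <- do.call(rbind, rows)
  res2 <- strand_asymmetry_by_rtd(graded, g, NULL)
  expect_gt(res2$gradient, 0.1)
})
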
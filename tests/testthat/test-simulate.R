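test_that("mutation sampling round-trips through classification", {
  g <- fx_genome()
  # one-hot signature: all mutations re-classify to that channel
  sig <- stats::setNames(1, "A[C>A]A")
  m <- sample_mutations(g, sig, 50, sample = "s", seed = 4)
  expect_equal(nrow(m), 50)
  expect_true(all(classify_sbs(m, g) == "A[C>A]A"))
  expect_false(anyDuplicated(m$pos) > 0)
  # n = 0 -> empty
  expect_equal(nrow(sample_mutations(g, sig, 0, seed = 1)), 0)
})

test_that("sampled channel frequencies follow the signature (multinomial)", {
  g <- fx_genome_cal()
  sig <- default_background_sbs()
  m <- sample_mutations(g, sig, 5000, sample = "s", seed = 8)
  p <- build_profile(m, "SBS96", g)
  expect_gte(cosine(as.numeric(p), sig[names(p)]), 0.99)
  # per-channel goodness of fit at the 99% level
  gof <- stats::chisq.test(as.vector(p), p = sig[names(p)])
  expect_gt(gof$p.value, 0.01)
})

test_that("a channel with no matching genomic sites raises a named error", {
  g <- tiny_genome("AAAAAAAAAA")  # no C-centred contexts at all
  sig <- stats::setNames(1, "A[C>A]A")
  expect_error(sample_mutations(g, sig, 5, seed = 1), "A\\[C>A\\]A")
})

test_that("clonal VAFs are near 0.5 and contamination sits below the filter", {
  g <- fx_genome()
  m <- sample_mutations(g, default_background_sbs(), 400, sample = "s",
                        contamination = 0.3, seed = 9)
  expect_gt(nrow(m), 400)  # extra low-VAF records appended
  low <- m$vaf < 0.2
  expect_gt(sum(low), 0)
  expect_gt(mean(m$vaf[!low]), 0.4)
  expect_lt(mean(m$vaf[!low]), 0.6)
  kept <- filter_vaf(m)
  expect_true(all(kept$vaf >= 0.2))
})

test_that("doublet sampling emits adjacent pairs that re-classify", {
  g <- fx_genome()
  sig <- default_dbs_signature()
  d <- sample_doublets(g, sig, 25, sample = "s", seed = 5)
  dd <- detect_doublets(d)
  expect_equal(nrow(dd$doublets), 25)
  expect_equal(nrow(dd$singles), 0)
  expect_true(all(classify_dbs(dd$doublets) %in%
                    names(sig)[sig > 0]))
})

test_that("indel sampling hits its target channels", {
  g <- fx_genome_cal()
  sig <- default_background_indel()
  ind <- sample_indels(g, sig, 120, sample = "s", seed = 6)
  expect_equal(nrow(ind), 120)
  ch <- classify_indel(ind, g)
  expect_true(all(!is.na(ch)))
  expect_true(all(ch %in% names(sig)[sig > 0]))
  # aggregated frequencies track the signature
  p <- build_profile(ind, "ID29", g)
  expect_gte(cosine(as.numeric(p), sig[names(p)]), 0.9)
})

test_that("simulated experiments are byte-identical under a fixed seed", {
  g <- make_genome(30000, 0.45, n_genes = 4, seed = 11)
  cfg <- sim_config(n_controls = 4, treatments = list(
    treatment_spec("tx", 2, sub_excess = 100)), seed = 77,
    background_sub_burden = 60, background_indel_burden = 4,
    shared_per_group = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(g, cfg, dir = d1)
  simulate_experiment(g, cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 5)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("control burdens are Poisson around the configured means", {
  g <- fx_genome_cal()
  cfg <- sim_config(n_controls = 100, treatments = list(), seed = 13,
                    background_sub_burden = 80, background_indel_burden = 6,
                    background_dbs_burden = 1, shared_per_group = 0,
                    contamination = 0)
  ex <- simulate_experiment(g, cfg)
  subs <- vapply(ex$catalogs, function(r) sum(nchar(r$ref) == 1 &
                                                nchar(r$alt) == 1), numeric(1))
  # doublets contribute 2 substitution rows each; subtract them
  dbl <- vapply(ex$catalogs, function(r) {
    s <- r[nchar(r$ref) == 1 & nchar(r$alt) == 1, ]
    nrow(detect_doublets(s)$doublets)
  }, numeric(1))
  singles <- subs - 2 * dbl
  expect_lt(abs(mean(singles) - 80) / 80, 0.05)
  expect_lt(abs(stats::var(singles) - 80) / 80, 0.35)  # Poisson dispersion
  ind <- vapply(ex$catalogs, function(r) sum(nchar(r$ref) != nchar(r$alt)),
                numeric(1))
  expect_lt(abs(mean(ind) - 6) / 6, 0.15)
})

test_that("zero-excess treatments are indistinguishable from controls", {
  g <- fx_genome_cal()
  cfg <- sim_config(n_controls = 20, treatments = list(
    treatment_spec("nullA", 4, sub_excess = 0),
    treatment_spec("nullB", 4, sub_excess = 0)), seed = 21,
    background_sub_burden = 120, shared_per_group = 0, contamination = 0)
  ex <- simulate_experiment(g, cfg)
  burden <- vapply(ex$catalogs, nrow, numeric(1))
  is_ctrl <- ex$metadata$treatment == "control"
  p <- stats::wilcox.test(burden[ex$metadata$sample[is_ctrl]],
                          burden[ex$metadata$sample[!is_ctrl]],
                          exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("the truth manifest round-trips the injected signature exactly", {
  g <- make_genome(30000, 0.45, n_genes = 2, seed = 3)
  truth_sig <- fx_truth_sbs()
  cfg <- sim_config(n_controls = 2, treatments = list(
    treatment_spec("tx", 2, sub_signature = truth_sig, sub_excess = 50)),
    seed = 5, background_sub_burden = 30, background_indel_burden = 0,
    background_dbs_burden = 0, shared_per_group = 0)
  d <- withr::local_tempdir()
  simulate_experiment(g, cfg, dir = d)
  manifest <- jsonlite::read_json(file.path(d, "truth.json"),
                                  simplifyVector = FALSE)
  re_read <- unlist(manifest$treatments[[1]]$sub_signature)
  expect_equal(cosine(re_read[sbs96_channels()], truth_sig), 1.0,
               tolerance = 1e-12)
  expect_error(
    sim_config(treatments = list(treatment_spec("a"), treatment_spec("a"))),
    "duplicate")
})
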
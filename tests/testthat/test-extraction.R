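mk_prof <- function(counts, scheme = "SBS96", sample = "s") {
  channels <- scheme_channels(scheme)
  v <- stats::setNames(integer(length(channels)), channels)
  v[seq_along(counts)] <- as.integer(counts)
  structure(v, scheme = scheme, sample = sample, excluded = 0L)
}

test_that("background model is the exact mean/aggregate of control profiles", {
  p1 <- mk_prof(c(10, 20, 30))
  p2 <- mk_prof(c(10, 20, 30))
  bg <- fit_background(list(a = p1, b = p2))
  expect_equal(unname(bg$mean_profile[1:3]), c(10, 20, 30))
  expect_equal(sum(bg$aggregate_profile), sum(p1) + sum(p2))
  expect_equal(bg$mean_burden, 60)
  p3 <- mk_prof(c(40, 0, 20))
  bg2 <- fit_background(list(a = p1, b = p3))
  expect_equal(unname(bg2$mean_profile[1]), 25)
  expect_equal(sum(bg2$aggregate_profile), sum(p1) + sum(p3))
  expect_error(fit_background(list(a = p1)), "at least 2")
  expect_error(fit_background(list(a = p1, b = mk_prof(1, "ID29"))), "mix")
})

test_that("background recovery: fitted signature matches the truth on
           simulated controls", {
  g <- fx_genome_cal()
  profs <- fx_controls(g, n = 35, burden = 245, seed = 51)
  bg <- fit_background(profs)
  truth <- default_background_sbs()
  expect_gte(cosine(bg$signature, truth[names(bg$signature)]), 0.98)
  expect_lt(abs(bg$mean_burden - 245) / 245, 0.05)
})

test_that("SNR matches hand calculations and degenerate conventions", {
  ctrl <- cbind(a = c(100, 0), b = c(100, 0))
  tr_same <- ctrl
  expect_equal(snr(tr_same, ctrl), 0)

  tr <- cbind(x = c(100, 200), y = c(100, 200))
  s <- snr(tr, ctrl)
  expect_true(is.infinite(s))
  expect_true(isTRUE(attr(s, "degenerate")))

  ctrl2 <- cbind(a = c(98, 2), b = c(102, 2))
  tr2 <- cbind(x = c(100, 50), y = c(100, 58))
  # centroids (100,2) vs (100,54): signal 52; rms dispersions 2 and 4
  expect_equal(snr(tr2, ctrl2), 52 / 6)
  # per-channel alternative: sd vectors (sqrt(8),0) and (0,sqrt(32))
  expect_equal(snr(tr2, ctrl2, sigma = "per_channel"),
               52 / (sqrt(8) + sqrt(32)))
  expect_error(snr(tr2[, 1, drop = FALSE], ctrl2), "at least 2")
})

test_that("background subtraction recovers a clean excess exactly", {
  bg <- fit_background(list(a = mk_prof(c(100, 0)), b = mk_prof(c(100, 0))))
  tr <- cbind(x = c(100, 200), y = c(100, 200))
  rownames(tr) <- scheme_channels("SBS96")[1:2]
  m <- rbind(tr, matrix(0, 94, 2,
                        dimnames = list(scheme_channels("SBS96")[-(1:2)], NULL)))
  sig <- extract_signature(m, bg)
  expect_equal(unname(sig$probs[2]), 1)
  expect_equal(sig$clipped_mass, 0)
  expect_equal(sum(sig$probs), 1)
  expect_equal(sig$n_excess_mean, 200)
  # no excess -> error
  m2 <- m * 0; m2[1, ] <- 100
  expect_error(extract_signature(m2, bg), "no excess")
})

test_that("null treatments yield large clipped mass; injected signatures are
           recovered with high cosine", {
  g <- fx_genome_cal()
  profs <- fx_controls(g, n = 35, burden = 245, seed = 52)
  bgm <- fit_background(profs)
  truth <- fx_truth_sbs()
  set.seed(53)
  treat <- lapply(1:3, function(i) {
    id <- sprintf("t%d", i)
    m <- rbind(
      sample_mutations(g, default_background_sbs(), stats::rpois(1, 245),
                       sample = id),
      sample_mutations(g, truth, stats::rpois(1, 500), sample = id))
    build_profile(m, "SBS96", g, sample = id)
  })
  names(treat) <- sprintf("t%d", 1:3)
  sig <- extract_signature(treat, bgm)
  expect_gte(cosine(sig$probs, truth), 0.95)
  expect_lt(sig$clipped_mass, 0.15)

  # background-only "treatment": subtraction leaves mostly noise
  nullt <- lapply(1:3, function(i) {
    id <- sprintf("n%d", i)
    m <- sample_mutations(g, default_background_sbs(), 260, sample = id)
    build_profile(m, "SBS96", g, sample = id)
  })
  names(nullt) <- sprintf("n%d", 1:3)
  sig0 <- extract_signature(nullt, bgm)
  expect_gt(sig0$clipped_mass, sig$clipped_mass)
})

test_that("stability is the maximum pairwise cosine across subclones", {
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  expect_equal(stability(list(a, a)), 1.0)
  expect_equal(stability(list(a, b)), 0.0)
  # three subclones engineered to pairwise cosines 0.6, 0.9 (max) and lower
  s1 <- c(1, 0); s2 <- c(0.6, sqrt(1 - 0.36)); s3 <- c(0.9, sqrt(1 - 0.81))
  cs <- c(cosine(s1, s2), cosine(s1, s3), cosine(s2, s3))
  expect_equal(stability(list(s1, s2, s3)), max(cs))
  expect_true(is.na(stability(list(a))))
  expect_true(is.na(stability(list(a, NULL))))
})

test_that("gates implement the class-specific thresholds", {
  ok <- call_signature("t", "substitution", q = 0.001, snr = 3,
                       stability = 0.9)
  expect_true(ok$passes)
  low_snr <- call_signature("t", "substitution", q = 0.001, snr = 1.9,
                            stability = 0.95)
  expect_false(low_snr$passes)
  expect_false(low_snr$gate_trace[["snr_ge_min"]])
  expect_true(low_snr$gate_trace[["q_lt_max"]])

  ind <- call_signature("t", "indel", q = 0.001, snr = 3, stability = 0.75,
                        mean_burden = 19)
  expect_false(ind$passes)
  expect_false(ind$gate_trace[["mean_burden_ge_min"]])
  ind_ok <- call_signature("t", "indel", q = 0.001, snr = 3, stability = 0.75,
                           mean_burden = 25)
  expect_true(ind_ok$passes)
  # indel stability gate is 0.7, not 0.8
  expect_true(call_signature("t", "indel", q = 0.001, snr = 3,
                             stability = 0.72, mean_burden = 25)$passes)

  dbl <- call_signature("t", "doublet", q = 0.001, total_burden = 21)
  expect_true(dbl$passes)
  expect_false(call_signature("t", "doublet", q = 0.001,
                              total_burden = 20)$passes)
  # NA stability (single informative subclone) fails, flagged in the trace
  expect_false(call_signature("t", "substitution", q = 0.001, snr = 3,
                              stability = NA)$passes)
})
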
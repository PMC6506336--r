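## Genome-topography analyses: transcriptional strand asymmetry,
## replication-timing-domain distribution against a simulated expectation,
## and CpG enrichment.

SUB_CLASS_OF <- function(records, genome) {
  ## pyrimidine-collapsed substitution class per record
  ref <- records$ref; alt <- records$alt
  pyr <- ref %in% c("C", "T")
  ref[!pyr] <- chartr("ACGT", "TGCA", ref[!pyr])
  alt[!pyr] <- chartr("ACGT", "TGCA", alt[!pyr])
  paste0(ref, ">", alt)
}

#' Assign transcriptional strand status to substitutions
#'
#' For a substitution inside a gene footprint, the pyrimidine of the mutated
#' base pair lies either on the gene's coding (non-transcribed) strand or on
#' the template (transcribed) strand. Positions covered by genes on both
#' strands are ambiguous and excluded from the strand test; positions outside
#' any gene are intergenic.
#'
#' @param records substitution records.
#' @param genome a [toy_genome()] with a gene track.
#' @return character vector with levels `transcribed`, `non_transcribed`,
#'   `ambiguous`, `intergenic`.
#' @export
assign_tx_strand <- function(records, genome) {
  n <- nrow(records)
  out <- character(n)
  flat <- flat_id(genome, records$chrom, records$pos)
  g <- genome$flat_gene[flat]
  pyr_plus <- records$ref %in% c("C", "T")  # pyrimidine base is on + strand
  out[g == 0L] <- "intergenic"
  out[g == 3L] <- "ambiguous"
  plus_gene <- g == 1L
  minus_gene <- g == 2L
  ## pyrimidine on the gene's coding strand => non-transcribed
  out[(plus_gene & pyr_plus) | (minus_gene & !pyr_plus)] <- "non_transcribed"
  out[(plus_gene & !pyr_plus) | (minus_gene & pyr_plus)] <- "transcribed"
  out
}

#' Tally transcriptional strand status per substitution class
#'
#' @param records substitution records.
#' @param genome a [toy_genome()].
#' @return data.frame with one row per pyrimidine substitution class:
#'   transcribed, non_transcribed, excluded_ambiguous, intergenic.
#' @export
strand_tally <- function(records, genome) {
  cls <- SUB_CLASS_OF(records, genome)
  st <- assign_tx_strand(records, genome)
  f <- factor(cls, levels = SUB_CLASSES)
  data.frame(
    mutation_class = SUB_CLASSES,
    transcribed = as.integer(table(f[st == "transcribed"])),
    non_transcribed = as.integer(table(f[st == "non_transcribed"])),
    excluded_ambiguous = as.integer(table(f[st == "ambiguous"])),
    intergenic = as.integer(table(f[st == "intergenic"])),
    stringsAsFactors = FALSE)
}

#' Chi-square test of transcriptional strand asymmetry per class
#'
#' Pearson goodness-of-fit of (transcribed, non-transcribed) counts against
#' the symmetric 50:50 expectation, per substitution class, with BH
#' correction across the six classes. Classes with fewer than `min_total`
#' unambiguous genic mutations are skipped (NA, flagged).
#'
#' @param tallies data.frame from [strand_tally()].
#' @param min_total minimum unambiguous genic count for testing (default 5).
#' @return the tallies with added columns `tested`, `chisq`, `p`, `q` and
#'   significance `tier` (`""`, `"*"`, `"**"`, `"***"` at q <= 0.05, 0.01,
#'   0.001).
#' @export
strand_asymmetry_test <- function(tallies, min_total = 5L) {
  tot <- tallies$transcribed + tallies$non_transcribed
  tested <- tot >= min_total
  chisq <- p <- rep(NA_real_, nrow(tallies))
  for (i in which(tested)) {
    o <- c(tallies$transcribed[i], tallies$non_transcribed[i])
    e <- sum(o) / 2
    chisq[i] <- sum((o - e)^2 / e)
    p[i] <- stats::pchisq(chisq[i], df = 1, lower.tail = FALSE)
  }
  q <- rep(NA_real_, nrow(tallies))
  q[tested] <- adjust_pvalues(p[tested])
  tier <- ifelse(is.na(q), "",
                 ifelse(q <= 0.001, "***",
                        ifelse(q <= 0.01, "**", ifelse(q <= 0.05, "*", ""))))
  cbind(tallies, tested = tested, chisq = chisq, p = p, q = q, tier = tier,
        stringsAsFactors = FALSE)
}

## per-decile availability of the 32 trinucleotide classes
decile_availability <- function(genome) {
  out <- matrix(0, nrow = 10, ncol = 32)
  for (cn in genome$contigs) {
    c32 <- genome$ctx32[[cn]]
    d <- genome$decile[[cn]]
    ok <- !is.na(c32) & d > 0L
    idx <- (d[ok] - 1L) * 32L + c32[ok]
    out <- out + matrix(tabulate(idx, nbins = 320L), 10, 32, byrow = TRUE)
  }
  out
}

#' Replication-timing distribution of mutations vs simulated expectation
#'
#' Compares the observed counts of mutations per replication-timing decile
#' with the distribution expected from the signature profile and the
#' genome's per-decile trinucleotide availability, obtained by simulating
#' `n_sims` catalogs of equal size. The observed distribution is flagged as
#' different from the expectation via a Monte-Carlo chi-square test.
#'
#' @param records substitution records.
#' @param genome a [toy_genome()] with an RTD track covering all ten deciles.
#' @param signature SBS96 signature used for the expectation (e.g. the
#'   extracted treatment signature).
#' @param n_sims number of simulated catalogs (default 100).
#' @param seed optional seed.
#' @return object of class `rtd_distribution`: observed and expected decile
#'   counts, normalized densities, `p_mc` and `different` flag.
#' @export
rtd_analysis <- function(records, genome, signature, n_sims = 100L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genome$rtd)) stop("genome has no RTD track")
  avail <- decile_availability(genome)
  if (all(avail == 0)) stop("RTD track covers no genome positions")
  if (any(rowSums(avail) == 0))
    stop("decile(s) absent from the RTD track: ",
         paste(which(rowSums(avail) == 0), collapse = ", "))
  flat <- flat_id(genome, records$chrom, records$pos)
  d <- genome$flat_decile[flat]
  observed <- tabulate(d[d > 0L], nbins = 10L)
  n <- sum(observed)
  sig <- normalize_signature(signature, sbs96_channels())
  ctx <- parse_sbs_channels()$ctx
  p32 <- vapply(1:32, function(t) sum(sig[ctx == t]), numeric(1))
  ok <- p32 > 0 & colSums(avail) > 0
  p32 <- p32[ok] / sum(p32[ok])
  av <- avail[, ok, drop = FALSE]
  expected <- matrix(0L, nrow = n_sims, ncol = 10)
  for (s in seq_len(n_sims)) {
    kc <- stats::rmultinom(1, n, p32)
    dec <- integer(10)
    for (j in which(kc > 0L))
      dec <- dec + as.vector(stats::rmultinom(1, kc[j], av[, j]))
    expected[s, ] <- dec
  }
  m <- colMeans(expected)
  stat <- function(x) sum((x - m)^2 / pmax(m, 1e-9))
  obs_stat <- stat(observed)
  sim_stats <- apply(expected, 1, stat)
  p_mc <- (1 + sum(sim_stats >= obs_stat)) / (1 + n_sims)
  structure(list(observed = observed, expected = expected,
                 expected_mean = m,
                 density_observed = observed / sum(observed),
                 density_expected = m / sum(m),
                 n_sims = n_sims, p_mc = p_mc,
                 different = p_mc < 0.05),
            class = "rtd_distribution")
}

#' @export
print.rtd_distribution <- function(x, ...) {
  cat("rtd_distribution:", sum(x$observed), "mutations;",
      "MC p =", signif(x$p_mc, 3),
      if (x$different) "(different from expectation)" else "(consistent)", "\n")
  invisible(x)
}

#' CpG enrichment of mutations at G:C base pairs
#'
#' Fisher exact test on the 2x2 table of mutated vs eligible-unmutated G:C
#' sites inside vs outside the CpG track.
#'
#' @param records substitution records at G:C reference pairs (records with
#'   A/T reference are ignored).
#' @param genome a [toy_genome()] with a CpG track.
#' @return list with `table`, `odds_ratio`, `p`.
#' @export
cpg_enrichment <- function(records, genome) {
  if (is.null(genome$cpg) || nrow(genome$cpg) == 0L)
    stop("genome has no CpG track")
  gc_site <- genome$flat_base == 1L | genome$flat_base == 2L
  elig_cpg <- sum(gc_site & genome$flat_cpg)
  elig_non <- sum(gc_site & !genome$flat_cpg)
  keep <- records$ref %in% c("C", "G")
  flat <- flat_id(genome, records$chrom[keep], records$pos[keep])
  mut_cpg <- sum(genome$flat_cpg[flat])
  mut_non <- sum(!genome$flat_cpg[flat])
  tab <- matrix(c(mut_cpg, mut_non,
                  elig_cpg - mut_cpg, elig_non - mut_non), nrow = 2,
                dimnames = list(c("CpG", "nonCpG"),
                                c("mutated", "unmutated")))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Transcriptional strand asymmetry across replication-timing deciles
#'
#' Per-decile transcribed and non-transcribed counts for one substitution
#' class, with the asymmetry summarized as the transcribed fraction and a
#' gradient (mean asymmetry in early deciles 1-5 minus late deciles 6-10).
#'
#' @param records substitution records.
#' @param genome a [toy_genome()] with gene and RTD tracks.
#' @param mutation_class pyrimidine class to profile (default `"C>T"`); use
#'   `NULL` for all classes pooled.
#' @return list with `per_decile` (data.frame: decile, transcribed,
#'   non_transcribed, asymmetry) and `gradient`.
#' @export
strand_asymmetry_by_rtd <- function(records, genome, mutation_class = "C>T") {
  cls <- SUB_CLASS_OF(records, genome)
  keep <- if (is.null(mutation_class)) rep(TRUE, nrow(records))
          else cls == mutation_class
  rec <- records[keep, , drop = FALSE]
  st <- assign_tx_strand(rec, genome)
  flat <- flat_id(genome, rec$chrom, rec$pos)
  d <- genome$flat_decile[flat]
  tally <- function(status) tabulate(d[st == status & d > 0L], nbins = 10L)
  tx <- tally("transcribed"); ntx <- tally("non_transcribed")
  asym <- ifelse(tx + ntx > 0, tx / (tx + ntx), NA_real_)
  grad <- mean(asym[1:5], na.rm = TRUE) - mean(asym[6:10], na.rm = TRUE)
  list(per_decile = data.frame(decile = 1:10, transcribed = tx,
                               non_transcribed = ntx, asymmetry = asym),
       gradient = grad)
}
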
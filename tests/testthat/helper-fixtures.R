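# shared fixtures, built once per test run

.fx <- new.env()

# mid-size annotated genome used by sampling / extraction tests
fx_genome <- function() {
  if (is.null(.fx$g))
    .fx$g <- make_genome(60000, 0.45, n_genes = 8, seed = 101)
  .fx$g
}

# larger genome for calibration-style tests (long repeat tracts present)
fx_genome_cal <- function() {
  if (is.null(.fx$gc))
    .fx$gc <- make_genome(150000, 0.45, n_genes = 10, seed = 100)
  .fx$gc
}

tiny_genome <- function(seq, ...) toy_genome(c(chr1 = seq), ...)

# uniform signature restricted to trinucleotide classes present in a genome
present_uniform_sig <- function(genome) {
  info <- data.frame(channel = sbs96_channels())
  ctx <- paste0(substr(info$channel, 1, 1), substr(info$channel, 3, 3),
                substr(info$channel, 7, 7))
  present <- names(genome$trinuc_counts)[genome$trinuc_counts > 0]
  w <- as.numeric(ctx %in% present)
  stats::setNames(w / sum(w), info$channel)
}

# a sparse, moderately realistic treatment signature (T>A dominant)
fx_truth_sbs <- function() {
  s <- c("T[T>A]A" = 0.35, "C[T>A]T" = 0.25, "A[T>A]A" = 0.15,
         "G[T>A]C" = 0.10, "T[C>T]G" = 0.08, "A[C>G]G" = 0.07)
  full <- stats::setNames(numeric(96), sbs96_channels())
  full[names(s)] <- s
  full / sum(full)
}

# control SBS96 profiles + matrix + background model for a genome
fx_controls <- function(genome, n = 35, burden = 245, seed = 1) {
  set.seed(seed)
  profs <- lapply(seq_len(n), function(i) {
    id <- sprintf("c%02d", i)
    m <- sample_mutations(genome, default_background_sbs(),
                          stats::rpois(1, burden), sample = id)
    build_profile(m, "SBS96", genome, sample = id)
  })
  names(profs) <- sprintf("c%02d", seq_len(n))
  profs
}
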
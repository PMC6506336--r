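## Toy genome container
##
## Sequences are stored as plain character strings plus integer-coded copies;
## per-position annotation codes (trinucleotide class, gene strand, RTD decile,
## CpG flag) are precomputed once so that downstream classification, sampling
## and topography analyses are O(1) lookups.

base_to_int <- function(chars) {
  ## A=0, C=1, G=2, T=3; anything else NA
  m <- match(chars, BASES)
  m - 1L
}

seq_to_int <- function(seq) {
  base_to_int(strsplit(seq, "", fixed = TRUE)[[1]])
}

compute_ctx <- function(si) {
  L <- length(si)
  if (L < 3L) return(rep(NA_integer_, L))
  code <- rep(NA_integer_, L)
  i <- 2:(L - 1L)
  code[i] <- 16L * si[i - 1L] + 4L * si[i] + si[i + 1L] + 1L
  code
}

interval_code <- function(L, ivs, value_fun) {
  ## paints integer codes over [start,end] intervals (1-based inclusive)
  v <- integer(L)
  if (is.null(ivs) || nrow(ivs) == 0L) return(v)
  for (k in seq_len(nrow(ivs))) {
    idx <- ivs$start[k]:ivs$end[k]
    v[idx] <- value_fun(v[idx], k)
  }
  v
}

#' Construct a toy genome object
#'
#' Packages contig sequences with optional gene, replication-timing-decile
#' and CpG annotation tracks, precomputing per-position trinucleotide classes
#' and annotation codes, plus the 32 pyrimidine-centred trinucleotide counts.
#'
#' @param sequences named character vector, one DNA string per contig
#'   (A/C/G/T; N allowed and excluded from contexts).
#' @param genes data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates), or NULL.
#' @param rtd data.frame with columns `chrom`, `start`, `end`, `decile`
#'   (integer 1-10), or NULL.
#' @param cpg data.frame with columns `chrom`, `start`, `end`, or NULL.
#' @return an object of class `toy_genome`.
#' @export
toy_genome <- function(sequences, genes = NULL, rtd = NULL, cpg = NULL) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be a named character vector")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("sequences may contain only A, C, G, T, N")
  lens <- nchar(sequences)
  check_track <- function(tr, extra) {
    if (is.null(tr)) return(invisible(NULL))
    need <- c("chrom", "start", "end", extra)
    if (!all(need %in% names(tr)))
      stop("track is missing columns: ", paste(setdiff(need, names(tr)), collapse = ", "))
    if (!all(tr$chrom %in% names(sequences))) stop("track refers to unknown contig")
    if (any(tr$start < 1L) || any(tr$end > lens[tr$chrom]))
      stop("track interval outside contig bounds")
    if (any(tr$start > tr$end)) stop("track interval with start > end")
    invisible(NULL)
  }
  check_track(genes, "strand")
  check_track(rtd, "decile")
  check_track(cpg, character(0))
  if (!is.null(genes) && !all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")

  contigs <- names(sequences)
  seq_int <- lapply(sequences, seq_to_int)
  ctx <- lapply(seq_int, compute_ctx)
  map32 <- trinuc64_to32()
  ctx32 <- lapply(ctx, function(x) map32[x])

  per_contig_track <- function(tr) {
    if (is.null(tr)) return(NULL)
    split(tr, factor(tr$chrom, levels = contigs))
  }
  g_by <- per_contig_track(genes)
  r_by <- per_contig_track(rtd)
  c_by <- per_contig_track(cpg)

  gene_code <- lapply(contigs, function(cn) {
    ivs <- g_by[[cn]]
    L <- lens[[cn]]
    if (is.null(ivs) || nrow(ivs) == 0L) return(integer(L))
    v <- integer(L)
    for (k in seq_len(nrow(ivs))) {
      idx <- ivs$start[k]:ivs$end[k]
      sc <- if (ivs$strand[k] == "+") 1L else 2L
      cur <- v[idx]
      v[idx] <- ifelse(cur == 0L, sc, ifelse(cur == sc, sc, 3L))
    }
    v
  })
  names(gene_code) <- contigs
  decile <- lapply(contigs, function(cn) {
    ivs <- r_by[[cn]]
    L <- lens[[cn]]
    v <- integer(L)
    if (!is.null(ivs) && nrow(ivs) > 0L)
      for (k in seq_len(nrow(ivs))) v[ivs$start[k]:ivs$end[k]] <- ivs$decile[k]
    v
  })
  names(decile) <- contigs
  cpg_flag <- lapply(contigs, function(cn) {
    ivs <- c_by[[cn]]
    L <- lens[[cn]]
    v <- logical(L)
    if (!is.null(ivs) && nrow(ivs) > 0L)
      for (k in seq_len(nrow(ivs))) v[ivs$start[k]:ivs$end[k]] <- TRUE
    v
  })
  names(cpg_flag) <- contigs

  offsets <- cumsum(c(0L, unname(lens[-length(lens)])))
  names(offsets) <- contigs
  all32 <- unlist(ctx32, use.names = FALSE)
  counts <- tabulate(all32, nbins = 32L)
  names(counts) <- trinuc32_names()
  sites_by_ctx <- split(seq_along(all32), factor(all32, levels = 1:32))

  structure(list(
    sequences = sequences,
    genes = genes, rtd = rtd, cpg = cpg,
    contigs = contigs, lengths = lens, offsets = offsets,
    seq_int = seq_int, ctx32 = ctx32,
    gene_code = gene_code, decile = decile, cpg_flag = cpg_flag,
    trinuc_counts = counts,
    sites_by_ctx = sites_by_ctx,
    flat_gene = unlist(gene_code, use.names = FALSE),
    flat_decile = unlist(decile, use.names = FALSE),
    flat_cpg = unlist(cpg_flag, use.names = FALSE),
    flat_base = unlist(seq_int, use.names = FALSE),
    flat_pyr = unlist(lapply(seq_int, function(s) s == 1L | s == 3L),
                      use.names = FALSE),
    runs = lapply(seq_int, function(si) {
      r <- rle(si)
      ends <- cumsum(r$lengths)
      list(len = rep(r$lengths, r$lengths),
           start = rep(ends - r$lengths + 1L, r$lengths),
           end = rep(ends, r$lengths))
    })
  ), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$contigs), "contig(s),",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  cat("  genes:", if (is.null(x$genes)) 0L else nrow(x$genes),
      " RTD intervals:", if (is.null(x$rtd)) 0L else nrow(x$rtd),
      " CpG intervals:", if (is.null(x$cpg)) 0L else nrow(x$cpg), "\n")
  invisible(x)
}

## flat-id <-> (chrom, pos) helpers
flat_id <- function(genome, chrom, pos) {
  genome$offsets[chrom] + pos
}
flat_to_pos <- function(genome, id) {
  ci <- findInterval(id, cumsum(genome$lengths) - genome$lengths + 1L)
  chrom <- genome$contigs[ci]
  list(chrom = chrom, pos = as.integer(id - genome$offsets[chrom]))
}

genome_base <- function(genome, chrom, pos) {
  ## vectorized base lookup returning characters
  out <- character(length(pos))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    out[i] <- BASES[genome$seq_int[[cn]][pos[i]] + 1L]
  }
  out
}

genome_substr <- function(genome, chrom, start, end) {
  substr(genome$sequences[[chrom]], start, end)
}

#' Generate a random toy genome with annotation tracks
#'
#' Draws an i.i.d. base sequence at the requested GC fraction, places
#' `n_genes` non-overlapping gene footprints on random strands, tiles the
#' contig into ten equal-width replication-timing deciles (labels assigned in
#' shuffled order), and marks CG-dense windows as CpG intervals (windows whose
#' CG-dinucleotide count reaches the 95th percentile across windows).
#'
#' @param length contig length in bases (>= 1000).
#' @param gc_fraction GC content in (0, 1).
#' @param n_genes number of gene footprints to place.
#' @param seed integer seed; the genome is deterministic given the seed.
#' @param contig contig name.
#' @param gene_fraction approximate fraction of the contig covered by gene
#'   footprints; individual gene lengths vary around `gene_fraction * length
#'   / n_genes` by +/- 50 percent.
#' @param cpg_window window size (bp) used to detect CG-dense intervals.
#' @return a `toy_genome`.
#' @examples
#' g <- make_genome(10000, 0.5, n_genes = 5, seed = 1)
#' sum(g$trinuc_counts) == 10000 - 2
#' @export
make_genome <- function(length, gc_fraction, n_genes, seed,
                        contig = "chr1",
                        gene_fraction = 0.35,
                        cpg_window = 100L) {
  if (length < 1000L) stop("genome length must be at least 1000 bp")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly between 0 and 1")
  set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  seq <- paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")

  genes <- NULL
  if (n_genes > 0L) {
    mean_len <- gene_fraction * length / n_genes
    lens <- pmax(10L, round(stats::runif(n_genes, 0.5, 1.5) * mean_len))
    free <- length - sum(lens)
    if (free < n_genes)
      stop("genome length too small to host ", n_genes, " genes")
    gaps <- diff(c(0L, sort(sample.int(free, n_genes))))
    starts <- cumsum(gaps) + cumsum(c(0L, lens[-n_genes])) + 1L
    ## shift so genes start after the gap preceding them
    starts <- as.integer(starts)
    genes <- data.frame(chrom = contig, start = starts,
                        end = as.integer(starts + lens - 1L),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
  }

  width <- floor(length / 10)
  starts <- (0:9) * width + 1L
  ends <- c(starts[-1] - 1L, length)
  rtd <- data.frame(chrom = contig, start = as.integer(starts),
                    end = as.integer(ends),
                    decile = sample(1:10), stringsAsFactors = FALSE)

  ## CG-dense windows
  si <- seq_to_int(seq)
  is_cg <- si[-length(si)] == 1L & si[-1] == 2L
  nwin <- floor(length / cpg_window)
  win_id <- rep(seq_len(nwin), each = cpg_window)[seq_along(is_cg)]
  keep <- !is.na(win_id)
  counts <- tapply(is_cg[keep], win_id[keep], sum)
  thr <- max(1, stats::quantile(counts, 0.95, type = 1, names = FALSE))
  dense <- which(counts >= thr)
  cpg <- NULL
  if (length(dense) > 0L) {
    st <- (dense - 1L) * cpg_window + 1L
    en <- pmin(dense * cpg_window, length)
    ## merge adjacent windows
    brk <- c(TRUE, diff(dense) > 1L)
    grp <- cumsum(brk)
    cpg <- data.frame(chrom = contig,
                      start = as.integer(tapply(st, grp, min)),
                      end = as.integer(tapply(en, grp, max)),
                      stringsAsFactors = FALSE)
  }
  names(seq) <- contig
  toy_genome(seq, genes = genes, rtd = rtd, cpg = cpg)
}
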
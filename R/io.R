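## On-disk interchange: FASTA genome, BED annotation tracks (0-based
## half-open, converted on read/write), TSV profile and signature matrices.

#' Write a toy genome as FASTA plus BED annotation tracks
#'
#' @param genome a [toy_genome()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  if (!is.null(genome$genes)) {
    g <- genome$genes
    out <- data.frame(chrom = g$chrom, start = g$start - 1L, end = g$end,
                      name = sprintf("gene%03d", seq_len(nrow(g))),
                      score = 0L, strand = g$strand)
    utils::write.table(out, file.path(dir, "genes.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(genome$rtd)) {
    r <- genome$rtd
    out <- data.frame(chrom = r$chrom, start = r$start - 1L, end = r$end,
                      name = r$decile)
    utils::write.table(out, file.path(dir, "rtd.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(genome$cpg)) {
    c <- genome$cpg
    out <- data.frame(chrom = c$chrom, start = c$start - 1L, end = c$end)
    utils::write.table(out, file.path(dir, "cpg.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

read_bed <- function(path, extra = character(0)) {
  if (!file.exists(path)) return(NULL)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$start <- tab$start + 1L  # BED is 0-based half-open
  if (length(extra)) names(tab)[3 + seq_along(extra)] <- extra
  tab
}

#' Read a toy genome written by [write_genome()]
#'
#' @param dir directory containing `genome.fa` and optional BED tracks.
#' @return a [toy_genome()].
#' @export
read_genome <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genes <- read_bed(file.path(dir, "genes.bed"), c("name", "score", "strand"))
  if (!is.null(genes)) genes <- genes[, c("chrom", "start", "end", "strand")]
  rtd <- read_bed(file.path(dir, "rtd.bed"), "decile")
  if (!is.null(rtd)) {
    rtd$decile <- as.integer(rtd$decile)
    rtd <- rtd[, c("chrom", "start", "end", "decile")]
  }
  cpg <- read_bed(file.path(dir, "cpg.bed"))
  if (!is.null(cpg)) cpg <- cpg[, c("chrom", "start", "end")]
  toy_genome(seqs, genes = genes, rtd = rtd, cpg = cpg)
}

#' Write a channels-by-signatures matrix as TSV
#'
#' First column `channel` carries the channel labels; remaining columns are
#' named signatures.
#'
#' @param m numeric matrix with channel rownames.
#' @param path output path.
#' @export
write_signature_matrix <- function(m, path) {
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a channels-by-signatures TSV (COSMIC-style)
#'
#' @param path TSV with a channel-label column (named `channel`, `Type` or
#'   the first column) and one named column per signature.
#' @return numeric matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab_col <- intersect(c("channel", "Type", "MutationType"), names(tab))
  lab_col <- if (length(lab_col)) lab_col[1] else names(tab)[1]
  m <- as.matrix(tab[, setdiff(names(tab), lab_col), drop = FALSE])
  rownames(m) <- tab[[lab_col]]
  storage.mode(m) <- "double"
  m
}
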
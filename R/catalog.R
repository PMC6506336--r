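## Catalog ingestion and the post-calling filters

CATALOG_COLS <- c("chrom", "pos", "ref", "alt", "vaf", "sample")

empty_catalog <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vaf = numeric(0), sample = character(0),
             stringsAsFactors = FALSE)
}

sort_catalog <- function(records) {
  records[order(records$chrom, records$pos, records$ref, records$alt), ,
          drop = FALSE]
}

#' Load a per-subclone mutation catalog
#'
#' Reads a TSV catalog (columns `chrom`, `pos`, `ref`, `alt`, `vaf`, optional
#' `sample`) or a VCF v4.x file. Multi-allelic VCF lines are split into one
#' record per alternate allele. Malformed rows are dropped with a message
#' giving the count. Records are returned sorted by (chrom, pos).
#'
#' @param path path to the catalog file.
#' @param sample sample id to assign (overrides any column in the file).
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param vaf_field for VCF input, the INFO or FORMAT key carrying the
#'   variant allele fraction.
#' @return data.frame of mutation records.
#' @export
load_catalog <- function(path, sample = NULL,
                         format = c("auto", "tsv", "vcf"),
                         vaf_field = "VAF") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  rec <- if (format == "vcf") {
    load_catalog_vcf(path, vaf_field)
  } else {
    load_catalog_tsv(path)
  }
  if (!is.null(sample)) rec$sample <- rep(sample, nrow(rec))
  if (is.null(rec$sample)) rec$sample <- rep(NA_character_, nrow(rec))
  sort_catalog(rec[, CATALOG_COLS])
}

load_catalog_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "vaf")
  if (!all(need %in% names(tab))) {
    stop("unrecognized catalog format in ", path, ": missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (nrow(tab) == 0L) return(empty_catalog())
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  tab$vaf <- suppressWarnings(as.numeric(tab$vaf))
  ok <- !is.na(tab$pos) & tab$pos >= 1L &
    grepl("^[ACGTN]+$", tab$ref) & grepl("^[ACGTN]+$", tab$alt) &
    tab$ref != tab$alt
  if (any(!ok))
    message(sum(!ok), " malformed row(s) rejected from ", basename(path))
  tab <- tab[ok, , drop = FALSE]
  if (is.null(tab$sample)) tab$sample <- NA_character_
  tab
}

load_catalog_vcf <- function(path, vaf_field = "VAF") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_catalog())
  vaf <- rep(NA_real_, nrow(fix))
  info <- vcfR::extract.info(v, element = vaf_field, as.numeric = TRUE)
  if (!all(is.na(info))) {
    vaf <- info
  } else if (ncol(v@gt) >= 2L) {
    g <- vcfR::extract.gt(v, element = vaf_field, as.numeric = TRUE)
    if (!is.null(g)) vaf <- as.numeric(g[, 1])
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  data.frame(chrom = fix$CHROM[idx],
             pos = as.integer(fix$POS[idx]),
             ref = fix$REF[idx],
             alt = unlist(alts),
             vaf = vaf[idx],
             sample = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a mutation catalog as TSV
#'
#' @param records data.frame of mutation records.
#' @param path output path.
#' @export
write_catalog <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter records on variant allele fraction
#'
#' Keeps records with `vaf >= threshold` (the post-calling filter applied to
#' substitutions and indels). Record order is preserved.
#'
#' @param records data.frame of mutation records with a `vaf` column.
#' @param threshold minimum VAF retained (default 0.2).
#' @return filtered data.frame.
#' @export
filter_vaf <- function(records, threshold = 0.2) {
  if (is.null(records$vaf) || anyNA(records$vaf))
    stop("filter_vaf: all records must carry a VAF")
  records[records$vaf >= threshold, , drop = FALSE]
}

#' Remove mutations shared among subclones of one parental culture
#'
#' A mutation (chrom, pos, ref, alt) present in two or more subclones is a
#' pre-existing (parental) event, not a de novo mutation, and is removed from
#' every subclone in which it occurs.
#'
#' @param subclone_sets named list of record data.frames, one per subclone of
#'   a single parental culture.
#' @return named list of the same shape with shared mutations removed.
#' @export
remove_shared <- function(subclone_sets) {
  if (length(subclone_sets) < 2L) {
    warning("remove_shared: single subclone, nothing to compare; passing through")
    return(subclone_sets)
  }
  keys <- lapply(subclone_sets, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"))
  tab <- table(unlist(lapply(keys, unique)))
  shared <- names(tab)[tab >= 2L]
  mapply(function(r, k) r[!(k %in% shared), , drop = FALSE],
         subclone_sets, keys, SIMPLIFY = FALSE)
}

#' Detect adjacent double substitutions
#'
#' Pairs of substitutions at adjacent positions on one contig are merged into
#' doublet records and removed from the single-substitution set. Runs of
#' three or more adjacent substitutions are excluded from both outputs and
#' returned separately as multi-substitution events.
#'
#' @param records data.frame of single-base substitution records for one
#'   sample.
#' @return list with elements `doublets` (data.frame: `chrom`, `pos` of the
#'   5' base, `ref_dinuc`, `alt_dinuc`, `sample`), `singles` (the remaining
#'   substitution records) and `excluded` (records in runs of >= 3).
#' @export
detect_doublets <- function(records) {
  if (!all(is_substitution(records)))
    stop("detect_doublets expects single-base substitutions only")
  records <- sort_catalog(records)
  n <- nrow(records)
  if (n == 0L)
    return(list(doublets = data.frame(chrom = character(0), pos = integer(0),
                                      ref_dinuc = character(0),
                                      alt_dinuc = character(0),
                                      sample = character(0)),
                singles = records, excluded = records))
  adjacent <- c(FALSE, records$chrom[-1] == records$chrom[-n] &
                  records$pos[-1] == records$pos[-n] + 1L)
  run_id <- cumsum(!adjacent)
  run_len <- ave(run_id, run_id, FUN = length)
  singles <- records[run_len == 1L, , drop = FALSE]
  excluded <- records[run_len >= 3L, , drop = FALSE]
  pairs <- records[run_len == 2L, , drop = FALSE]
  if (nrow(pairs) > 0L) {
    first <- seq(1L, nrow(pairs), by = 2L)
    doublets <- data.frame(
      chrom = pairs$chrom[first],
      pos = pairs$pos[first],
      ref_dinuc = paste0(pairs$ref[first], pairs$ref[first + 1L]),
      alt_dinuc = paste0(pairs$alt[first], pairs$alt[first + 1L]),
      sample = pairs$sample[first],
      stringsAsFactors = FALSE)
  } else {
    doublets <- data.frame(chrom = character(0), pos = integer(0),
                           ref_dinuc = character(0), alt_dinuc = character(0),
                           sample = character(0))
  }
  list(doublets = doublets, singles = singles, excluded = excluded)
}
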
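## Mutation classification into channel schemes

is_substitution <- function(records) {
  nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref != records$alt
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Substitutions are collapsed to the pyrimidine strand: a mutation whose
#' reference base is a purine is represented by the reverse complement of its
#' full reference triplet. Records whose flanking context is unavailable
#' (contig edge or N) get NA and are counted as excluded.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genome a [toy_genome()] providing flanking context.
#' @return character vector of channel labels (NA where excluded), with
#'   attribute `excluded` giving the number of NA results.
#' @export
classify_sbs <- function(records, genome) {
  n <- nrow(records)
  out <- rep(NA_character_, n)
  if (n == 0L) return(structure(out, excluded = 0L))
  if (!all(is_substitution(records)))
    stop("classify_sbs expects single-base substitutions only")
  tri32 <- trinuc32_names()
  for (cn in unique(records$chrom)) {
    i <- which(records$chrom == cn)
    pos <- records$pos[i]
    si <- genome$seq_int[[cn]]
    if (any(pos < 1L | pos > length(si))) stop("position outside contig ", cn)
    gref <- BASES[si[pos] + 1L]
    if (any(gref != records$ref[i], na.rm = TRUE))
      stop("reference allele mismatch with genome on contig ", cn)
    c32 <- genome$ctx32[[cn]][pos]
    ok <- !is.na(c32)
    pyr <- records$ref[i] %in% c("C", "T")
    alt <- records$alt[i]
    alt[!pyr] <- chartr("ACGT", "TGCA", alt[!pyr])
    ref_c <- ifelse(pyr, records$ref[i], chartr("ACGT", "TGCA", records$ref[i]))
    tri <- tri32[c32]
    out[i[ok]] <- sprintf("%s[%s>%s]%s",
                          substr(tri[ok], 1, 1), ref_c[ok], alt[ok],
                          substr(tri[ok], 3, 3))
  }
  structure(out, excluded = sum(is.na(out)))
}

#' Classify double substitutions into DBS78 channels
#'
#' @param doublets data.frame with columns `ref_dinuc`, `alt_dinuc`
#'   (as produced by [detect_doublets()]).
#' @return character vector of canonical channel labels.
#' @export
classify_dbs <- function(doublets) {
  if (nrow(doublets) == 0L) return(character(0))
  canonical_dbs(doublets$ref_dinuc, doublets$alt_dinuc)
}

## longest k < len such that the first k bases following the deleted motif
## match the motif prefix, or the k bases preceding it match the motif suffix
mh_length <- function(seq, s, e, motif) {
  len <- nchar(motif)
  L <- nchar(seq)
  best <- 0L
  for (k in seq_len(len - 1L)) {
    if (e + k <= L && substr(seq, e + 1L, e + k) == substr(motif, 1L, k))
      best <- max(best, k)
    if (s - k >= 1L && substr(seq, s - k, s - 1L) == substr(motif, len - k + 1L, len))
      best <- max(best, k)
  }
  best
}

classify_indel_one <- function(seq, L, pos, ref, alt) {
  ## strip common prefix then common suffix (VCF-anchored or raw dialects)
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L); alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  if (nchar(ref) > 0L && nchar(alt) > 0L)
    return(list(channel = NA_character_, reason = "complex"))
  if (nchar(ref) == 0L && nchar(alt) == 0L)
    return(list(channel = NA_character_, reason = "empty"))

  if (nchar(alt) == 0L) {          # deletion of ref at [pos, pos+len-1]
    motif <- ref; len <- nchar(motif)
    s <- pos; e <- pos + len - 1L
    if (s < 1L || e > L) return(list(channel = NA_character_, reason = "edge"))
    if (substr(seq, s, e) != motif)
      stop("deleted motif does not match the reference sequence")
    ## left-align
    while (s > 1L && substr(seq, s - 1L, s - 1L) == substr(seq, e, e)) {
      s <- s - 1L; e <- e - 1L
    }
    motif <- substr(seq, s, e)
    if (s == 1L || e == L) return(list(channel = NA_character_, reason = "edge"))
    copies <- 1L
    j <- s - len
    while (j >= 1L && substr(seq, j, j + len - 1L) == motif) {
      copies <- copies + 1L; j <- j - len
    }
    j <- e + 1L
    while (j + len - 1L <= L && substr(seq, j, j + len - 1L) == motif) {
      copies <- copies + 1L; j <- j + len
    }
    if (len == 1L) {
      b <- if (motif %in% c("C", "G")) "C" else "T"
      return(list(channel = sprintf("del:1bp:%s:%s", b, tract_bin(copies)),
                  reason = NA_character_))
    }
    lc <- len_cat(len)
    if (copies >= 2L)
      return(list(channel = sprintf("del:%s:rep", lc), reason = NA_character_))
    if (mh_length(seq, s, e, motif) >= 1L)
      return(list(channel = "del:MH", reason = NA_character_))
    return(list(channel = sprintf("del:%s:norep", lc), reason = NA_character_))
  }

  ## insertion of alt before position pos
  motif <- alt; len <- nchar(motif)
  s <- pos
  if (s < 2L || s > L) return(list(channel = NA_character_, reason = "edge"))
  ## left-align: inserting m before s == inserting rot(m) before s-1
  ## when the last motif base equals the base at s-1
  while (s > 2L && substr(motif, len, len) == substr(seq, s - 1L, s - 1L)) {
    motif <- paste0(substr(seq, s - 1L, s - 1L), substr(motif, 1L, len - 1L))
    s <- s - 1L
  }
  copies <- 0L
  j <- s - len
  while (j >= 1L && substr(seq, j, j + len - 1L) == motif) {
    copies <- copies + 1L; j <- j - len
  }
  j <- s
  while (j + len - 1L <= L && substr(seq, j, j + len - 1L) == motif) {
    copies <- copies + 1L; j <- j + len
  }
  if (len == 1L) {
    b <- if (motif %in% c("C", "G")) "C" else "T"
    return(list(channel = sprintf("ins:1bp:%s:%s", b, tract_bin(copies)),
                reason = NA_character_))
  }
  lc <- len_cat(len)
  list(channel = sprintf("ins:%s:%s", lc, if (copies >= 1L) "rep" else "norep"),
       reason = NA_character_)
}

tract_bin <- function(copies) {
  if (copies <= 0L) "0" else if (copies <= 2L) "1-2"
  else if (copies <= 4L) "3-4" else "5+"
}
len_cat <- function(len) {
  if (len == 2L) "2bp" else if (len == 3L) "3bp" else "4bp+"
}

#' Classify insertions and deletions into the 29-channel indel scheme
#'
#' Indels are left-aligned against the reference before classification, so the
#' assigned channel is invariant to the caller's normalization. See
#' [id29_channels()] for the schema. Indels spanning a contig edge and complex
#' substitutions are excluded with a reason.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF-style anchored alleles or raw alleles both accepted).
#' @param genome a [toy_genome()].
#' @return character vector of channel labels (NA where excluded) with
#'   attributes `excluded` (count) and `reasons`.
#' @export
classify_indel <- function(records, genome) {
  n <- nrow(records)
  out <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cn <- records$chrom[i]
    seq <- genome$sequences[[cn]]
    if (is.null(seq)) stop("unknown contig: ", cn)
    r <- classify_indel_one(seq, nchar(seq), records$pos[i],
                            records$ref[i], records$alt[i])
    out[i] <- r$channel
    reasons[i] <- r$reason
  }
  structure(out, excluded = sum(is.na(out)), reasons = reasons)
}

#' Build a count profile over a channel scheme
#'
#' Classifies the records of the matching mutation class and tabulates them
#' over all channels of the scheme. The profile total plus the number of
#' excluded records equals the number of input records.
#'
#' @param records for `SBS96`/`ID29`, a data.frame of mutation records; for
#'   `DBS78`, a data.frame of doublet records from [detect_doublets()].
#' @param scheme one of `"SBS96"`, `"DBS78"`, `"ID29"`.
#' @param genome a [toy_genome()] (not needed for `DBS78`).
#' @param sample optional sample id stored as an attribute.
#' @return named integer vector over the scheme's channels, with attributes
#'   `scheme`, `sample` and `excluded`.
#' @export
build_profile <- function(records, scheme = c("SBS96", "DBS78", "ID29"),
                          genome = NULL, sample = NULL) {
  scheme <- match.arg(scheme)
  channels <- scheme_channels(scheme)
  ch <- switch(scheme,
               SBS96 = classify_sbs(records, genome),
               DBS78 = classify_dbs(records),
               ID29  = classify_indel(records, genome))
  counts <- table(factor(ch, levels = channels))
  out <- as.integer(counts)
  names(out) <- channels
  structure(out, scheme = scheme, sample = sample,
            excluded = sum(is.na(ch)))
}

#' Stack per-sample profiles into a channels-by-samples matrix
#'
#' @param profiles named list of profiles from [build_profile()], all of one
#'   scheme.
#' @return integer matrix (channels x samples) with attribute `scheme`.
#' @export
profile_matrix <- function(profiles) {
  schemes <- unique(vapply(profiles, function(p) attr(p, "scheme"), character(1)))
  if (length(schemes) != 1L) stop("profiles mix channel schemes")
  m <- do.call(cbind, lapply(profiles, as.integer))
  rownames(m) <- names(profiles[[1]])
  colnames(m) <- names(profiles)
  structure(m, scheme = schemes)
}
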
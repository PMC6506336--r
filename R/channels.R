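BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement for plain character DNA (A/C/G/T only).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACG", "TTAA"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Single-base substitution channel scheme (96 channels)
#'
#' Channels are the 6 pyrimidine-collapsed substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 4 possible 5' and
#' 4 possible 3' flanking bases, labelled in the conventional
#' `"A[C>A]A"` form and ordered substitution-major.
#'
#' @return character vector of 96 channel labels.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (sub in SUB_CLASSES)
    for (f in BASES)
      for (t in BASES)
        out <- c(out, sprintf("%s[%s]%s", f, sub, t))
  out
}

## Canonical reference dinucleotides for the 78-class doublet scheme.
## The four reverse-complement-palindromic references (AT, CG, GC, TA)
## additionally canonicalize their alt by lexicographic minimum.
DBS_CANON_REF <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
DBS_PALINDROMIC_REF <- c("AT", "CG", "GC", "TA")

#' Canonicalize a double-substitution type
#'
#' Maps a (reference dinucleotide, alternate dinucleotide) pair, both bases
#' changed, onto its canonical representative in the 78-class doublet scheme.
#' A pair whose reference is not among the canonical set is replaced by the
#' reverse complement of both dinucleotides; for reverse-complement-palindromic
#' references the lexicographically smaller of alt and its reverse complement
#' is used.
#'
#' @param ref,alt character vectors of dinucleotides (both positions must
#'   differ between `ref` and `alt`).
#' @return character vector of canonical labels of the form `"CT>AA"`.
#' @examples
#' canonical_dbs("AG", "TT")  # "CT>AA"
#' canonical_dbs("CC", "TT")  # "CC>TT"
#' @export
canonical_dbs <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(alt) != length(ref)) stop("ref and alt must have equal length")
  bad <- nchar(ref) != 2L | nchar(alt) != 2L
  if (any(bad)) stop("ref and alt must be dinucleotides")
  r1 <- substr(ref, 1, 1); r2 <- substr(ref, 2, 2)
  a1 <- substr(alt, 1, 1); a2 <- substr(alt, 2, 2)
  if (any(r1 == a1 | r2 == a2))
    stop("not a double substitution: both bases must change")
  flip <- !(ref %in% DBS_CANON_REF)
  ref[flip] <- revcomp(ref[flip])
  alt[flip] <- revcomp(alt[flip])
  pal <- ref %in% DBS_PALINDROMIC_REF
  if (any(pal)) {
    rc_alt <- revcomp(alt[pal])
    alt[pal] <- pmin(alt[pal], rc_alt)
  }
  paste0(ref, ">", alt)
}

#' Double-substitution channel scheme (78 channels)
#'
#' All 16 reference dinucleotides with both bases substituted give
#' 144 raw types; collapsing reverse-complement pairs (12 of which are
#' fixed points) leaves 78 canonical classes.
#'
#' @return character vector of 78 channel labels (e.g. `"CC>TT"`).
#' @export
dbs78_channels <- function() {
  refs <- as.vector(outer(BASES, BASES, paste0))
  out <- character(0)
  for (r in refs) {
    for (x in BASES) for (y in BASES) {
      a <- paste0(x, y)
      if (x != substr(r, 1, 1) && y != substr(r, 2, 2))
        out <- c(out, canonical_dbs(r, a))
    }
  }
  sort(unique(out))
}

#' Indel channel scheme (29 channels)
#'
#' Indels are classified by class (deletion vs insertion), motif size and,
#' for 1-bp events, pyrimidine-collapsed base (C or T) and the length of the
#' same-base repeat tract at the site; multi-bp events by motif length
#' (2, 3, >=4 bp) and whether the motif sits in a flanking repeat; plus a
#' single microhomology-mediated deletion category. Tract length counts the
#' total copies of the motif in the reference tract (the deleted copy
#' included for deletions, existing copies only for insertions), binned as
#' 0, 1-2, 3-4, >=5.
#'
#' @return data.frame with columns `channel`, `class` (`del`/`ins`),
#'   `subtype` and `tract`, one row per channel, in canonical order.
#' @export
id29_channels <- function() {
  tract_bins <- c("0", "1-2", "3-4", "5+")
  rows <- list()
  for (cls in c("del", "ins"))
    for (b in c("C", "T"))
      for (tr in tract_bins)
        rows[[length(rows) + 1L]] <-
          data.frame(channel = sprintf("%s:1bp:%s:%s", cls, b, tr),
                     class = cls, subtype = paste0("1bp_", b), tract = tr)
  for (cls in c("del", "ins"))
    for (len in c("2bp", "3bp", "4bp+"))
      for (rep in c("norep", "rep"))
        rows[[length(rows) + 1L]] <-
          data.frame(channel = sprintf("%s:%s:%s", cls, len, rep),
                     class = cls, subtype = len, tract = rep)
  rows[[length(rows) + 1L]] <-
    data.frame(channel = "del:MH", class = "del", subtype = "MH", tract = "MH")
  do.call(rbind, rows)
}

#' Channel labels for a scheme
#'
#' @param scheme one of `"SBS96"`, `"DBS78"`, `"ID29"`.
#' @return character vector of channel labels in canonical order.
#' @export
scheme_channels <- function(scheme = c("SBS96", "DBS78", "ID29")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         SBS96 = sbs96_channels(),
         DBS78 = dbs78_channels(),
         ID29  = id29_channels()$channel)
}

## 32 pyrimidine-centred trinucleotides, ordered 5' base, centre (C then T),
## 3' base -- the context marginal used for genome availability bookkeeping.
trinuc32_names <- function() {
  out <- character(0)
  for (f in BASES)
    for (c in c("C", "T"))
      for (t in BASES)
        out <- c(out, paste0(f, c, t))
  out
}

## Map from a raw trinucleotide (64 codes, 0-based code = 16*b5 + 4*b0 + b3
## with A=0,C=1,G=2,T=3) to the index 1..32 of its pyrimidine-collapsed class.
trinuc64_to32 <- function() {
  tri64 <- character(64)
  k <- 1L
  for (f in BASES) for (c in BASES) for (t in BASES) {
    tri64[k] <- paste0(f, c, t); k <- k + 1L
  }
  collapsed <- ifelse(substr(tri64, 2, 2) %in% c("C", "T"),
                      tri64, revcomp(tri64))
  match(collapsed, trinuc32_names())
}
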
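## Synthetic-data generation: signatures with known truth, placed on a toy
## genome so that every downstream stage is testable without external data.

normalize_signature <- function(x, channels) {
  if (is.null(names(x))) {
    if (length(x) != length(channels))
      stop("unnamed signature must have length ", length(channels))
    names(x) <- channels
  }
  if (!all(names(x) %in% channels))
    stop("unknown channel label(s): ",
         paste(utils::head(setdiff(names(x), channels), 5), collapse = ", "))
  full <- stats::setNames(numeric(length(channels)), channels)
  full[names(x)] <- x
  if (any(full < 0)) stop("signature probabilities must be non-negative")
  s <- sum(full)
  if (s <= 0) stop("signature has zero total mass")
  full / s
}

parse_sbs_channels <- function() {
  ch <- sbs96_channels()
  f <- substr(ch, 1, 1)
  ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5)
  t <- substr(ch, 7, 7)
  ctx <- match(paste0(f, ref, t), trinuc32_names())
  data.frame(channel = ch, five = f, ref = ref, alt = alt, three = t,
             ctx = ctx, stringsAsFactors = FALSE)
}

draw_vaf <- function(n, shape = c(20, 20)) {
  stats::rbeta(n, shape[1], shape[2])
}

#' Default background substitution signature
#'
#' A flattish 96-channel profile enriched for C>A with 3' A or T neighbours,
#' mimicking the culture-associated background process.
#'
#' @return named numeric vector over the SBS96 channels, summing to 1.
#' @export
default_background_sbs <- function() {
  ch <- parse_sbs_channels()
  w <- rep(1, 96)
  w[ch$ref == "C" & ch$alt == "A" & ch$three %in% c("A", "T")] <- 8
  w[ch$ref == "C" & ch$alt == "T"] <- 2
  stats::setNames(w / sum(w), ch$channel)
}

#' Default background indel signature
#'
#' Mass on 1-bp T and C deletions/insertions at short-to-long repeat tracts
#' plus small multi-bp and microhomology components.
#'
#' @return named numeric vector over the ID29 channels, summing to 1.
#' @export
default_background_indel <- function() {
  w <- c("del:1bp:T:1-2" = 0.15, "del:1bp:T:3-4" = 0.15, "del:1bp:T:5+" = 0.10,
         "del:1bp:C:1-2" = 0.15, "del:1bp:C:3-4" = 0.05,
         "ins:1bp:T:0" = 0.05, "ins:1bp:T:1-2" = 0.10, "ins:1bp:T:3-4" = 0.05,
         "ins:1bp:C:0" = 0.05,
         "del:2bp:norep" = 0.05, "del:MH" = 0.05, "ins:2bp:norep" = 0.05)
  normalize_signature(w, scheme_channels("ID29"))
}

#' Default doublet signature
#'
#' CC>TT-dominant doublet profile (the classic tandem pattern), with minor
#' mass on other canonical classes.
#'
#' @return named numeric vector over the DBS78 channels, summing to 1.
#' @export
default_dbs_signature <- function() {
  w <- c("CC>TT" = 0.4, "CC>AA" = 0.2, "TC>AA" = 0.2, "CT>AA" = 0.2)
  normalize_signature(w, scheme_channels("DBS78"))
}

#' Sample substitutions from a signature over a toy genome
#'
#' Draws channel counts from the signature (multinomial), then places each
#' mutation at a genomic site whose trinucleotide matches the channel's
#' context, so re-classification recovers the channel exactly. Placement can
#' be biased by transcriptional strand and replication-timing decile to
#' inject topography structure.
#'
#' @param genome a [toy_genome()].
#' @param signature SBS96 signature (named or length-96 vector).
#' @param n number of mutations.
#' @param strand_bias weight multiplier applied to genic sites whose
#'   pyrimidine lies on the coding (non-transcribed) strand; 1 = symmetric.
#' @param rtd_gradient weight multiplier reaching this factor at the latest
#'   replication-timing decile (geometric in decile); 1 = flat.
#' @param sample sample id for the emitted records.
#' @param contamination expected number of additional low-VAF (< 0.2)
#'   records per true mutation, drawn Poisson; exercises the VAF filter.
#' @param vaf_shape Beta shape parameters for clonal VAFs.
#' @param seed optional seed; NULL uses the current RNG stream.
#' @param exclude integer vector of flat site ids to avoid (internal).
#' @return data.frame of mutation records sorted by position.
#' @export
sample_mutations <- function(genome, signature, n, strand_bias = 1,
                             rtd_gradient = 1, sample = "S1",
                             contamination = 0, vaf_shape = c(20, 20),
                             seed = NULL, exclude = integer(0)) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 0) stop("n must be non-negative")
  sig <- normalize_signature(signature, sbs96_channels())
  info <- parse_sbs_channels()
  pos_prob <- sig > 0
  avail <- lengths(genome$sites_by_ctx)[info$ctx]
  bad <- pos_prob & avail == 0L
  if (any(bad))
    stop("channel(s) with positive probability but no matching genomic sites: ",
         paste(info$channel[bad], collapse = ", "))
  n_low <- if (contamination > 0) stats::rpois(1, n * contamination) else 0L
  n_tot <- n + n_low
  if (n_tot == 0L) {
    out <- empty_catalog()
    return(out)
  }
  counts <- as.vector(stats::rmultinom(1, n_tot, sig))
  used <- exclude
  flat <- integer(n_tot)
  chan <- integer(n_tot)
  k0 <- 0L
  ord <- order(counts, decreasing = TRUE)
  for (ci in ord) {
    k <- counts[ci]
    if (k == 0L) next
    cand <- genome$sites_by_ctx[[info$ctx[ci]]]
    if (length(used)) cand <- cand[!(cand %in% used)]
    if (length(cand) < k)
      stop("not enough free genomic sites for channel ", info$channel[ci])
    w <- NULL
    if (strand_bias != 1 || rtd_gradient != 1) {
      w <- rep(1, length(cand))
      if (strand_bias != 1) {
        g <- genome$flat_gene[cand]
        pyr_plus <- genome$flat_pyr[cand]
        on_coding <- (g == 1L & pyr_plus) | (g == 2L & !pyr_plus)
        w[on_coding] <- w[on_coding] * strand_bias
      }
      if (rtd_gradient != 1) {
        d <- genome$flat_decile[cand]
        has <- d > 0L
        w[has] <- w[has] * rtd_gradient^((d[has] - 1) / 9)
      }
    }
    pick <- cand[sample.int(length(cand), k, prob = w)]
    flat[(k0 + 1L):(k0 + k)] <- pick
    chan[(k0 + 1L):(k0 + k)] <- ci
    k0 <- k0 + k
    used <- c(used, pick)
  }
  loc <- flat_to_pos(genome, flat)
  pyr <- genome$flat_pyr[flat]
  ref <- ifelse(pyr, info$ref[chan], chartr("ACGT", "TGCA", info$ref[chan]))
  alt <- ifelse(pyr, info$alt[chan], chartr("ACGT", "TGCA", info$alt[chan]))
  vaf <- draw_vaf(n_tot, vaf_shape)
  if (n_low > 0L) {
    low_idx <- sample.int(n_tot, n_low)
    vaf[low_idx] <- stats::runif(n_low, 0.02, 0.19)
  }
  out <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt,
                    vaf = vaf, sample = sample, stringsAsFactors = FALSE)
  sort_catalog(out)
}

#' Sample adjacent double substitutions from a doublet signature
#'
#' Each doublet is placed jointly at a dinucleotide site matching its
#' reference class (either orientation) and emitted as two adjacent
#' substitution records sharing one VAF, so that [detect_doublets()]
#' recovers it.
#'
#' @param genome a [toy_genome()].
#' @param signature DBS78 signature.
#' @param n number of doublets.
#' @param sample sample id.
#' @param vaf_shape Beta shape parameters for VAFs.
#' @param seed optional seed.
#' @param exclude flat site ids to avoid (internal).
#' @return data.frame of substitution records (two per doublet).
#' @export
sample_doublets <- function(genome, signature, n, sample = "S1",
                            vaf_shape = c(20, 20), seed = NULL,
                            exclude = integer(0)) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(empty_catalog())
  sig <- normalize_signature(signature, dbs78_channels())
  counts <- as.vector(stats::rmultinom(1, n, sig))
  labs <- names(sig)
  used <- exclude
  rows <- list()
  for (ci in which(counts > 0L)) {
    k <- counts[ci]
    ref <- substr(labs[ci], 1, 2)
    alt <- substr(labs[ci], 4, 5)
    refs <- unique(c(ref, revcomp(ref)))
    cand <- integer(0)
    orient <- integer(0)
    for (oi in seq_along(refs)) {
      r1 <- base_to_int(substr(refs[oi], 1, 1))
      r2 <- base_to_int(substr(refs[oi], 2, 2))
      for (cn in genome$contigs) {
        si <- genome$seq_int[[cn]]
        L <- length(si)
        hit <- which(si[-L] == r1 & si[-1] == r2)
        hit <- hit[hit >= 2L & hit + 1L <= L - 1L]
        if (length(hit)) {
          cand <- c(cand, genome$offsets[[cn]] + hit)
          orient <- c(orient, rep(oi, length(hit)))
        }
      }
    }
    keep <- !(cand %in% used) & !((cand + 1L) %in% used)
    cand <- cand[keep]; orient <- orient[keep]
    if (length(cand) < k)
      stop("channel(s) with positive probability but no matching genomic sites: ",
           labs[ci])
    sel <- sample.int(length(cand), k)
    pick <- cand[sel]; po <- orient[sel]
    alt_use <- ifelse(refs[po] == ref, alt, revcomp(alt))
    ref_use <- refs[po]
    loc <- flat_to_pos(genome, pick)
    vaf <- draw_vaf(k, vaf_shape)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = rep(loc$chrom, each = 2L),
      pos = as.vector(rbind(loc$pos, loc$pos + 1L)),
      ref = as.vector(rbind(substr(ref_use, 1, 1), substr(ref_use, 2, 2))),
      alt = as.vector(rbind(substr(alt_use, 1, 1), substr(alt_use, 2, 2))),
      vaf = rep(vaf, each = 2L),
      sample = sample, stringsAsFactors = FALSE)
    used <- c(used, pick, pick + 1L, pick - 1L, pick + 2L)
  }
  sort_catalog(do.call(rbind, rows))
}

## run-length annotation used by the indel sampler (precomputed on the genome)
run_info <- function(genome) {
  genome$runs
}

tract_ok <- function(len, bin) {
  switch(bin,
         "0" = len == 0L,
         "1-2" = len >= 1L & len <= 2L,
         "3-4" = len >= 3L & len <= 4L,
         "5+" = len >= 5L)
}

#' Sample indels from an ID29 signature
#'
#' Placement is repeat-tract aware: 1-bp events are placed in (or next to)
#' homopolymer runs whose length matches the target tract bin; multi-bp and
#' microhomology events are generated by targeted proposals verified through
#' [classify_indel()], so every emitted indel re-classifies to its channel.
#'
#' @param genome a [toy_genome()].
#' @param signature ID29 signature.
#' @param n number of indels.
#' @param sample sample id.
#' @param vaf_shape Beta shape parameters for VAFs.
#' @param seed optional seed.
#' @return data.frame of VCF-style anchored indel records.
#' @export
sample_indels <- function(genome, signature, n, sample = "S1",
                          vaf_shape = c(20, 20), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(empty_catalog())
  sig <- normalize_signature(signature, scheme_channels("ID29"))
  counts <- as.vector(stats::rmultinom(1, n, sig))
  labs <- names(sig)
  runs <- run_info(genome)
  used <- integer(0)
  rows <- list()
  for (ci in which(counts > 0L)) {
    recs <- sample_indel_channel(genome, runs, labs[ci], counts[ci], used)
    if (nrow(recs) == 0L) next
    flat <- flat_id(genome, recs$chrom, recs$pos)
    span <- nchar(recs$ref) + 1L
    used <- c(used, unlist(mapply(function(f, s) f:(f + s), flat, span,
                                  SIMPLIFY = FALSE)))
    recs$vaf <- draw_vaf(nrow(recs), vaf_shape)
    recs$sample <- sample
    rows[[length(rows) + 1L]] <- recs
  }
  sort_catalog(do.call(rbind, rows)[, CATALOG_COLS])
}

sample_indel_channel <- function(genome, runs, lab, k, used) {
  parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
  cls <- parts[1]
  no_sites <- function()
    stop("channel(s) with positive probability but no matching genomic sites: ",
         lab)
  take <- function(cand) {
    cand <- cand[!(cand %in% used)]
    if (length(cand) < k) no_sites()
    cand[sample.int(length(cand), k)]
  }
  if (length(parts) >= 2 && parts[2] == "1bp") {
    b <- parts[3]; bin <- parts[4]
    targets <- c(b, chartr("CT", "GA", b))
    cand <- integer(0)
    for (cn in genome$contigs) {
      si <- genome$seq_int[[cn]]
      ri <- runs[[cn]]
      L <- length(si)
      base_chr <- BASES[si + 1L]
      if (cls == "del") {
        hit <- which(base_chr %in% targets & tract_ok(ri$len, bin) &
                       ri$start >= 2L & ri$end <= L - 1L)
      } else {
        if (bin == "0") {
          p <- 2:(L - 2L)
          hit <- p[!(base_chr[p] %in% targets) & !(base_chr[p + 1L] %in% targets)]
          ## insertion point: after p; pick which target base at emit time
        } else {
          is_start <- ri$start == seq_len(L)
          hit <- which(is_start & base_chr %in% targets &
                         tract_ok(ri$len, bin) & seq_len(L) >= 2L &
                         ri$end <= L - 1L)
          hit <- hit - 1L  # anchor base before the run
        }
      }
      cand <- c(cand, genome$offsets[[cn]] + hit)
    }
    if (length(cand) == 0L) no_sites()
    pick <- take(cand)
    loc <- flat_to_pos(genome, pick)
    if (cls == "del") {
      ## anchor at the base before the chosen run position
      anchor <- genome_base(genome, loc$chrom, loc$pos - 1L)
      delbase <- genome_base(genome, loc$chrom, loc$pos)
      return(data.frame(chrom = loc$chrom, pos = loc$pos - 1L,
                        ref = paste0(anchor, delbase), alt = anchor,
                        vaf = NA_real_, sample = NA_character_,
                        stringsAsFactors = FALSE))
    }
    anchor <- genome_base(genome, loc$chrom, loc$pos)
    ins <- if (bin == "0") {
      sample(targets, length(pick), replace = TRUE)
    } else {
      genome_base(genome, loc$chrom, loc$pos + 1L)
    }
    return(data.frame(chrom = loc$chrom, pos = loc$pos,
                      ref = anchor, alt = paste0(anchor, ins),
                      vaf = NA_real_, sample = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (parts[1] == "del" && parts[2] == "MH")
    return(reject_sample_indel(genome, lab, k, used, propose_mh))
  len <- switch(parts[2], "2bp" = 2L, "3bp" = 3L, "4bp+" = 4L)
  if (parts[3] == "rep") {
    if (cls == "del")
      return(tandem_del(genome, lab, len, k, used))
    return(reject_sample_indel(genome, lab, k, used,
                               function(g, m) propose_dup(g, m, len)))
  }
  propose <- if (cls == "del") {
    function(g, m) propose_del(g, m, len)
  } else {
    function(g, m) propose_ins(g, m, len)
  }
  reject_sample_indel(genome, lab, k, used, propose)
}

## targeted proposal generators; each returns candidate records
propose_del <- function(genome, m, len) {
  cn <- sample(genome$contigs, m, replace = TRUE,
               prob = genome$lengths / sum(genome$lengths))
  L <- genome$lengths[cn]
  s <- 2L + floor(stats::runif(m) * (L - len - 2L))
  ref <- substr(rep(genome$sequences[cn], 1), s - 1L, s + len - 1L)
  data.frame(chrom = cn, pos = s - 1L, ref = ref, alt = substr(ref, 1, 1),
             vaf = NA_real_, sample = NA_character_, stringsAsFactors = FALSE)
}
propose_mh <- function(genome, m) propose_del(genome, m, 3L)
propose_ins <- function(genome, m, len) {
  cn <- sample(genome$contigs, m, replace = TRUE,
               prob = genome$lengths / sum(genome$lengths))
  L <- genome$lengths[cn]
  p <- 2L + floor(stats::runif(m) * (L - len - 3L))
  anchor <- substr(rep(genome$sequences[cn], 1), p, p)
  motif <- vapply(seq_len(m), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
  data.frame(chrom = cn, pos = p, ref = anchor, alt = paste0(anchor, motif),
             vaf = NA_real_, sample = NA_character_, stringsAsFactors = FALSE)
}
propose_dup <- function(genome, m, len) {
  cn <- sample(genome$contigs, m, replace = TRUE,
               prob = genome$lengths / sum(genome$lengths))
  L <- genome$lengths[cn]
  p <- 1L + floor(stats::runif(m) * (L - len - 2L))
  seqs <- genome$sequences[cn]
  anchor <- substr(seqs, p, p)
  motif <- substr(seqs, p + 1L, p + len)
  data.frame(chrom = cn, pos = p, ref = anchor, alt = paste0(anchor, motif),
             vaf = NA_real_, sample = NA_character_, stringsAsFactors = FALSE)
}

tandem_del <- function(genome, lab, len, k, used) {
  cand <- integer(0)
  for (cn in genome$contigs) {
    si <- genome$seq_int[[cn]]
    L <- length(si)
    if (L < 2L * len + 2L) next
    s <- 2:(L - 2L * len)
    ok <- rep(TRUE, length(s))
    for (o in 0:(len - 1L)) ok <- ok & si[s + o] == si[s + len + o]
    cand <- c(cand, genome$offsets[[cn]] + s[ok])
  }
  cand <- cand[!(cand %in% used)]
  if (length(cand) < k)
    stop("channel(s) with positive probability but no matching genomic sites: ",
         lab)
  ## verify via classification (left-alignment can shift the tract)
  loc <- flat_to_pos(genome, cand)
  recs <- data.frame(chrom = loc$chrom, pos = loc$pos - 1L,
                     ref = substr(genome$sequences[loc$chrom], loc$pos - 1L,
                                  loc$pos + len - 1L),
                     alt = genome_base(genome, loc$chrom, loc$pos - 1L),
                     vaf = NA_real_, sample = NA_character_,
                     stringsAsFactors = FALSE)
  ch <- classify_indel(recs, genome)
  recs <- recs[!is.na(ch) & ch == lab, , drop = FALSE]
  if (nrow(recs) < k)
    stop("channel(s) with positive probability but no matching genomic sites: ",
         lab)
  recs[sample.int(nrow(recs), k), , drop = FALSE]
}

reject_sample_indel <- function(genome, lab, k, used, propose, max_rounds = 40L) {
  out <- NULL
  got <- 0L
  for (round in seq_len(max_rounds)) {
    m <- max(20L, 6L * (k - got))
    cand <- propose(genome, m)
    cand <- cand[!grepl("N", cand$ref) & !grepl("N", cand$alt), , drop = FALSE]
    if (nrow(cand) == 0L) next
    ch <- classify_indel(cand, genome)
    keep <- !is.na(ch) & ch == lab
    flat <- flat_id(genome, cand$chrom, cand$pos)
    keep <- keep & !(flat %in% used)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) > 0L) {
      out <- rbind(out, cand)
      out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
      got <- nrow(out)
    }
    if (got >= k) return(out[seq_len(k), , drop = FALSE])
  }
  stop("channel(s) with positive probability but no matching genomic sites: ",
       lab)
}
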
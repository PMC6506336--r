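## End-to-end screen: catalogs -> filters -> profiles -> burden tests ->
## background fit -> signature extraction and gating -> doublet chance null
## -> signature comparison -> topography. Returned as a single fitted-object
## so results can be inspected with print/summary/coef/plot.

stage_seed <- function(seed, stage) {
  ## stage-scoped seeds: deterministic, independent of stage order
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

validate_gates <- function(gates) {
  stopifnot(is.list(gates))
  if (!is.finite(gates$q_max) || gates$q_max <= 0 || gates$q_max > 1)
    stop("invalid gate: q_max must be in (0, 1]")
  if (gates$snr_min < 0) stop("invalid gate: snr_min must be >= 0")
  for (cl in names(gates$stability_min)) {
    s <- gates$stability_min[[cl]]
    if (!is.finite(s) || s < 0 || s > 1)
      stop("invalid gate: stability threshold for ", cl, " must be in [0, 1]")
  }
  if (gates$min_indels_per_subclone < 0 || gates$min_doublets_total < 0)
    stop("invalid gate: burden floors must be non-negative")
  invisible(gates)
}

#' Screen mutagen-treated subclones for mutational signatures
#'
#' Runs the full analysis: VAF filtering, removal of mutations shared within
#' a parental culture, doublet detection, SBS96/DBS78/ID29 profiling,
#' bootstrap burden tests per mutation class, background-model fitting from
#' controls, background-subtraction signature extraction with SNR and
#' stability gating, the chance-adjacency doublet null per sample, cosine
#' comparison and clustering of the passing substitution signatures, and
#' (optionally) topography analyses per passing treatment.
#'
#' @param x a `sim_experiment`, or a named list of mutation-record
#'   data.frames (one per subclone).
#' @param metadata data.frame with columns `sample`, `treatment`, `group`
#'   (`treatment == "control"` marks controls); taken from `x` when it is a
#'   `sim_experiment`.
#' @param genome a [toy_genome()]; taken from `x` when available.
#' @param gates gate thresholds, see [default_gates()].
#' @param vaf_threshold VAF filter threshold (default 0.2).
#' @param n_boot bootstrap resamples for the burden null.
#' @param n_sims_rtd simulated catalogs for the replication-timing
#'   expectation.
#' @param sigma SNR dispersion reduction (see [snr()]).
#' @param topography run the topography stage for passing treatments.
#' @param seed master seed; stage seeds are derived from it, so results are
#'   identical across runs with the same inputs and seed.
#' @return object of class `mutagen_screen`.
#' @export
mutagen_screen <- function(x, metadata = NULL, genome = NULL,
                           gates = default_gates(), vaf_threshold = 0.2,
                           n_boot = 10000L, n_sims_rtd = 100L,
                           sigma = c("rms", "per_channel"),
                           topography = TRUE, seed = 1L) {
  sigma <- match.arg(sigma)
  validate_gates(gates)
  if (inherits(x, "sim_experiment")) {
    catalogs <- x$catalogs
    if (is.null(metadata)) metadata <- x$metadata
    if (is.null(genome)) genome <- x$genome
  } else catalogs <- x
  stopifnot(is.list(catalogs), !is.null(metadata), inherits(genome, "toy_genome"))
  if (!all(metadata$sample %in% names(catalogs)))
    stop("metadata refers to sample(s) without a catalog")
  catalogs <- catalogs[metadata$sample]

  ## 1. VAF filter
  catalogs <- lapply(catalogs, filter_vaf, threshold = vaf_threshold)

  ## 2. shared-mutation removal within each parental culture
  for (g in unique(metadata$group)) {
    members <- metadata$sample[metadata$group == g]
    if (length(members) >= 2L)
      catalogs[members] <- remove_shared(catalogs[members])
  }

  ## 3. per-sample doublet detection and profiles
  samples <- metadata$sample
  singles <- doublets <- excluded_runs <- list()
  prof_sbs <- prof_dbs <- prof_id <- list()
  for (s in samples) {
    rec <- catalogs[[s]]
    is_sub <- is_substitution(rec)
    dd <- detect_doublets(rec[is_sub, , drop = FALSE])
    singles[[s]] <- dd$singles
    doublets[[s]] <- dd$doublets
    excluded_runs[[s]] <- dd$excluded
    prof_sbs[[s]] <- build_profile(dd$singles, "SBS96", genome, sample = s)
    prof_dbs[[s]] <- build_profile(dd$doublets, "DBS78", sample = s)
    prof_id[[s]] <- build_profile(rec[!is_sub, , drop = FALSE], "ID29",
                                  genome, sample = s)
  }
  profiles <- list(SBS96 = profile_matrix(prof_sbs),
                   DBS78 = profile_matrix(prof_dbs),
                   ID29 = profile_matrix(prof_id))

  is_ctrl <- metadata$treatment == "control"
  ctrl_samples <- samples[is_ctrl]
  treatments <- setdiff(unique(metadata$treatment), "control")
  samples_of <- function(tr) metadata$sample[metadata$treatment == tr]

  ## 4. burden tests per mutation class, BH within class
  class_counts <- function(mat) colSums(mat)
  burden <- list()
  class_mats <- list(substitution = profiles$SBS96,
                     doublet = profiles$DBS78,
                     indel = profiles$ID29)
  set.seed(stage_seed(seed, "burden"))
  for (cl in names(class_mats)) {
    counts <- class_counts(class_mats[[cl]])
    tc <- lapply(treatments, function(tr) counts[samples_of(tr)])
    names(tc) <- treatments
    if (length(tc))
      burden[[cl]] <- burden_test(tc, counts[ctrl_samples],
                                  mutation_class = cl, n_boot = n_boot)
  }
  burden <- do.call(rbind, burden)
  rownames(burden) <- NULL

  ## 5. background models from controls
  background <- list(
    SBS96 = fit_background(profiles$SBS96[, ctrl_samples, drop = FALSE]),
    ID29 = fit_background(profiles$ID29[, ctrl_samples, drop = FALSE]))

  ## 6. extraction + gating per treatment
  qs <- function(tr, cl) {
    i <- burden$treatment == tr & burden$mutation_class == cl
    if (any(i)) burden$q[i] else NA_real_
  }
  calls <- list(); signatures <- list(SBS96 = list(), DBS78 = list(), ID29 = list())
  for (tr in treatments) {
    ss <- samples_of(tr)
    tm_sbs <- profiles$SBS96[, ss, drop = FALSE]
    tm_id <- profiles$ID29[, ss, drop = FALSE]
    tm_dbs <- profiles$DBS78[, ss, drop = FALSE]
    attr(tm_sbs, "scheme") <- "SBS96"
    attr(tm_id, "scheme") <- "ID29"
    attr(tm_dbs, "scheme") <- "DBS78"

    sig_sbs <- tryCatch(extract_signature(tm_sbs, background$SBS96, source = tr),
                        error = function(e) NULL)
    sig_id <- tryCatch(extract_signature(tm_id, background$ID29, source = tr),
                       error = function(e) NULL)
    sig_dbs <- if (sum(tm_dbs) > 0)
      extract_signature(tm_dbs, NULL, source = tr) else NULL

    snr_sbs <- snr(tm_sbs, profiles$SBS96[, ctrl_samples, drop = FALSE], sigma)
    snr_id <- snr(tm_id, profiles$ID29[, ctrl_samples, drop = FALSE], sigma)
    stab_sbs <- stability(per_subclone_signatures(tm_sbs, background$SBS96))
    stab_id <- stability(per_subclone_signatures(tm_id, background$ID29))

    calls[[paste0(tr, ".substitution")]] <- call_signature(
      tr, "substitution", q = qs(tr, "substitution"), snr = snr_sbs,
      stability = stab_sbs, mean_burden = mean(colSums(tm_sbs)),
      total_burden = sum(tm_sbs), signature = sig_sbs, gates = gates)
    calls[[paste0(tr, ".indel")]] <- call_signature(
      tr, "indel", q = qs(tr, "indel"), snr = snr_id,
      stability = stab_id, mean_burden = mean(colSums(tm_id)),
      total_burden = sum(tm_id), signature = sig_id, gates = gates)
    calls[[paste0(tr, ".doublet")]] <- call_signature(
      tr, "doublet", q = qs(tr, "doublet"),
      mean_burden = mean(colSums(tm_dbs)), total_burden = sum(tm_dbs),
      signature = sig_dbs, gates = gates)

    if (!is.null(sig_sbs)) signatures$SBS96[[tr]] <- sig_sbs
    if (!is.null(sig_id)) signatures$ID29[[tr]] <- sig_id
    if (!is.null(sig_dbs)) signatures$DBS78[[tr]] <- sig_dbs
  }

  ## 7. doublet chance null per sample
  dbl_stats <- NULL
  dn_rows <- list()
  for (s in samples) {
    n_singles <- sum(profiles$SBS96[, s])
    n_dbl <- sum(profiles$DBS78[, s])
    n_sub <- n_singles + 2L * n_dbl
    if (n_sub < 1L) next
    prof <- profiles$SBS96[, s]
    if (sum(prof) == 0L) next
    null <- prob_no_doublet(n_sub, prof / sum(prof), genome)
    dn_rows[[s]] <- cbind(sample = s, n_sub = n_sub,
                          doublet_excess_test(n_dbl, null))
  }
  doublet_null_tab <- do.call(rbind, dn_rows)
  rownames(doublet_null_tab) <- NULL

  ## 8. comparison of passing substitution signatures
  passing_sbs <- vapply(treatments, function(tr)
    isTRUE(calls[[paste0(tr, ".substitution")]]$passes), logical(1))
  similarity <- dendrogram <- NULL
  if (sum(passing_sbs) >= 2L) {
    sigs <- lapply(signatures$SBS96[treatments[passing_sbs]], function(s) s$probs)
    similarity <- cosine_matrix(sigs)
    dendrogram <- signature_hclust(sigs)
  }

  ## 9. topography for passing treatments
  topo <- NULL
  if (topography && any(passing_sbs)) {
    topo <- list()
    for (tr in treatments[passing_sbs]) {
      rec <- do.call(rbind, singles[samples_of(tr)])
      tal <- strand_tally(rec, genome)
      topo[[tr]] <- list(
        strand = strand_asymmetry_test(tal),
        rtd = rtd_analysis(rec, genome, signatures$SBS96[[tr]]$probs,
                           n_sims = n_sims_rtd,
                           seed = stage_seed(seed, paste0("rtd.", tr))),
        cpg = if (!is.null(genome$cpg)) cpg_enrichment(rec, genome),
        strand_by_rtd = strand_asymmetry_by_rtd(rec, genome, NULL))
    }
  }

  structure(list(
    metadata = metadata, profiles = profiles, burden = burden,
    background = background, calls = calls, signatures = signatures,
    doublet_null = doublet_null_tab, similarity = similarity,
    dendrogram = dendrogram, topography = topo,
    gates = gates, seed = seed,
    n_controls = length(ctrl_samples), treatments = treatments
  ), class = "mutagen_screen")
}

calls_table <- function(x) {
  do.call(rbind, lapply(x$calls, function(cl) data.frame(
    treatment = cl$treatment, mutation_class = cl$mutation_class,
    q = cl$q, snr = cl$snr, stability = cl$stability,
    mean_burden = cl$mean_burden, total_burden = cl$total_burden,
    clipped_mass = if (!is.null(cl$signature)) cl$signature$clipped_mass
                   else NA_real_,
    passes = cl$passes, stringsAsFactors = FALSE, row.names = NULL)))
}

#' @export
print.mutagen_screen <- function(x, ...) {
  cat("mutagen_screen:", x$n_controls, "controls,",
      length(x$treatments), "treatment(s)\n")
  ct <- calls_table(x)
  np <- sum(ct$passes)
  cat("  signature calls passing all gates:", np, "of", nrow(ct), "\n")
  if (np > 0) {
    p <- ct[ct$passes, ]
    cat(paste0("    ", p$treatment, " [", p$mutation_class, "]",
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
summary.mutagen_screen <- function(object, ...) {
  out <- list(calls = calls_table(object), burden = object$burden,
              doublet_null = object$doublet_null)
  class(out) <- "summary.mutagen_screen"
  out
}

#' @export
print.summary.mutagen_screen <- function(x, ...) {
  cat("Signature calls:\n")
  print(x$calls, digits = 3)
  cat("\nBurden tests:\n")
  print(x$burden, digits = 3)
  invisible(x)
}

#' Extract the signature matrix from a screen
#'
#' @param object a `mutagen_screen`.
#' @param scheme which channel scheme to return.
#' @param ... unused.
#' @return channels-by-treatments matrix of extracted signature
#'   probabilities (treatments with an extractable signature only).
#' @export
coef.mutagen_screen <- function(object, scheme = c("SBS96", "DBS78", "ID29"),
                                ...) {
  scheme <- match.arg(scheme)
  sigs <- object$signatures[[scheme]]
  if (length(sigs) == 0L) return(NULL)
  m <- do.call(cbind, lapply(sigs, function(s) s$probs))
  colnames(m) <- names(sigs)
  m
}

#' Plot an extracted signature profile
#'
#' @param x a `mutagen_screen`.
#' @param treatment treatment to plot (default: first with a signature).
#' @param scheme channel scheme.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.mutagen_screen <- function(x, treatment = NULL,
                                scheme = c("SBS96", "DBS78", "ID29"), ...) {
  scheme <- match.arg(scheme)
  sigs <- x$signatures[[scheme]]
  if (length(sigs) == 0L) stop("no extracted signatures to plot")
  if (is.null(treatment)) treatment <- names(sigs)[1]
  s <- sigs[[treatment]]
  if (is.null(s)) stop("no ", scheme, " signature for treatment ", treatment)
  cols <- if (scheme == "SBS96")
    rep(c("#03BCEE", "#010101", "#E32926", "#CAC9C9", "#A1CE63", "#EBC6C4"),
        each = 16) else "grey40"
  graphics::barplot(s$probs, col = cols, border = NA, las = 2,
                    cex.names = 0.35, ylab = "probability",
                    main = paste0(treatment, " (", scheme, ")"), ...)
  invisible(x)
}

#' Write screen outputs to disk
#'
#' Writes the burden table, signature matrices, gated calls with gate
#' traces, background model, similarity matrix, newick dendrogram, doublet
#' null table, topography tables and a JSON summary. Outputs are
#' byte-identical across runs with identical inputs and seed.
#'
#' @param x a `mutagen_screen`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(x$burden, "burden.tsv")
  ct <- calls_table(x)
  trace <- do.call(rbind, lapply(x$calls, function(cl) {
    t <- cl$gate_trace
    paste(sprintf("%s=%s", names(t), t), collapse = ";")
  }))
  ct$gate_trace <- as.vector(trace)
  wt(ct, "calls.tsv")
  for (sch in names(x$signatures)) {
    m <- coef.mutagen_screen(x, sch)
    if (!is.null(m))
      write_signature_matrix(m, file.path(dir, sprintf("signatures_%s.tsv",
                                                       tolower(sch))))
  }
  bg <- data.frame(channel = names(x$background$SBS96$mean_profile),
                   mean_profile = x$background$SBS96$mean_profile,
                   signature = x$background$SBS96$signature)
  wt(bg, "background_sbs.tsv")
  if (!is.null(x$similarity))
    write_signature_matrix(x$similarity, file.path(dir, "similarity.tsv"))
  if (!is.null(x$dendrogram))
    write_newick(x$dendrogram, file.path(dir, "dendrogram.nwk"))
  if (!is.null(x$doublet_null)) wt(x$doublet_null, "doublet_null.tsv")
  if (!is.null(x$topography)) {
    st <- do.call(rbind, lapply(names(x$topography), function(tr)
      cbind(treatment = tr, x$topography[[tr]]$strand)))
    wt(st, "topography_strand.tsv")
  }
  summary <- list(
    n_controls = x$n_controls,
    treatments = x$treatments,
    passing = calls_table(x)[calls_table(x)$passes,
                             c("treatment", "mutation_class")],
    seed = x$seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
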
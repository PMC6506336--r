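## Experiment-level simulation: controls plus treatment groups of subclones,
## emulating a subclone mutagenesis screen (35 solvent/media controls with a
## background process of ~245 substitutions, ~10 indels and ~1 doublet per
## subclone; treatment groups of 2-4 subclones carrying background plus a
## configurable treatment signature and excess burden per mutation class).

#' Specify one mutagen treatment for simulation
#'
#' @param name treatment name (unique within a configuration).
#' @param n_subclones number of daughter subclones (2-4).
#' @param sub_signature,sub_excess SBS96 signature and mean excess
#'   substitution burden per subclone (Poisson).
#' @param dbs_signature,dbs_excess DBS78 signature and mean excess doublets.
#' @param indel_signature,indel_excess ID29 signature and mean excess indels.
#' @param strand_bias transcriptional strand bias factor for the injected
#'   substitutions (1 = none).
#' @param rtd_gradient replication-timing gradient factor for the injected
#'   substitutions (1 = flat).
#' @return a `treatment_spec` list.
#' @export
treatment_spec <- function(name, n_subclones = 3L,
                           sub_signature = NULL, sub_excess = 0,
                           dbs_signature = NULL, dbs_excess = 0,
                           indel_signature = NULL, indel_excess = 0,
                           strand_bias = 1, rtd_gradient = 1) {
  if (!n_subclones %in% 2:4)
    stop("n_subclones must be 2, 3 or 4")
  if (any(c(sub_excess, dbs_excess, indel_excess) < 0))
    stop("excess burdens must be non-negative")
  structure(list(name = name, n_subclones = as.integer(n_subclones),
                 sub_signature = sub_signature, sub_excess = sub_excess,
                 dbs_signature = dbs_signature, dbs_excess = dbs_excess,
                 indel_signature = indel_signature, indel_excess = indel_excess,
                 strand_bias = strand_bias, rtd_gradient = rtd_gradient),
            class = "treatment_spec")
}

#' Simulation configuration
#'
#' Defaults reproduce the screen's study design: 35 control subclones with a
#' background process of ~245 substitutions, ~10 indels and ~1 doublet per
#' subclone (Poisson between-subclone dispersion), organized into parental
#' cultures of 2-3 subclones that share a configurable number of
#' pre-existing mutations.
#'
#' @param n_controls number of control subclones.
#' @param treatments list of [treatment_spec()] objects.
#' @param background_sub_burden,background_indel_burden,background_dbs_burden
#'   mean background burdens per subclone.
#' @param background_sub_signature,background_indel_signature,background_dbs_signature
#'   background signatures (defaults: [default_background_sbs()],
#'   [default_background_indel()], [default_dbs_signature()]).
#' @param shared_per_group number of parental (shared) mutations injected
#'   into every subclone of a group; removed by [remove_shared()].
#' @param contamination expected low-VAF artifact records per true
#'   substitution; exercises [filter_vaf()].
#' @param seed master seed; a fixed seed makes the whole experiment
#'   byte-identical across runs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_controls = 35L, treatments = list(),
                       background_sub_burden = 245,
                       background_indel_burden = 10,
                       background_dbs_burden = 1,
                       background_sub_signature = default_background_sbs(),
                       background_indel_signature = default_background_indel(),
                       background_dbs_signature = default_dbs_signature(),
                       shared_per_group = 25L,
                       contamination = 0.05,
                       seed = 1L) {
  if (n_controls < 2L) stop("need at least 2 control subclones")
  if (any(c(background_sub_burden, background_indel_burden,
            background_dbs_burden) < 0))
    stop("background burdens must be non-negative")
  nm <- vapply(treatments, function(t) t$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate treatment names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(
    n_controls = as.integer(n_controls), treatments = treatments,
    background_sub_burden = background_sub_burden,
    background_indel_burden = background_indel_burden,
    background_dbs_burden = background_dbs_burden,
    background_sub_signature =
      normalize_signature(background_sub_signature, sbs96_channels()),
    background_indel_signature =
      normalize_signature(background_indel_signature, scheme_channels("ID29")),
    background_dbs_signature =
      normalize_signature(background_dbs_signature, dbs78_channels()),
    shared_per_group = as.integer(shared_per_group),
    contamination = contamination, seed = as.integer(seed)
  ), class = "sim_config")
}

simulate_subclone <- function(genome, config, sample, treatment = NULL) {
  parts <- list()
  n_sub <- stats::rpois(1, config$background_sub_burden)
  parts$sub <- sample_mutations(genome, config$background_sub_signature,
                                n_sub, sample = sample,
                                contamination = config$contamination)
  n_ind <- stats::rpois(1, config$background_indel_burden)
  if (n_ind > 0L)
    parts$ind <- sample_indels(genome, config$background_indel_signature,
                               n_ind, sample = sample)
  n_dbs <- stats::rpois(1, config$background_dbs_burden)
  if (n_dbs > 0L)
    parts$dbs <- sample_doublets(genome, config$background_dbs_signature,
                                 n_dbs, sample = sample,
                                 exclude = flat_id(genome, parts$sub$chrom,
                                                   parts$sub$pos))
  if (!is.null(treatment)) {
    ns <- stats::rpois(1, treatment$sub_excess)
    if (ns > 0L) {
      sig <- if (is.null(treatment$sub_signature))
        config$background_sub_signature else treatment$sub_signature
      excl <- flat_id(genome, parts$sub$chrom, parts$sub$pos)
      parts$tsub <- sample_mutations(genome, sig, ns,
                                     strand_bias = treatment$strand_bias,
                                     rtd_gradient = treatment$rtd_gradient,
                                     sample = sample, exclude = excl)
    }
    nd <- stats::rpois(1, treatment$dbs_excess)
    if (nd > 0L) {
      sig <- if (is.null(treatment$dbs_signature))
        default_dbs_signature() else treatment$dbs_signature
      subs_so_far <- do.call(rbind, parts[intersect(names(parts),
                                                    c("sub", "tsub", "dbs"))])
      parts$tdbs <- sample_doublets(genome, sig, nd, sample = sample,
                                    exclude = flat_id(genome, subs_so_far$chrom,
                                                      subs_so_far$pos))
    }
    ni <- stats::rpois(1, treatment$indel_excess)
    if (ni > 0L) {
      sig <- if (is.null(treatment$indel_signature))
        config$background_indel_signature else treatment$indel_signature
      parts$tind <- sample_indels(genome, sig, ni, sample = sample)
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  sort_catalog(out)
}

#' Simulate a full subclone mutagenesis experiment
#'
#' Generates per-subclone mutation catalogs for controls and treatment
#' groups over a toy genome, together with a truth manifest recording the
#' injected signatures and burdens for parameter-recovery testing. With a
#' fixed seed the output is byte-identical across runs.
#'
#' @param genome a [toy_genome()].
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes the genome
#'   (FASTA + BED tracks), one TSV catalog per subclone, a sample metadata
#'   table and a JSON truth manifest.
#' @return an object of class `sim_experiment`: list with `catalogs` (named
#'   list of record data.frames), `metadata` (sample, treatment, group),
#'   `truth` and `genome`.
#' @export
simulate_experiment <- function(genome, config, dir = NULL) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  set.seed(config$seed)
  catalogs <- list()
  meta <- list()

  add_group <- function(samples, group, treatment_name, treatment = NULL) {
    shared <- NULL
    if (config$shared_per_group > 0L)
      shared <- sample_mutations(genome, config$background_sub_signature,
                                 config$shared_per_group, sample = NA_character_)
    for (s in samples) {
      cat_s <- simulate_subclone(genome, config, s, treatment)
      if (!is.null(shared)) {
        sh <- shared; sh$sample <- s
        cat_s <- sort_catalog(rbind(cat_s, sh))
      }
      catalogs[[s]] <<- cat_s
      meta[[length(meta) + 1L]] <<- data.frame(
        sample = s, treatment = treatment_name, group = group,
        stringsAsFactors = FALSE)
    }
  }

  ## controls, grouped into parental cultures of up to 3 subclones
  ctrl_samples <- sprintf("Ctrl%02d", seq_len(config$n_controls))
  grp <- ceiling(seq_len(config$n_controls) / 3)
  for (g in unique(grp))
    add_group(ctrl_samples[grp == g], sprintf("CtrlCulture%02d", g), "control")

  for (tr in config$treatments) {
    samples <- sprintf("%s_s%d", tr$name, seq_len(tr$n_subclones))
    add_group(samples, tr$name, tr$name, tr)
  }

  metadata <- do.call(rbind, meta)
  truth <- list(
    seed = config$seed,
    n_controls = config$n_controls,
    background = list(
      sub_burden = config$background_sub_burden,
      indel_burden = config$background_indel_burden,
      dbs_burden = config$background_dbs_burden,
      sub_signature = as.list(config$background_sub_signature),
      indel_signature = as.list(config$background_indel_signature),
      dbs_signature = as.list(config$background_dbs_signature)),
    treatments = lapply(config$treatments, function(tr) list(
      name = tr$name, n_subclones = tr$n_subclones,
      sub_excess = tr$sub_excess, dbs_excess = tr$dbs_excess,
      indel_excess = tr$indel_excess,
      strand_bias = tr$strand_bias, rtd_gradient = tr$rtd_gradient,
      sub_signature = if (!is.null(tr$sub_signature))
        as.list(normalize_signature(tr$sub_signature, sbs96_channels())),
      dbs_signature = if (!is.null(tr$dbs_signature))
        as.list(normalize_signature(tr$dbs_signature, dbs78_channels())),
      indel_signature = if (!is.null(tr$indel_signature))
        as.list(normalize_signature(tr$indel_signature,
                                    scheme_channels("ID29"))))))

  out <- structure(list(catalogs = catalogs, metadata = metadata,
                        truth = truth, genome = genome),
                   class = "sim_experiment")
  if (!is.null(dir)) write_experiment(out, dir)
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("sim_experiment:", nrow(x$metadata), "subclones (",
      sum(x$metadata$treatment == "control"), "controls,",
      length(unique(x$metadata$treatment[x$metadata$treatment != "control"])),
      "treatments )\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' @param experiment a `sim_experiment`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(experiment$genome, dir)
  cat_dir <- file.path(dir, "catalogs")
  dir.create(cat_dir, showWarnings = FALSE)
  for (s in names(experiment$catalogs))
    write_catalog(experiment$catalogs[[s]], file.path(cat_dir, paste0(s, ".tsv")))
  utils::write.table(experiment$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(experiment$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
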
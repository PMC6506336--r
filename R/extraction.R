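## Background-subtraction signature extraction with signal-to-noise and
## stability gating.
##
## The treatment subclone profile is modelled as a linear combination of the
## background process and the mutagen process,
##   M_subclone = N_background * P_background + N_mutagen * P_mutagen,
## and since control subclones carry only the background process the mutagen
## signature is recovered by subtracting the mean control profile:
##   P_mutagen = (M_subclone - M_control) / (N_subclone - N_control).

#' Fit the background model from control profiles
#'
#' The background substitution signature is the mean of the control subclone
#' profiles; for sparse classes (indels, doublets) the aggregate (summed)
#' profile is also kept. Per-channel dispersion is recorded.
#'
#' @param control_profiles channels-by-subclones matrix (or list of profiles
#'   from [build_profile()]) of one scheme.
#' @return object of class `background_model` with elements `scheme`,
#'   `mean_profile`, `aggregate_profile`, `signature` (normalized mean),
#'   `mean_burden`, `sd_burden`, `channel_sd`, `n_controls`.
#' @export
fit_background <- function(control_profiles) {
  if (is.list(control_profiles)) control_profiles <- profile_matrix(control_profiles)
  if (ncol(control_profiles) < 2L) stop("need at least 2 control profiles")
  scheme <- attr(control_profiles, "scheme")
  mean_profile <- rowMeans(control_profiles)
  aggregate <- rowSums(control_profiles)
  burdens <- colSums(control_profiles)
  if (mean(burdens) <= 0) stop("control profiles are empty")
  structure(list(
    scheme = scheme,
    mean_profile = mean_profile,
    aggregate_profile = aggregate,
    signature = mean_profile / sum(mean_profile),
    mean_burden = mean(burdens),
    sd_burden = stats::sd(burdens),
    channel_sd = apply(control_profiles, 1, stats::sd),
    n_controls = ncol(control_profiles)
  ), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model (", x$scheme, "): ", x$n_controls,
      " controls, mean burden ", round(x$mean_burden, 1), "\n", sep = "")
  invisible(x)
}

#' Signal-to-noise ratio between treatment and control profiles
#'
#' The Euclidean distance between the treatment and control profile
#' centroids, divided by the summed within-group dispersions, computed on
#' raw count profiles. The group dispersion is by default the root mean
#' square Euclidean distance of member profiles from their centroid
#' (`sigma = "rms"`); `sigma = "per_channel"` instead uses the Euclidean
#' norm of the per-channel standard deviation vector.
#'
#' @param treatment_profiles,control_profiles channels-by-subclones count
#'   matrices (>= 2 columns each).
#' @param sigma dispersion reduction, `"rms"` or `"per_channel"`.
#' @return the SNR; `0` when both dispersions vanish and the centroids
#'   coincide; `Inf` (with attribute `degenerate = TRUE`) when both
#'   dispersions vanish but the centroids differ.
#' @export
snr <- function(treatment_profiles, control_profiles,
                sigma = c("rms", "per_channel")) {
  sigma <- match.arg(sigma)
  if (is.list(treatment_profiles)) treatment_profiles <- profile_matrix(treatment_profiles)
  if (is.list(control_profiles)) control_profiles <- profile_matrix(control_profiles)
  if (ncol(treatment_profiles) < 2L || ncol(control_profiles) < 2L)
    stop("need at least 2 profiles per group")
  ct <- rowMeans(treatment_profiles)
  cc <- rowMeans(control_profiles)
  signal <- sqrt(sum((ct - cc)^2))
  disp <- function(m) {
    if (sigma == "rms") {
      sqrt(mean(colSums((m - rowMeans(m))^2)))
    } else {
      sqrt(sum(apply(m, 1, stats::sd)^2))
    }
  }
  noise <- disp(treatment_profiles) + disp(control_profiles)
  if (noise == 0) {
    if (signal == 0) return(0)
    return(structure(Inf, degenerate = TRUE))
  }
  signal / noise
}

#' Extract a mutagen signature by background subtraction
#'
#' Subtracts the background mean profile from the mean treatment profile and
#' divides by the excess burden; the result sums to one by construction.
#' Negative channels (sampling noise) are clipped to zero with the clipped
#' mass recorded, then the signature is renormalized.
#'
#' @param treatment_profiles channels-by-subclones count matrix (a single
#'   profile vector is also accepted, e.g. for per-subclone signatures).
#' @param background a [fit_background()] model of the same scheme, or NULL
#'   to skip subtraction (used for doublets, whose background is negligible).
#' @param source optional label (treatment or subclone id) recorded on the
#'   signature.
#' @return object of class `mut_signature`: list with `scheme`, `probs`
#'   (named, sums to 1), `clipped_mass`, `n_excess_mean`, `source`.
#' @export
extract_signature <- function(treatment_profiles, background = NULL,
                              source = NULL) {
  if (is.list(treatment_profiles) && !is.matrix(treatment_profiles))
    treatment_profiles <- profile_matrix(treatment_profiles)
  if (!is.matrix(treatment_profiles))
    treatment_profiles <- matrix(treatment_profiles,
                                 dimnames = list(names(treatment_profiles), NULL))
  mt <- rowMeans(treatment_profiles)
  nt <- mean(colSums(treatment_profiles))
  if (is.null(background)) {
    if (nt <= 0) stop("no excess burden: treatment profile is empty")
    probs <- mt / sum(mt)
    clipped <- 0
    excess <- nt
    scheme <- attr(treatment_profiles, "scheme")
  } else {
    scheme <- background$scheme
    excess <- nt - background$mean_burden
    if (excess <= 0)
      stop("no excess burden: treatment mean burden (", round(nt, 1),
           ") does not exceed the background mean burden (",
           round(background$mean_burden, 1), ")")
    probs <- (mt - background$mean_profile) / excess
    clipped <- -sum(probs[probs < 0])
    probs[probs < 0] <- 0
    probs <- probs / sum(probs)
  }
  structure(list(scheme = scheme, probs = probs, clipped_mass = clipped,
                 n_excess_mean = excess, source = source),
            class = "mut_signature")
}

#' @export
print.mut_signature <- function(x, ...) {
  top <- sort(x$probs, decreasing = TRUE)[1:3]
  cat("mut_signature (", x$scheme, ")",
      if (!is.null(x$source)) paste0(" [", x$source, "]"), ": ",
      "excess burden ", round(x$n_excess_mean, 1),
      ", clipped mass ", signif(x$clipped_mass, 3), "\n", sep = "")
  cat("  top channels:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Per-subclone signatures for the stability measure
#'
#' Applies the subtraction to each subclone profile individually, against
#' the shared background mean burden.
#'
#' @param treatment_profiles channels-by-subclones count matrix.
#' @param background a [fit_background()] model.
#' @return list of `mut_signature` objects (NULL for subclones with no
#'   excess burden).
#' @export
per_subclone_signatures <- function(treatment_profiles, background) {
  if (is.list(treatment_profiles)) treatment_profiles <- profile_matrix(treatment_profiles)
  lapply(seq_len(ncol(treatment_profiles)), function(j) {
    m <- treatment_profiles[, j, drop = FALSE]
    attr(m, "scheme") <- background$scheme
    tryCatch(extract_signature(m, background,
                               source = colnames(treatment_profiles)[j]),
             error = function(e) NULL)
  })
}

#' Stability of a signature across subclones
#'
#' The maximum pairwise cosine similarity among the signatures extracted
#' from the individual subclones of one treatment: a high value means the
#' signature is consistent in at least two subclones.
#'
#' @param per_subclone list of `mut_signature` objects (or probability
#'   vectors); NULL entries (no excess) are dropped.
#' @return the maximum pairwise cosine, or `NA` (flagged, gate fails) when
#'   fewer than two subclone signatures are available.
#' @export
stability <- function(per_subclone) {
  probs <- lapply(per_subclone, function(s) {
    if (is.null(s)) NULL else if (inherits(s, "mut_signature")) s$probs else s
  })
  probs <- Filter(Negate(is.null), probs)
  if (length(probs) < 2L) return(NA_real_)
  best <- -Inf
  for (i in seq_len(length(probs) - 1L))
    for (j in (i + 1L):length(probs))
      best <- max(best, cosine(probs[[i]], probs[[j]]))
  best
}

#' Default gate thresholds per mutation class
#'
#' Substitutions: adjusted burden p < 0.01, SNR >= 2, stability >= 0.8.
#' Indels: adjusted p < 0.01, SNR >= 2, stability >= 0.7 and mean indel
#' burden per subclone >= 20. Doublets: adjusted p < 0.01 and more than 20
#' doublets in total (background doublets are negligible, so no SNR or
#' stability gate).
#'
#' @return nested list of thresholds, overridable in [call_signature()].
#' @export
default_gates <- function() {
  list(q_max = 0.01, snr_min = 2,
       stability_min = list(substitution = 0.8, indel = 0.7),
       min_indels_per_subclone = 20,
       min_doublets_total = 20)
}

#' Gate a treatment's signature call
#'
#' Combines the burden q-value, SNR and stability (plus the class-specific
#' burden floors) into a pass/fail decision with a full gate trace.
#'
#' @param treatment treatment id.
#' @param mutation_class `"substitution"`, `"indel"` or `"doublet"`.
#' @param q adjusted burden p-value.
#' @param snr signal-to-noise ratio (NA allowed for doublets).
#' @param stability stability measure (NA fails the gate).
#' @param mean_burden mean per-subclone burden of the class (treatment).
#' @param total_burden total count of the class across subclones.
#' @param signature optional `mut_signature` attached to the call.
#' @param gates threshold list, see [default_gates()].
#' @return object of class `signature_call`: fields plus `passes` and
#'   `gate_trace` (named logical vector of each comparison).
#' @export
call_signature <- function(treatment,
                           mutation_class = c("substitution", "indel", "doublet"),
                           q, snr = NA_real_, stability = NA_real_,
                           mean_burden = NA_real_, total_burden = NA_real_,
                           signature = NULL, gates = default_gates()) {
  mutation_class <- match.arg(mutation_class)
  trace <- c(q_lt_max = isTRUE(q < gates$q_max))
  if (mutation_class == "doublet") {
    trace["doublets_gt_min"] <- isTRUE(total_burden > gates$min_doublets_total)
  } else {
    trace["snr_ge_min"] <- isTRUE(snr >= gates$snr_min)
    smin <- gates$stability_min[[mutation_class]]
    trace["stability_ge_min"] <- isTRUE(stability >= smin)
    if (mutation_class == "indel")
      trace["mean_burden_ge_min"] <-
        isTRUE(mean_burden >= gates$min_indels_per_subclone)
  }
  structure(list(treatment = treatment, mutation_class = mutation_class,
                 q = q, snr = snr, stability = stability,
                 mean_burden = mean_burden, total_burden = total_burden,
                 signature = signature,
                 passes = all(trace), gate_trace = trace),
            class = "signature_call")
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("signature_call: %s [%s] -> %s\n", x$treatment,
              x$mutation_class, if (x$passes) "PASS" else "fail"))
  tr <- x$gate_trace
  cat("  gates:", paste(sprintf("%s=%s", names(tr), tr), collapse = ", "), "\n")
  invisible(x)
}
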
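## Mutation-burden testing: bootstrap null of control subclone means,
## one-sided p-values with add-one correction, BH adjustment per mutation
## class, and a mutagenicity effect size.

#' Bootstrap null distribution of control-group means
#'
#' Resamples `group_size` control burdens with replacement `n_boot` times and
#' returns the resample means, the null distribution for a treatment with
#' that many subclones.
#'
#' @param control_counts numeric vector of per-subclone control burdens.
#' @param group_size number of subclones in the treatment group (2-4 unless
#'   `strict = FALSE`).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed optional seed.
#' @param strict if TRUE (default), `group_size` outside 2-4 is an error.
#' @return numeric vector of `n_boot` bootstrap means.
#' @export
bootstrap_null <- function(control_counts, group_size, n_boot = 10000L,
                           seed = NULL, strict = TRUE) {
  if (length(control_counts) < 2L) stop("need at least 2 control counts")
  if (n_boot < 1000L) stop("n_boot must be at least 1000")
  if (strict && !group_size %in% 2:4)
    stop("group_size must be 2, 3 or 4 (use strict = FALSE to override)")
  if (!is.null(seed)) set.seed(seed)
  draws <- sample(control_counts, group_size * n_boot, replace = TRUE)
  rowMeans(matrix(draws, ncol = group_size))
}

#' One-sided bootstrap p-value for a treatment mean burden
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_boot)`; the add-one keeps the
#' estimate away from zero (resolution floor `1/(n_boot+1)`). One-sided:
#' only an increase over the control distribution counts.
#'
#' @param treatment_mean observed mean burden of the treatment subclones.
#' @param null_distribution bootstrap means from [bootstrap_null()].
#' @return p-value in (0, 1].
#' @export
burden_pvalue <- function(treatment_mean, null_distribution) {
  if (length(null_distribution) == 0L) stop("empty null distribution")
  (1 + sum(null_distribution >= treatment_mean)) /
    (1 + length(null_distribution))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param ps numeric vector of p-values in `[0, 1]`.
#' @return vector of BH step-up adjusted values.
#' @export
adjust_pvalues <- function(ps) {
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(ps, method = "BH")
}

#' Mutagenicity index
#'
#' Effect size of mutagenesis over background:
#' `(mean_treatment - mean_control) / mean_control`.
#'
#' @param mean_treatment mean burden of treatment subclones.
#' @param mean_control mean burden of control subclones (> 0).
#' @return the index (>= -1).
#' @export
mutagenicity_index <- function(mean_treatment, mean_control) {
  if (any(mean_control <= 0)) stop("mean_control must be positive")
  (mean_treatment - mean_control) / mean_control
}

#' Burden tests for all treatments in one mutation class
#'
#' Builds one bootstrap null per distinct group size, computes the one-sided
#' p-value and mutagenicity index per treatment, and applies BH correction
#' across treatments (correction is per mutation class: substitutions,
#' doublets and indels are tested separately).
#'
#' @param treatment_counts named list: treatment -> numeric vector of
#'   per-subclone burdens.
#' @param control_counts numeric vector of control per-subclone burdens.
#' @param mutation_class label recorded in the output.
#' @param n_boot bootstrap resamples per null.
#' @param seed optional seed.
#' @return data.frame: treatment, mutation_class, n_subclones,
#'   mean_treatment, mean_control, p, q, mutagenicity_index.
#' @export
burden_test <- function(treatment_counts, control_counts,
                        mutation_class = "substitution",
                        n_boot = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(treatment_counts, length, integer(1))
  nulls <- lapply(sort(unique(sizes)), function(g)
    bootstrap_null(control_counts, g, n_boot = n_boot, strict = FALSE))
  names(nulls) <- as.character(sort(unique(sizes)))
  mc <- mean(control_counts)
  means <- vapply(treatment_counts, mean, numeric(1))
  ps <- vapply(seq_along(means), function(i)
    burden_pvalue(means[i], nulls[[as.character(sizes[i])]]), numeric(1))
  data.frame(treatment = names(treatment_counts),
             mutation_class = mutation_class,
             n_subclones = as.integer(sizes),
             mean_treatment = unname(means),
             mean_control = mc,
             p = ps,
             q = adjust_pvalues(ps),
             mutagenicity_index = mutagenicity_index(unname(means), mc),
             stringsAsFactors = FALSE, row.names = NULL)
}
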
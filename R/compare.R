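## Signature comparison: cosine similarity, hierarchical clustering on
## 1 - cosine, and matching against reference catalogs.

as_probs <- function(x) {
  if (inherits(x, "mut_signature")) x$probs else x
}

#' Cosine similarity between two signatures
#'
#' @param sig_a,sig_b numeric vectors (or `mut_signature` objects) over the
#'   same channel scheme; neither may be the zero vector.
#' @return `dot(a, b) / (||a|| ||b||)`.
#' @export
cosine <- function(sig_a, sig_b) {
  a <- as_probs(sig_a); b <- as_probs(sig_b)
  if (length(a) != length(b)) stop("signatures have different lengths")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Pairwise cosine similarity matrix
#'
#' @param signatures named list of signatures (vectors or `mut_signature`),
#'   or a channels-by-signatures matrix.
#' @return symmetric matrix of cosines with unit diagonal.
#' @export
cosine_matrix <- function(signatures) {
  m <- if (is.matrix(signatures)) signatures else
    do.call(cbind, lapply(signatures, as_probs))
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) stop("cosine undefined for a zero vector")
  s <- crossprod(m) / tcrossprod(norms)
  ## clamp rounding noise
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Hierarchical clustering of signatures
#'
#' Clusters signatures on the distance `1 - cosine`. Signatures are ordered
#' by label before clustering, so the tree topology is invariant to the
#' input order (deterministic tie-breaking by lexicographic label order).
#'
#' @param signatures named list of signatures or a named-column matrix
#'   (>= 2 signatures).
#' @param linkage_method agglomeration method for [stats::hclust()]
#'   (default `"average"`).
#' @return an `hclust` object.
#' @export
signature_hclust <- function(signatures, linkage_method = "average") {
  m <- if (is.matrix(signatures)) signatures else
    do.call(cbind, lapply(signatures, as_probs))
  if (is.null(colnames(m)) && !is.matrix(signatures))
    colnames(m) <- names(signatures)
  if (ncol(m) < 2L) stop("need at least 2 signatures to cluster")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("signatures must carry unique labels")
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- stats::as.dist(1 - cosine_matrix(m))
  stats::hclust(d, method = linkage_method)
}

#' Export a signature dendrogram as newick
#'
#' @param hc an `hclust` from [signature_hclust()].
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Match a signature against a reference catalog
#'
#' Computes the cosine similarity of the query against every reference
#' signature and returns them sorted descending (ties broken by label).
#' Reference channels are matched by label, never by position.
#'
#' @param signature query signature (named vector or `mut_signature`).
#' @param reference_catalog channels-by-signatures matrix with channel
#'   rownames (e.g. from [read_signature_matrix()]).
#' @return data.frame: reference, cosine, rank.
#' @export
match_reference <- function(signature, reference_catalog) {
  probs <- as_probs(signature)
  if (is.null(names(probs)))
    stop("query signature must have channel names")
  missing <- setdiff(names(probs), rownames(reference_catalog))
  extra <- setdiff(rownames(reference_catalog), names(probs))
  if (length(missing) || length(extra))
    stop("channel labels do not match the reference catalog; offending: ",
         paste(utils::head(c(missing, extra), 10), collapse = ", "))
  ref <- reference_catalog[names(probs), , drop = FALSE]
  cs <- vapply(seq_len(ncol(ref)), function(j) cosine(probs, ref[, j]),
               numeric(1))
  names(cs) <- colnames(ref)
  ord <- order(-cs, names(cs))
  data.frame(reference = names(cs)[ord], cosine = unname(cs[ord]),
             rank = seq_along(cs), stringsAsFactors = FALSE)
}
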
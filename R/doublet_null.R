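## Chance model for adjacent double substitutions.
##
## Given a sample with n substitutions drawn from a signature, how likely is
## it that at least one pair lands on adjacent positions by chance? The
## sequential model places mutations one at a time: the i-th mutation of
## trinucleotide class t has success probability
##   P_i = N_available(t) / N_remaining(t),
## where placing a mutation removes its own position and (in expectation over
## the genome's neighbour composition) its two neighbours from availability.
## The product of the P_i is the probability of seeing no adjacent pair.

## expected removal matrix: R[t, s] = expected positions of class s removed
## when one mutation is placed at a uniform class-t site (own site + its
## neighbours), plus the class counts N
doublet_genome_stats <- function(genome) {
  N <- as.numeric(genome$trinuc_counts)
  R <- diag(32)
  cross <- matrix(0, 32, 32)
  for (cn in genome$contigs) {
    c32 <- genome$ctx32[[cn]]
    L <- length(c32)
    if (L < 4L) next
    a <- c32[-L]; b <- c32[-1]
    ok <- !is.na(a) & !is.na(b)
    idx <- (a[ok] - 1L) * 32L + b[ok]
    tab <- tabulate(idx, nbins = 32L * 32L)
    m <- matrix(tab, 32, 32, byrow = TRUE)
    cross <- cross + m + t(m)   # neighbours on both sides
  }
  pos <- N > 0
  R[pos, ] <- R[pos, ] + cross[pos, , drop = FALSE] / N[pos]
  list(N = N, R = R)
}

## deterministic apportionment of n mutations to the 32 trinucleotide
## classes implied by an SBS96 signature, largest-remainder method,
## processed in decreasing class-probability order
apportion_classes <- function(signature, n) {
  sig <- normalize_signature(signature, sbs96_channels())
  ctx <- parse_sbs_channels()$ctx
  p32 <- vapply(1:32, function(t) sum(sig[ctx == t]), numeric(1))
  raw <- p32 * n
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    frac <- raw - k
    ord <- order(frac, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1L
  }
  ord <- order(p32, decreasing = TRUE)
  classes <- rep(ord, k[ord])
  list(classes = classes, k = k, p32 = p32)
}

#' Sequential probability of observing no adjacent double substitution
#'
#' Computes the probability that `n_sub` substitutions drawn from a
#' signature over a genome produce no two adjacent mutations, using
#' sequential placement with expected-case availability bookkeeping: each
#' placed mutation removes its own position and, in expectation over the
#' genome's neighbour composition, its two neighbours. Mutations are
#' apportioned to trinucleotide classes by the signature's context marginal
#' and processed in decreasing class-probability order.
#'
#' @param n_sub number of substitutions (>= 1).
#' @param profile SBS96 signature (or count profile) of the sample.
#' @param genome a [toy_genome()].
#' @return object of class `doublet_null`: list with `n_substitutions`,
#'   `p_no_doublet`, `p_at_least_one`, `method = "sequential"`.
#' @export
prob_no_doublet <- function(n_sub, profile, genome) {
  if (n_sub < 1L) stop("n_sub must be at least 1")
  st <- doublet_genome_stats(genome)
  ap <- apportion_classes(profile, n_sub)
  if (any(ap$p32 > 0 & st$N == 0))
    stop("profile has positive probability on trinucleotide class(es) absent ",
         "from the genome: ",
         paste(trinuc32_names()[ap$p32 > 0 & st$N == 0], collapse = ", "))
  A <- st$N      # available (non-adjacent, unused) positions, in expectation
  Nrem <- st$N   # remaining distinct positions per class
  p <- 1
  for (t in ap$classes) {
    if (Nrem[t] <= 0)
      stop("n_sub exceeds the eligible positions of class ",
           trinuc32_names()[t])
    p <- p * max(0, A[t]) / Nrem[t]
    A <- A - st$R[t, ]
    Nrem[t] <- Nrem[t] - 1
  }
  structure(list(n_substitutions = as.integer(n_sub),
                 p_no_doublet = p, p_at_least_one = 1 - p,
                 method = "sequential", mc_se = NA_real_),
            class = "doublet_null")
}

#' @export
print.doublet_null <- function(x, ...) {
  cat(sprintf("doublet_null (%s): n_sub = %d, P(no doublet) = %.4g, P(>=1) = %.4g\n",
              x$method, x$n_substitutions, x$p_no_doublet, x$p_at_least_one))
  invisible(x)
}

## positions of each trinucleotide class, per contig, with flat ids
class_positions <- function(genome) {
  genome$sites_by_ctx
}

#' Monte-Carlo oracle for the doublet chance probability
#'
#' Repeatedly places `n_sub` mutations at uniformly chosen positions
#' matching the profile's trinucleotide mix, without replacement within each
#' class, and reports the fraction of replicates containing at least one
#' adjacent pair, with its binomial standard error.
#'
#' @param n_sub number of substitutions.
#' @param profile SBS96 signature of the sample.
#' @param genome a [toy_genome()].
#' @param n_reps number of Monte-Carlo replicates (>= 1000).
#' @param seed optional seed.
#' @return `doublet_null` object with `method = "monte_carlo"` and `mc_se`.
#' @export
mc_doublet_oracle <- function(n_sub, profile, genome, n_reps = 1e5,
                              seed = NULL) {
  if (n_reps < 1000) stop("n_reps must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  ap <- apportion_classes(profile, n_sub)
  sites <- class_positions(genome)
  use <- which(ap$k > 0L)
  for (t in use)
    if (length(sites[[t]]) < ap$k[t])
      stop("n_sub exceeds the eligible positions of class ",
           trinuc32_names()[t])
  ## contig boundaries in flat coordinates: adjacency never crosses them,
  ## and flat ids are contiguous within a contig, so diff == 1 suffices
  ## except across offsets; mask boundary pairs explicitly
  boundary <- cumsum(genome$lengths)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    pos <- unlist(lapply(use, function(t) {
      s <- sites[[t]]
      s[sample.int(length(s), ap$k[t])]
    }), use.names = FALSE)
    pos <- sort.int(pos)
    d <- which(diff(pos) == 1L)
    if (length(d) && any(!(pos[d] %in% boundary))) hits <- hits + 1L
  }
  est <- hits / n_reps
  structure(list(n_substitutions = as.integer(n_sub),
                 p_no_doublet = 1 - est, p_at_least_one = est,
                 method = "monte_carlo",
                 mc_se = sqrt(est * (1 - est) / n_reps)),
            class = "doublet_null")
}

#' Exhaustive enumeration of the doublet chance probability
#'
#' Enumerates every way of choosing the apportioned number of positions per
#' trinucleotide class (uniform without replacement within class) and
#' returns the exact probability that no two chosen positions are adjacent.
#' Only feasible for tiny genomes; used as the brute-force oracle.
#'
#' @param n_sub number of substitutions.
#' @param profile SBS96 signature.
#' @param genome a small [toy_genome()].
#' @param max_combos guard on the number of enumerated configurations.
#' @return `doublet_null` object with `method = "enumeration"`.
#' @export
enum_doublet_prob <- function(n_sub, profile, genome, max_combos = 2e6) {
  ap <- apportion_classes(profile, n_sub)
  sites <- class_positions(genome)
  use <- which(ap$k > 0L)
  combos <- lapply(use, function(t) {
    s <- sites[[t]]
    if (length(s) < ap$k[t])
      stop("n_sub exceeds the eligible positions of class ",
           trinuc32_names()[t])
    if (length(s) == ap$k[t]) return(list(s))
    utils::combn(s, ap$k[t], simplify = FALSE)
  })
  n_total <- prod(vapply(combos, length, numeric(1)))
  if (n_total > max_combos)
    stop("enumeration too large (", n_total, " configurations)")
  boundary <- cumsum(genome$lengths)
  grid <- expand.grid(lapply(combos, seq_along))
  good <- 0L
  for (i in seq_len(nrow(grid))) {
    pos <- sort.int(unlist(lapply(seq_along(use), function(j)
      combos[[j]][[grid[i, j]]]), use.names = FALSE))
    d <- which(diff(pos) == 1L)
    if (!length(d) || all(pos[d] %in% boundary)) good <- good + 1L
  }
  p <- good / n_total
  structure(list(n_substitutions = as.integer(n_sub),
                 p_no_doublet = p, p_at_least_one = 1 - p,
                 method = "enumeration", mc_se = NA_real_),
            class = "doublet_null")
}

#' Test whether observed doublets exceed the chance expectation
#'
#' Converts the null P(no doublet) into a Poisson rate for chance adjacent
#' pairs (`lambda = -log p_no_doublet`) and reports the upper-tail
#' probability of observing at least the observed count.
#'
#' @param observed_doublets observed count of adjacent double substitutions.
#' @param null a `doublet_null` for the sample's substitution number.
#' @param alpha enrichment significance level.
#' @return data.frame: observed, expected_pairs, p_at_least_one, p_tail,
#'   enriched.
#' @export
doublet_excess_test <- function(observed_doublets, null, alpha = 0.01) {
  lambda <- -log(max(null$p_no_doublet, .Machine$double.xmin))
  p_tail <- if (observed_doublets <= 0) 1 else
    stats::ppois(observed_doublets - 1, lambda, lower.tail = FALSE)
  data.frame(observed = observed_doublets,
             expected_pairs = lambda,
             p_at_least_one = null$p_at_least_one,
             p_tail = p_tail,
             enriched = p_tail < alpha)
}
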
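#' Parameters of the linear birth (Yule) clone-growth process
#'
#' Clone growth within a tumor is modeled as a pure linear birth process:
#' every cell of a clone divides independently at constant rate
#' \code{birth_rate} (lambda) for a growth period \code{duration} (T).
#' Starting from a single founder cell, the clone size at time T is
#' geometric on \{1, 2, ...\} with success parameter
#' \eqn{q = \exp(-\lambda T)}; only the product \eqn{\lambda T} is
#' identifiable, and all downstream inference is parameterized by q.
#'
#' @param birth_rate Per-cell division rate (divisions per unit time, >= 0).
#' @param duration Growth time per xenograft generation (> 0).
#' @return An object of class \code{"birth_params"} with elements
#'   \code{birth_rate}, \code{duration} and the derived geometric survival
#'   parameter \code{q = exp(-birth_rate * duration)}.
#' @examples
#' bp <- birth_params(birth_rate = 1, duration = 1)
#' bp$q  # exp(-1)
#' @export
birth_params <- function(birth_rate, duration) {
  stopifnot(is.numeric(birth_rate), length(birth_rate) == 1L, is.finite(birth_rate),
            is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (birth_rate < 0) stop("birth_rate must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(birth_rate = birth_rate, duration = duration,
                 q = exp(-birth_rate * duration)),
            class = "birth_params")
}

#' @export
print.birth_params <- function(x, ...) {
  cat(sprintf("Yule birth process: lambda = %g, T = %g (q = exp(-lambda*T) = %g, mean size = %g)\n",
              x$birth_rate, x$duration, x$q, 1 / x$q))
  invisible(x)
}

#' Sampling plan for integration-site analysis of a tumor
#'
#' Captures how a dissociated tumor is assayed: the fraction of cells used
#' for IS analysis, the sequencing depth, and the relative-abundance cutoff
#' below which an IS call is considered invalid.
#'
#' @param fraction_sampled Proportion f of dissociated cells used for IS
#'   analysis, in (0, 1]. The study sampled 3--30% of cells.
#' @param read_depth Total sequence reads per sample (integer > 0).
#' @param cutoff Minimum relative read abundance for a valid IS call,
#'   default 0.0006 (0.06% of total sequence counts).
#' @return An object of class \code{"sampling_plan"}.
#' @export
sampling_plan <- function(fraction_sampled, read_depth = 10000L, cutoff = 6e-4) {
  stopifnot(is.numeric(fraction_sampled), length(fraction_sampled) == 1L,
            is.numeric(read_depth), length(read_depth) == 1L,
            is.numeric(cutoff), length(cutoff) == 1L)
  if (fraction_sampled <= 0 || fraction_sampled > 1)
    stop("fraction_sampled must be in (0, 1]")
  if (read_depth < 1) stop("read_depth must be a positive integer")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  structure(list(fraction_sampled = fraction_sampled,
                 read_depth = as.integer(round(read_depth)),
                 cutoff = cutoff),
            class = "sampling_plan")
}

#' Probability mass function of the Yule clone-size distribution
#'
#' Probability that a clone founded by a single cell has exactly \code{k}
#' cells after the growth period, \eqn{P(Z(T) = k) = q (1-q)^{k-1}} with
#' \eqn{q = \exp(-\lambda T)}. The distribution has mean \eqn{\exp(\lambda T)}.
#'
#' @param k Clone size(s), positive integer(s).
#' @param params A [birth_params()] object.
#' @return Vector of probabilities, same length as \code{k}.
#' @examples
#' yule_size_pmf(1:5, birth_params(0.5, 2))
#' @export
yule_size_pmf <- function(k, params) {
  stopifnot(inherits(params, "birth_params"))
  if (any(k < 1) || any(k != floor(k))) stop("k must be a positive integer")
  stats::dgeom(k - 1, prob = params$q)
}

#' Sample clone sizes from the Yule distribution
#'
#' Direct i.i.d. sampler for the clone-size law of [yule_size_pmf()]
#' (geometric on \{1, 2, ...\} with parameter \code{q}).
#'
#' @param params A [birth_params()] object.
#' @param n_clones Number of clones to draw (>= 0).
#' @return Integer-valued vector of \code{n_clones} clone sizes.
#' @export
yule_size_sample <- function(params, n_clones) {
  stopifnot(inherits(params, "birth_params"), n_clones >= 0)
  if (n_clones == 0) return(numeric(0))
  # numeric, not integer: sizes can exceed .Machine$integer.max for large lambda*T
  stats::rgeom(n_clones, prob = params$q) + 1
}

#' Event-driven (Gillespie) simulation of one Yule clone
#'
#' Exact realization of the linear birth process by simulating successive
#' division events: with current size z the waiting time to the next
#' division is exponential with rate \code{lambda * z}. Serves as an
#' independent oracle for [yule_size_sample()].
#'
#' @param params A [birth_params()] object.
#' @param max_mean_size Guard on the expected final size \eqn{\exp(\lambda T)};
#'   exceeding it aborts (runaway simulation).
#' @return Final clone size (integer >= 1).
#' @export
gillespie_yule <- function(params, max_mean_size = 1e6) {
  stopifnot(inherits(params, "birth_params"))
  lam <- params$birth_rate
  if (lam == 0) return(1L)
  if (exp(lam * params$duration) > max_mean_size)
    stop("expected clone size exp(lambda*T) exceeds max_mean_size guard")
  t <- 0
  z <- 1L
  repeat {
    t <- t + stats::rexp(1L, rate = lam * z)
    if (t > params$duration) return(z)
    z <- z + 1L
  }
}

#' Binomial engraftment of transplanted candidate cells
#'
#' Each transplanted marked cell independently engrafts (seeds a clone)
#' with probability \code{seeding_prob}; the number of engrafting clones is
#' binomial.
#'
#' @param n_candidate_cells Number of transplanted candidate cells (>= 0).
#' @param seeding_prob Per-cell engraftment probability in \[0, 1\].
#' @return Integer count of engrafting clones.
#' @export
seed_clones <- function(n_candidate_cells, seeding_prob) {
  stopifnot(n_candidate_cells >= 0, seeding_prob >= 0, seeding_prob <= 1)
  stats::rbinom(1L, size = n_candidate_cells, prob = seeding_prob)
}

#' Subsample a tumor for integration-site analysis
#'
#' Per-cell binomial thinning: each cell of each clone is independently
#' included in the IS-analysis aliquot with probability
#' \code{plan$fraction_sampled}. At tumor sizes far exceeding sample sizes
#' this is indistinguishable from exact without-replacement sampling.
#'
#' @param clone_sizes Vector of clone cell counts (>= 0).
#' @param plan A [sampling_plan()] object.
#' @return Vector of per-clone sampled cell counts.
#' @export
sample_tumor <- function(clone_sizes, plan) {
  stopifnot(inherits(plan, "sampling_plan"), all(clone_sizes >= 0))
  if (length(clone_sizes) == 0) return(numeric(0))
  if (plan$fraction_sampled == 1) return(clone_sizes)
  stats::rbinom(length(clone_sizes), size = clone_sizes, prob = plan$fraction_sampled)
}

# smallest sampled-cell count that clears the relative-abundance cutoff,
# with sampled-cell share s / (f * tumor_size) standing in for read share
min_detectable_count <- function(plan, tumor_size) {
  max(1, ceiling(plan$cutoff * plan$fraction_sampled * tumor_size - 1e-9))
}

#' Per-clone detection probability under the composite observation model
#'
#' Probability that a single engrafted clone is called in the IS table of a
#' tumor: its size Z is Yule(\code{params}); sampled cells S ~ Binomial(Z, f);
#' the clone is called iff S >= 1 and its sampled-cell share
#' S / (f * tumor_size) is at least the cutoff c. This is the success
#' probability p of the binomial detection model B(n, p) used for
#' clone-count inference. Computed by direct summation over Z with the
#' geometric tail truncated below \code{tol}.
#'
#' @param params A [birth_params()] object.
#' @param plan A [sampling_plan()] object.
#' @param tumor_size Total tumor cell count used to convert the cutoff to a
#'   minimum sampled-cell count.
#' @param tol Truncation tolerance for the tail of the size distribution.
#' @param max_terms Guard on the number of summation terms.
#' @return Detection probability in \[0, 1\].
#' @export
detection_probability <- function(params, plan, tumor_size, tol = 1e-12,
                                  max_terms = 1e7) {
  stopifnot(inherits(params, "birth_params"), inherits(plan, "sampling_plan"),
            tumor_size >= 1)
  q <- params$q
  f <- plan$fraction_sampled
  s_min <- min_detectable_count(plan, tumor_size)
  if (q == 1) {                       # all clones single cells
    return(if (s_min <= 1) f else 0)
  }
  # two truncation points: K_geom where the remaining geometric mass
  # (1-q)^K drops below tol, and K_det where detection given size k is
  # within tol of 1 (detection is monotone in k, so the tail beyond K_det
  # can be counted as fully detected with error <= tol)
  K_geom <- ceiling(log(tol) / log1p(-q))
  lo <- s_min; hi <- s_min
  while (stats::pbinom(s_min - 1, hi, f) > tol && hi < max_terms) {
    lo <- hi; hi <- 2 * hi
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (stats::pbinom(s_min - 1, mid, f) > tol) lo <- mid else hi <- mid
  }
  K <- min(K_geom, hi)
  if (K > max_terms)
    stop("truncation tolerance not reachable within max_terms guard")
  k <- seq_len(K)
  pmf <- stats::dgeom(k - 1, prob = q)
  p_call <- stats::pbinom(s_min - 1, size = k, prob = f, lower.tail = FALSE)
  out <- sum(pmf * p_call)
  if (K < K_geom) out <- out + (1 - q)^K   # tail: detection within tol of 1
  min(out, 1)
}
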
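#' Confidence rectangle for the nuisance parameters (q, f)
#'
#' Clone-count inference and the homogeneity tests treat two quantities as
#' unobservable nuisance parameters: the Yule geometric survival parameter
#' \eqn{q = \exp(-\lambda T)} and the effective sampling fraction f. A
#' confidence rectangle over (q, f) with joint coverage
#' \code{joint_coverage} is scanned on a grid; the final p-values and
#' bounds are suprema over the grid, and the total error budget is split
#' between the rectangle and the binomial inversion by \code{alpha_split}
#' (Bonferroni).
#'
#' @param q_interval Interval for q, within (0, 1\].
#' @param f_interval Interval for f, within (0, 1\].
#' @param joint_coverage Confidence level of the rectangle.
#' @param alpha_split Fraction of the total alpha allocated to the binomial
#'   inversion (the remainder budgets the rectangle).
#' @return Object of class \code{"nuisance_rectangle"}.
#' @export
nuisance_rectangle <- function(q_interval, f_interval,
                               joint_coverage = 0.995, alpha_split = 0.5) {
  stopifnot(length(q_interval) == 2, length(f_interval) == 2,
            all(q_interval > 0), all(q_interval <= 1),
            all(f_interval > 0), all(f_interval <= 1),
            q_interval[1] <= q_interval[2], f_interval[1] <= f_interval[2],
            joint_coverage > 0, joint_coverage < 1,
            alpha_split > 0, alpha_split <= 1)
  structure(list(q_interval = as.numeric(q_interval),
                 f_interval = as.numeric(f_interval),
                 joint_coverage = joint_coverage, alpha_split = alpha_split),
            class = "nuisance_rectangle")
}

rectangle_grid <- function(rectangle, resolution) {
  qs <- seq(rectangle$q_interval[1], rectangle$q_interval[2],
            length.out = resolution)
  fs <- seq(rectangle$f_interval[1], rectangle$f_interval[2],
            length.out = resolution)
  expand.grid(q = qs, f = fs, KEEP.OUT.ATTRS = FALSE)
}

# detection probability at each (q, f) node of a rectangle grid
p_det_over_grid <- function(grid, plan, tumor_size) {
  vapply(seq_len(nrow(grid)), function(i) {
    params <- birth_params(-log(grid$q[i]), 1)
    node_plan <- sampling_plan(grid$f[i], read_depth = plan$read_depth,
                               cutoff = plan$cutoff)
    detection_probability(params, node_plan, tumor_size)
  }, numeric(1))
}

# f values where the infimum of p_det over an f-interval can sit: the
# interval edges plus the points just past each jump of the integer
# detection bar s_min = ceiling(cutoff * f * tumor_size); within a
# constant-s_min stretch p_det is nondecreasing in f, so the left end of
# each stretch is the local worst case. When the bar is large the jumps
# are negligible and a plain spread of values suffices.
f_scan_values <- function(f_interval, cutoff, tumor_size, resolution,
                          max_breakpoints = 1000L) {
  cn <- cutoff * tumor_size
  s_lo <- ceiling(cn * f_interval[1] - 1e-9)
  s_hi <- ceiling(cn * f_interval[2] - 1e-9)
  fs <- seq(f_interval[1], f_interval[2], length.out = resolution)
  if (s_hi - s_lo >= 1 && s_hi - s_lo <= max_breakpoints) {
    brk <- (seq(s_lo, s_hi - 1) / cn) * (1 + 1e-12) + 1e-15
    fs <- c(fs, brk[brk > f_interval[1] & brk <= f_interval[2]])
  }
  sort(unique(pmin(fs, 1)))
}

#' Exact binomial upper confidence bound for n at known p
#'
#' Largest n such that \eqn{P(K \le k \mid n, p) \ge \alpha} under
#' K ~ Binomial(n, p): the one-sided upper confidence bound for the
#' binomial index parameter n obtained by inverting the exact CDF.
#'
#' @param k Observed count (>= 0).
#' @param p Success probability in (0, 1\].
#' @param alpha Inversion level (one-sided miscoverage).
#' @return Integer upper bound for n (equals \code{k} when \code{p = 1}).
#' @export
binom_n_upper <- function(k, p, alpha) {
  stopifnot(k >= 0, p > 0, p <= 1, alpha > 0, alpha < 1)
  if (p >= 1) return(as.integer(k))
  lo <- max(k, 0)                      # pbinom(k, k, p) >= alpha always
  hi <- max(2 * k, 2)
  while (stats::pbinom(k, hi, p) >= alpha) { lo <- hi; hi <- 2 * hi }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (stats::pbinom(k, mid, p) >= alpha) lo <- mid else hi <- mid
  }
  as.integer(lo)
}

#' Upper confidence bound on the number of engrafted clones
#'
#' The number of detected IS in a tumor is modeled as
#' K ~ Binomial(n, p_det(q, f)) where n is the unknown number of engrafted
#' clones and p_det is the composite detection probability
#' ([detection_probability()]). For every (q, f) node on a grid over the
#' nuisance rectangle the exact binomial CDF is inverted in n; the bound is
#' the supremum over the grid (attained at the minimal detection
#' probability, as the inversion is monotone in p). A refinement pass at
#' doubled grid resolution guards against a too-coarse grid. Total
#' miscoverage is the rectangle's alpha plus the binomial inversion alpha
#' (Bonferroni, per the rectangle's \code{alpha_split}).
#'
#' @param k_observed Number of detected IS (>= 0).
#' @param rectangle A [nuisance_rectangle()] over (q, f).
#' @param plan A [sampling_plan()] providing the read-share cutoff and
#'   depth (its \code{fraction_sampled} is overridden by the grid's f).
#' @param tumor_size Total tumor cell count for the cutoff conversion.
#' @param confidence Total confidence level (default 0.99).
#' @param grid_resolution Grid points per rectangle axis (default 25).
#' @param p_det_grid Optional precomputed detection-probability grids (the
#'   \code{p_det_grid} element of a previous bound at the same design),
#'   for replicated simulation.
#' @return Object of class \code{"clone_count_bound"} with \code{n_upper},
#'   \code{k_observed}, \code{confidence}, \code{alpha_binomial},
#'   \code{p_det_range}, and the reusable \code{p_det_grid}.
#' @export
upper_bound_total_clones <- function(k_observed, rectangle, plan, tumor_size,
                                     confidence = 0.99, grid_resolution = 25,
                                     p_det_grid = NULL) {
  stopifnot(k_observed >= 0, inherits(rectangle, "nuisance_rectangle"),
            inherits(plan, "sampling_plan"),
            confidence > 0, confidence < 1)
  alpha_binom <- (1 - confidence) * rectangle$alpha_split
  if (is.null(p_det_grid)) {
    fs <- f_scan_values(rectangle$f_interval, plan$cutoff, tumor_size,
                        grid_resolution)
    qgrid <- function(res) expand.grid(
      q = seq(rectangle$q_interval[1], rectangle$q_interval[2],
              length.out = res),
      f = fs, KEEP.OUT.ATTRS = FALSE)
    p_det_grid <- list(coarse = p_det_over_grid(qgrid(grid_resolution),
                                                plan, tumor_size),
                       fine = p_det_over_grid(qgrid(2L * grid_resolution),
                                              plan, tumor_size))
  }
  n1 <- binom_n_upper(k_observed, min(p_det_grid$coarse), alpha_binom)
  n2 <- binom_n_upper(k_observed, min(p_det_grid$fine), alpha_binom)
  if (abs(n2 - n1) > max(1, 1e-3 * max(n1, n2)))
    stop("nuisance grid too coarse: supremum moved between refinement passes")
  structure(list(k_observed = k_observed, n_upper = max(n1, n2),
                 confidence = confidence, alpha_binomial = alpha_binom,
                 p_det_range = range(p_det_grid$fine),
                 grid_resolution = grid_resolution,
                 p_det_grid = p_det_grid),
            class = "clone_count_bound")
}

#' @export
print.clone_count_bound <- function(x, ...) {
  cat(sprintf("Upper %.0f%% confidence bound on engrafted clones: %d (observed IS: %d, p_det in [%.4g, %.4g])\n",
              100 * x$confidence, x$n_upper, x$k_observed,
              x$p_det_range[1], x$p_det_range[2]))
  invisible(x)
}

#' Seeding efficiency interval from a clone-count bound
#'
#' Converts a clone-count bound into a percentage interval for the seeding
#' efficiency: the fraction of initially transplanted marked cells that
#' engrafted and founded a clone, bounded below by the detected IS count
#' and above by the upper confidence bound on engrafted clones.
#'
#' @param bound A [upper_bound_total_clones()] result.
#' @param n_marked_transplanted Number of marked cells transplanted.
#' @return Object of class \code{"seeding_efficiency"} with
#'   \code{interval_pct} (length-2 percentage interval).
#' @export
seeding_efficiency <- function(bound, n_marked_transplanted) {
  stopifnot(inherits(bound, "clone_count_bound"),
            n_marked_transplanted >= bound$k_observed)
  interval <- 100 * c(bound$k_observed, bound$n_upper) / n_marked_transplanted
  structure(list(bound = bound, n_marked_transplanted = n_marked_transplanted,
                 interval_pct = interval), class = "seeding_efficiency")
}

#' @export
print.seeding_efficiency <- function(x, ...) {
  cat(sprintf("Seeding efficiency: %.4g%% - %.4g%% of %d transplanted marked cells\n",
              x$interval_pct[1], x$interval_pct[2], x$n_marked_transplanted))
  invisible(x)
}

new_clone_test <- function(hypothesis, statistic, p_grid, grid_resolution,
                           mc_replicates, seed, degenerate = FALSE,
                           note = NULL) {
  structure(list(hypothesis = hypothesis, statistic = statistic,
                 p_supremum = if (nrow(p_grid) > 0) max(p_grid$p) else NA_real_,
                 p_grid = p_grid, grid_resolution = grid_resolution,
                 mc_replicates = mc_replicates, seed = seed,
                 degenerate = degenerate, note = note),
            class = "clone_test")
}

#' @export
print.clone_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, supremum p-value = %.4g (grid %dx, %d MC replicates)\n",
              x$hypothesis, x$statistic, x$p_supremum,
              x$grid_resolution, x$mc_replicates))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# reconstruct per-clone sampled cell counts from read shares
shares_to_counts <- function(shares, total_sampled, min_count = 1L) {
  pmax(min_count, round(shares / sum(shares) * total_sampled))
}

# draw n detection-conditioned sampled-cell counts at nuisance node (q, f):
# size ~ Geom(q)+1, sampled ~ Bin(size, f), accepted iff sampled >= s_min
r_detected_counts <- function(n, q, f, s_min) {
  out <- integer(0)
  batch <- max(1000L, 2L * n)
  guard <- 0L
  while (length(out) < n) {
    k <- stats::rgeom(batch, q) + 1
    s <- stats::rbinom(batch, k, f)
    out <- c(out, s[s >= s_min])
    guard <- guard + 1L
    if (guard > 10000L) stop("detection-conditioned sampler: acceptance rate too low")
    batch <- min(1e6L, 2L * batch)
  }
  out[seq_len(n)]
}

# heterogeneity log-likelihood-ratio: per-clone geometric fit (saturated)
# vs common geometric fit, on sampled-cell counts; columns of X are
# bootstrap replicates
llr_geometric_het <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X)
  sat <- colSums(ifelse(X == 1, 0, -log(X) + (X - 1) * log1p(-1 / X)))
  qhat <- 1 / colMeans(X)
  excess <- colSums(X - 1)
  fit <- m * log(qhat) + ifelse(excess == 0, 0, log1p(-qhat) * excess)
  2 * (sat - fit)
}

#' Test of identical proliferation rates within a tumor (within-tumor
#' growth homogeneity)
#'
#' Under the null every detected clone's sampled-cell count is an i.i.d.
#' draw from a detection-truncated Yule size law with a common rate. The
#' statistic is the log-likelihood ratio of a saturated per-clone geometric
#' model against the common fit, computed on sampled-cell counts
#' reconstructed from read shares (per-clone cell counts being
#' unobservable). The null distribution is a parametric bootstrap at each
#' (q, f) node of the nuisance rectangle; the reported p-value is the
#' supremum over the grid.
#'
#' @param shares Read shares of the detected clones of one tumor.
#' @param total_sampled Total sampled cells behind the shares.
#' @param rectangle A [nuisance_rectangle()].
#' @param cutoff Read-share detection cutoff (default 0.0006).
#' @param mc_replicates Bootstrap replicates per grid node.
#' @param grid_resolution Grid points per rectangle axis.
#' @param seed Root seed; node seeds are \code{seed + node index}.
#' @return Object of class \code{"clone_test"} (hypothesis
#'   \code{"H0 equal proliferation"}).
#' @export
test_equal_proliferation <- function(shares, total_sampled, rectangle,
                                     cutoff = 6e-4, mc_replicates = 2000,
                                     grid_resolution = 5, seed = 1) {
  stopifnot(inherits(rectangle, "nuisance_rectangle"), total_sampled >= 1)
  m <- length(shares)
  if (m < 2) {
    warning("fewer than 2 detected clones: no contrast, p = 1")
    return(new_clone_test("H0 equal proliferation", NA_real_,
                          data.frame(q = NA, f = NA, p = 1),
                          grid_resolution, mc_replicates, seed,
                          degenerate = TRUE))
  }
  s_min <- max(1L, ceiling(cutoff * total_sampled - 1e-9))
  x <- shares_to_counts(shares, total_sampled)
  stat_obs <- llr_geometric_het(matrix(x, ncol = 1))
  grid <- rectangle_grid(rectangle, grid_resolution)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    with_seed(seed + i, {
      draws <- r_detected_counts(m * mc_replicates, grid$q[i], grid$f[i], s_min)
      stat_null <- llr_geometric_het(matrix(draws, nrow = m))
      (1 + sum(stat_null >= stat_obs)) / (mc_replicates + 1)
    })
  }, numeric(1))
  new_clone_test("H0 equal proliferation", stat_obs,
                 cbind(grid, p = p), grid_resolution, mc_replicates, seed)
}

#' Test of constant growth rates across a transplantation step
#'
#' Under the null, a clone's expected contribution to the daughter tumor
#' derives from its parent contribution propagated through binomial
#' transplant thinning and common Yule growth of every transplanted cell.
#' The statistic is the multinomial deviance between the observed and the
#' propagated daughter shares over the parent-detected clone set; the null
#' distribution is simulated at each (q, f) nuisance node (transplanted
#' founders binomial, clone regrowth negative-binomial, daughter sampling
#' multinomial with the detection cutoff applied), and the reported
#' p-value is the supremum over the grid.
#'
#' @param parent_shares Named read shares of clones detected in the parent
#'   tumor.
#' @param daughter_shares Named read shares of clones detected in the
#'   daughter tumor (names matched against the parent's).
#' @param transplant_fraction Fraction of the parent tumor's cells injected
#'   into the daughter mouse.
#' @param parent_total_sampled,daughter_total_sampled Total sampled cells
#'   behind the two share vectors.
#' @inheritParams test_equal_proliferation
#' @return Object of class \code{"clone_test"} (hypothesis
#'   \code{"H0 constant growth"}). If no parent clone reappears in the
#'   daughter the test is degenerate and flagged.
#' @export
test_constant_growth <- function(parent_shares, daughter_shares,
                                 transplant_fraction,
                                 parent_total_sampled, daughter_total_sampled,
                                 rectangle, cutoff = 6e-4,
                                 mc_replicates = 2000, grid_resolution = 5,
                                 seed = 1) {
  stopifnot(inherits(rectangle, "nuisance_rectangle"),
            transplant_fraction > 0, transplant_fraction <= 1,
            !is.null(names(parent_shares)))
  m <- length(parent_shares)
  x <- shares_to_counts(parent_shares, parent_total_sampled)
  y <- rep(0, m)
  hit <- match(names(parent_shares), names(daughter_shares))
  y[!is.na(hit)] <- round(daughter_shares[hit[!is.na(hit)]] /
                            sum(daughter_shares) * daughter_total_sampled)
  deg <- sum(y) == 0
  if (deg) {
    warning("no parent clone detected in the daughter tumor; constant-growth test degenerates to seeding-homogeneity reporting")
    return(new_clone_test("H0 constant growth", NA_real_,
                          data.frame(q = NA, f = NA, p = NA_real_),
                          grid_resolution, mc_replicates, seed,
                          degenerate = TRUE,
                          note = "no shared clones between parent and daughter"))
  }
  s_min_d <- max(1L, ceiling(cutoff * daughter_total_sampled - 1e-9))
  deviance_stat <- function(yy, p_exp) {
    n_eff <- sum(yy)
    if (n_eff == 0) return(0)
    nz <- yy > 0
    2 * sum(yy[nz] * log(yy[nz] / (n_eff * p_exp[nz])))
  }
  p_exp <- x / sum(x)
  stat_obs <- deviance_stat(y, p_exp)
  grid <- rectangle_grid(rectangle, grid_resolution)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    with_seed(seed + i, {
      q <- grid$q[i]; f <- grid$f[i]
      n_cells <- pmax(1, round(x / f))      # parent tumor cells per clone
      total_x <- sum(x)
      stat_null <- vapply(seq_len(mc_replicates), function(b) {
        # parent aliquot is itself a noisy sample: resample it too, so the
        # null distribution carries both parent- and daughter-side noise
        xstar <- pmax(1, drop(stats::rmultinom(1L, total_x, prob = n_cells)))
        t_founders <- stats::rbinom(m, n_cells, transplant_fraction)
        S <- t_founders
        pos <- t_founders > 0
        S[pos] <- S[pos] + stats::rnbinom(sum(pos), size = t_founders[pos],
                                          prob = q)
        if (sum(S) == 0) return(0)
        ystar <- drop(stats::rmultinom(1L, daughter_total_sampled, prob = S))
        ystar[ystar < s_min_d] <- 0
        deviance_stat(ystar, xstar / sum(xstar))
      }, numeric(1))
      (1 + sum(stat_null >= stat_obs)) / (mc_replicates + 1)
    })
  }, numeric(1))
  new_clone_test("H0 constant growth", stat_obs,
                 cbind(grid, p = p), grid_resolution, mc_replicates, seed)
}

#' Test of equal seeding efficiencies across clones
#'
#' Under the null every transplanted cell engrafts with a common rate s, so
#' a clone with t transplanted cells engrafts with probability
#' 1 - (1-s)^t. Conditional on the number of engrafting clones, the test
#' resamples engraftment label sets by successive weighted sampling with
#' the odds implied by each candidate s (for small s this is sampling
#' weighted by clone size), using a centered two-sided Monte-Carlo p-value
#' for the size-engraftment association statistic, taken as a supremum
#' over a grid of common rates s around the moment-matched estimate
#' (the per-clone transplanted sizes being themselves reconstructions).
#'
#' @param transplanted_sizes Estimated transplanted cell count per clone.
#' @param engrafted Logical vector: did the clone found a detectable clone
#'   in the recipient?
#' @param mc_replicates Monte-Carlo replicates per grid node.
#' @param grid_resolution Number of candidate rates s in the supremum grid.
#' @param seed Root seed.
#' @return Object of class \code{"clone_test"} (hypothesis
#'   \code{"H0 equal seeding"}).
#' @export
test_equal_seeding <- function(transplanted_sizes, engrafted,
                               mc_replicates = 2000, grid_resolution = 5,
                               seed = 1) {
  stopifnot(length(transplanted_sizes) == length(engrafted),
            all(transplanted_sizes >= 1))
  n <- length(engrafted)
  m <- sum(engrafted)
  z <- log(transplanted_sizes)
  if (m == 0 || m == n || stats::sd(z) == 0) {
    return(new_clone_test("H0 equal seeding", NA_real_,
                          data.frame(s = NA, p = 1),
                          grid_resolution, mc_replicates, seed,
                          degenerate = TRUE,
                          note = "all or none engrafted (or no size contrast): no information against a common rate"))
  }
  z <- as.numeric(scale(z))
  stat_obs <- sum(z[engrafted])
  # moment-matched common rate: E[# engrafted clones] = m
  mean_engrafted <- function(v) {
    s <- stats::plogis(v)
    sum(-expm1(transplanted_sizes * log1p(-pmin(s, 1 - 1e-12))))
  }
  v_hat <- stats::uniroot(function(v) mean_engrafted(v) - m,
                          lower = -60, upper = 30, tol = 1e-8)$root
  vs <- v_hat + seq(-1.5, 1.5, length.out = grid_resolution)
  p <- vapply(seq_along(vs), function(i) {
    with_seed(seed + i, {
      s <- stats::plogis(vs[i])
      p_i <- pmin(-expm1(transplanted_sizes * log1p(-pmin(s, 1 - 1e-12))),
                  1 - 1e-12)
      w <- p_i / (1 - p_i)
      stat_null <- vapply(seq_len(mc_replicates), function(b) {
        sum(z[sample.int(n, m, prob = w)])
      }, numeric(1))
      ctr <- mean(stat_null)
      (1 + sum(abs(stat_null - ctr) >= abs(stat_obs - ctr))) /
        (mc_replicates + 1)
    })
  }, numeric(1))
  new_clone_test("H0 equal seeding", stat_obs,
                 data.frame(s = stats::plogis(vs), p = p),
                 grid_resolution, mc_replicates, seed)
}
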
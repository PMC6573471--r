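#' Establishment probability of a seeded invasion
#'
#' An insertion segregating at frequency `1/(2N)` escapes stochastic loss
#' with probability approximately `2u` for small transposition rates, so
#' the probability that an invasion seeded with `n` such insertions
#' establishes is `pe = 1 - pl^n` with `pl = max(0, 1 - 2u)`.
#'
#' @param u transposition rate per copy per generation.
#' @param n number of insertions in the starting population.
#' @return establishment probability in \[0, 1\] (vectorised over `u` and
#'   `n`).
#' @examples
#' establishment_probability(0.01, 10)  # 0.183
#' establishment_probability(0.1, 10)   # 0.893
#' @export
establishment_probability <- function(u, n) {
  if (any(u < 0) || any(n < 0)) stop("u and n must be >= 0")
  pl <- pmax(0, 1 - 2 * u)
  1 - pl^n
}

#' Expected fraction of individuals with an active TE
#'
#' Under Hardy-Weinberg random union of gametes, an individual escapes all
#' segregating cluster insertions (and so keeps an active TE) with
#' probability `fa = prod((1 - p_i)^2)` over the cluster-site frequencies
#' `p_i`.
#'
#' @param freqs numeric vector of cluster-insertion population frequencies
#'   in \[0, 1\].
#' @return probability in \[0, 1\]; `1` for an empty vector.
#' @examples
#' fraction_active(c(0.5, 0.5))  # 0.0625
#' @export
fraction_active <- function(freqs) {
  if (length(freqs) == 0) return(1)
  if (any(freqs < 0) || any(freqs > 1)) stop("frequencies must be in [0, 1]")
  prod((1 - freqs)^2)
}

#' Annotate the three invasion phases
#'
#' Splits a trajectory into the rapid-invasion, shotgun and inactive
#' phases.  The shotgun phase starts at the first generation at which at
#' least `threshold` (default 99\%) of individuals carry a cluster
#' insertion; the inactive phase starts at the first generation with a
#' fixed cluster insertion.  Later phases may be absent if the trajectory
#' never reaches the boundary.  Per phase, the annotation reports its
#' length, the diploid TE abundance and cluster-insertion abundance at its
#' start, and its stability, measured as the standard deviation of the
#' per-generation population-mean TE abundance within the phase.
#'
#' @param traj a `te_trajectory`.
#' @param threshold shotgun-onset threshold on [fraction_with_cluster()].
#' @return object of class `phase_annotation`: a data.frame with one row
#'   per observed phase and columns `phase`, `start`, `end`, `length`,
#'   `abundance_start`, `cluster_start`, `stability`.
#' @export
annotate_phases <- function(traj, threshold = 0.99) {
  rec <- traj$records
  if (nrow(rec) == 0) stop("empty trajectory")
  gen <- rec$generation
  i_sh <- which(rec$frac_cluster >= threshold)[1]
  i_fix <- which(rec$fixed_cluster >= 1)[1]
  last <- nrow(rec)

  bounds <- list()
  i_end_rapid <- min(i_sh - 1, i_fix - 1, last, na.rm = TRUE)
  if (i_end_rapid >= 1)
    bounds$rapid_invasion <- c(1, i_end_rapid)
  if (!is.na(i_sh) && (is.na(i_fix) || i_sh < i_fix))
    bounds$shotgun <- c(i_sh, min(i_fix - 1, last, na.rm = TRUE))
  if (!is.na(i_fix))
    bounds$inactive <- c(i_fix, last)

  rows <- lapply(names(bounds), function(ph) {
    b <- bounds[[ph]]
    idx <- b[1]:b[2]
    data.frame(phase = ph, start = gen[b[1]], end = gen[b[2]],
               length = gen[b[2]] - gen[b[1]] + 1,
               abundance_start = rec$mean_n[b[1]],
               cluster_start = rec$mean_cluster[b[1]],
               stability = stats::sd(rec$mean_n[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_annotation", "data.frame")
  out
}

#' Classify the outcome of an invasion
#'
#' Assigns one of four principal outcomes at an evaluation generation:
#' \describe{
#'   \item{lost}{all TE copies removed from the population.}
#'   \item{extinct}{population mean fitness dropped below 0.1.}
#'   \item{three_phase}{a cluster insertion fixed (TE permanently
#'     inactivated), or at least 99\% of individuals carry a cluster
#'     insertion (the invasion is in or past the shotgun phase).}
#'   \item{tsc_balance}{transposition-selection-cluster balance: copies
#'     persist, no cluster insertion fixed, fewer than 99\% of individuals
#'     carry a cluster insertion, and the mean copy number is stable over
#'     the trailing window (|OLS slope| below `slope_tol`).}
#'   \item{transient}{none of the above (still growing or shrinking).}
#' }
#' A quadrant label from the effectiveness of transposition and selection
#' (`N*u` vs 1 and `N*x` vs 1) is attached.
#'
#' @param traj a `te_trajectory`.
#' @param eval_generation generation at which to evaluate (default: last
#'   recorded).
#' @param window trailing fraction of generations used for the stability
#'   test.
#' @param slope_tol stability tolerance on the OLS slope, in copies per
#'   generation.
#' @param min_abundance minimum mean diploid copy number for a plateau to
#'   count as balance; a handful of copies lingering before loss is
#'   classified `transient` instead.
#' @return list with `outcome`, `quadrant` (1: Nu>1 & Nx>1, 2: Nu>1 only,
#'   3: neither, 4: Nx>1 only), `Nu`, `Nx`, `slope`.
#' @export
classify_outcome <- function(traj, eval_generation = NULL, window = 0.2,
                             slope_tol = 1e-3, min_abundance = 1) {
  rec <- traj$records
  p <- traj$params
  if (!is.null(eval_generation))
    rec <- rec[rec$generation <= eval_generation, , drop = FALSE]
  if (nrow(rec) == 0) stop("trajectory has no records before eval_generation")
  last <- rec[nrow(rec), ]
  Nu <- p$N * p$u
  Nx <- p$N * p$x
  quadrant <- if (Nu > 1 && Nx > 1) 1L else if (Nu > 1) 2L else
    if (Nx > 1) 4L else 3L

  slope <- NA_real_
  outcome <- if (traj$status == "lost" || last$mean_n == 0) {
    "lost"
  } else if (traj$status == "extinct" || last$mean_w < 0.1) {
    "extinct"
  } else if (last$fixed_cluster >= 1) {
    "three_phase"
  } else if (last$frac_cluster >= 0.99) {
    "three_phase"
  } else {
    tail_idx <- which(rec$generation >=
                        (1 - window) * rec$generation[nrow(rec)])
    slope <- unname(stats::coef(stats::lm(
      rec$mean_n[tail_idx] ~ rec$generation[tail_idx]))[2])
    if (is.finite(slope) && abs(slope) < slope_tol &&
        last$mean_n >= min_abundance) "tsc_balance"
    else "transient"
  }
  list(outcome = outcome, quadrant = quadrant, Nu = Nu, Nx = Nx,
       slope = slope)
}

#' Scan the (u, x) parameter space
#'
#' Draws transposition rates and selection coefficients log-uniformly from
#' the given ranges, runs one invasion per point seeded with
#' `n_seed` insertions at frequency `1/(2N)`, and records the outcome at
#' the final generation.
#'
#' @param arch a [build_architecture()] object.
#' @param u_range,x_range length-2 positive ranges for the log-uniform
#'   draws.
#' @param n_points number of (u, x) points.
#' @param generations generations per invasion.
#' @param N population size.
#' @param model fitness model kind.
#' @param n_seed seed insertions per invasion.
#' @param seed master seed.
#' @param slope_tol passed to [classify_outcome()].
#' @return data.frame with columns `u`, `x`, `N`, `Nu`, `Nx`, `outcome`,
#'   `quadrant`.
#' @export
parameter_space_scan <- function(arch, u_range = c(1e-3, 1),
                                 x_range = c(1e-4, 0.1), n_points = 50,
                                 generations = 10000, N = 1000,
                                 model = "linear", n_seed = 1000, seed = 1,
                                 slope_tol = 1e-3) {
  if (any(u_range <= 0) || any(x_range <= 0))
    stop("ranges must be positive for log-uniform sampling")
  set.seed(seed)
  u <- exp(stats::runif(n_points, log(u_range[1]), log(u_range[2])))
  x <- exp(stats::runif(n_points, log(x_range[1]), log(x_range[2])))
  out <- vector("list", n_points)
  for (i in seq_len(n_points)) {
    p <- simulation_params(u = u[i], x = x[i], model = model, N = N,
                           n_seed = n_seed, generations = generations)
    traj <- run_invasion(arch, p, seed = replicate_seed(seed, i),
                         full_stats_interval = 50L)
    cls <- classify_outcome(traj, slope_tol = slope_tol)
    out[[i]] <- data.frame(u = u[i], x = x[i], N = N, Nu = cls$Nu,
                           Nx = cls$Nx, outcome = cls$outcome,
                           quadrant = cls$quadrant,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Selection contrast between cluster, reference and genomic insertions
#'
#' Pools allele frequencies by site class over a set of populations and
#' compares the classes with two-sided two-sample Wilcoxon rank-sum tests.
#' Because reference-region insertions are strictly neutral markers, a
#' cluster-vs-reference frequency difference diagnoses selection on
#' cluster insertions (lower: negatively selected; higher: positively
#' selected).
#'
#' @param pops list of `te_population` objects (e.g. final populations of
#'   replicate runs).
#' @param arch the matching architecture; must include reference regions.
#' @param by unit of the rank-sum comparison: `"replicate"` (default)
#'   compares the per-replicate mean frequencies of the two classes, one
#'   observation per population; `"site"` pools individual site
#'   frequencies across populations.
#' @return list with `mean_freq` (named vector over classes), `n_sites`
#'   (occupied sites per class, pooled), and `tests`, a data.frame of
#'   pairwise rank-sum p-values.
#' @export
selection_contrast <- function(pops, arch, by = c("replicate", "site")) {
  by <- match.arg(by)
  if (arch$total_ref_bp <= 0)
    stop("architecture has no reference regions")
  afs <- lapply(pops, allele_frequencies, arch = arch)
  af <- do.call(rbind, afs)
  classes <- c("CLUSTER", "REFERENCE", "GENOMIC")
  pooled <- lapply(classes, function(cl) af$freq[af$class == cl])
  names(pooled) <- classes
  if (by == "replicate") {
    samples <- lapply(classes, function(cl) {
      v <- vapply(afs, function(a) mean(a$freq[a$class == cl]), numeric(1))
      v[!is.na(v)]
    })
    names(samples) <- classes
  } else {
    samples <- pooled
  }
  pairs <- utils::combn(classes, 2)
  tests <- data.frame(
    class_a = pairs[1, ], class_b = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      a <- samples[[pr[1]]]; b <- samples[[pr[2]]]
      if (length(a) == 0 || length(b) == 0) return(NA_real_)
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }),
    stringsAsFactors = FALSE)
  list(mean_freq = vapply(pooled, function(f) mean(f), numeric(1)),
       n_sites = vapply(pooled, length, integer(1)),
       by = by, tests = tests)
}

#' Shotgun-phase onset over replicate invasions
#'
#' Locates the onset of the shotgun phase for a set of replicate
#' trajectories and reports the mean number of cluster insertions per
#' diploid at onset.  Two conventions are supported: `"averaged"` finds
#' the first generation at which the replicate-averaged fraction of
#' cluster-carrying individuals reaches the threshold (one common onset
#' generation, the convention behind published onset statistics);
#' `"per_replicate"` applies the threshold to each replicate separately,
#' as [annotate_phases()] does.
#'
#' @param trajs a `te_replicates` object or list of `te_trajectory`
#'   sharing the same recorded generations.
#' @param threshold onset threshold on the fraction of individuals with a
#'   cluster insertion.
#' @param convention `"averaged"` or `"per_replicate"`.
#' @return list with `generation` (onset generation; `NA` if never
#'   reached; a vector for the per-replicate convention), `cluster_mean`
#'   and `cluster_se` (mean and standard error across replicates of the
#'   cluster insertions per diploid at onset), and `values` (the
#'   per-replicate measurements).
#' @export
shotgun_onset <- function(trajs, threshold = 0.99,
                          convention = c("averaged", "per_replicate")) {
  convention <- match.arg(convention)
  if (convention == "averaged") {
    gens <- trajs[[1]]$records$generation
    fr <- rowMeans(vapply(trajs, function(tr) tr$records$frac_cluster,
                          numeric(length(gens))))
    i <- which(fr >= threshold)[1]
    if (is.na(i))
      return(list(generation = NA_real_, cluster_mean = NA_real_,
                  cluster_se = NA_real_, values = numeric(0)))
    vals <- vapply(trajs, function(tr) tr$records$mean_cluster[i],
                   numeric(1))
    gen_on <- gens[i]
  } else {
    picks <- lapply(trajs, function(tr) {
      i <- which(tr$records$frac_cluster >= threshold)[1]
      c(gen = if (is.na(i)) NA_real_ else tr$records$generation[i],
        val = if (is.na(i)) NA_real_ else tr$records$mean_cluster[i])
    })
    gen_on <- vapply(picks, `[`, numeric(1), "gen")
    vals <- vapply(picks, `[`, numeric(1), "val")
    vals <- vals[!is.na(vals)]
  }
  list(generation = gen_on, cluster_mean = mean(vals),
       cluster_se = stats::sd(vals) / sqrt(length(vals)), values = vals)
}

#' Replicate quantiles of plateau TE abundance
#'
#' Extracts, per replicate, the haploid TE abundance (mean diploid copy
#' number / 2) at the plateau -- by default the final recorded generation
#' -- and returns quantiles across replicates.
#'
#' @param trajs a `te_replicates` object or list of `te_trajectory`.
#' @param q_low,q_high quantile bounds (default the 5\% and 95\%
#'   quantiles, i.e. a 90\% interval).
#' @param at either `"final"` or a generation number.
#' @return named numeric vector `c(low, high)` of haploid copy-number
#'   quantiles.
#' @export
abundance_quantiles <- function(trajs, q_low = 0.05, q_high = 0.95,
                                at = "final") {
  if (length(trajs) < 20)
    stop("at least 20 replicates are required for stable quantiles")
  plateau <- vapply(trajs, function(tr) {
    rec <- tr$records
    if (identical(at, "final")) rec$mean_n[nrow(rec)] / 2
    else {
      i <- which(rec$generation >= at)[1]
      if (is.na(i)) rec$mean_n[nrow(rec)] / 2 else rec$mean_n[i] / 2
    }
  }, numeric(1))
  q <- stats::quantile(plateau, probs = c(q_low, q_high), names = FALSE)
  c(low = q[1], high = q[2])
}
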
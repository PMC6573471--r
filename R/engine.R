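#' Simulation parameters
#'
#' Bundles all parameters of a trap-model invasion simulation.
#'
#' @param u transposition rate per copy per generation (the mean of the
#'   Poisson law governing new insertions on a gamete from an active,
#'   i.e. unsilenced, parent).
#' @param v excision rate per copy per generation (each non-reference copy
#'   on a gamete from an active parent is lost independently with this
#'   probability).
#' @param x per-copy fitness cost; `x = 0` gives neutral insertions.
#' @param t epistasis exponent of the exponential fitness model.
#' @param model fitness model kind: `"linear"`, `"exponential"` or
#'   `"cluster_neutral"` (see [fitness_model()]).
#' @param N population size (diploid individuals, constant).
#' @param n_seed TE insertions in the starting population, each seeded at
#'   frequency `1/(2N)`.
#' @param generations number of generations to simulate.
#' @param replicates default replicate count for [run_replicates()].
#' @param seed optional master seed.
#' @return object of class `simulation_params`.
#' @examples
#' simulation_params(u = 0.1, N = 1000, n_seed = 10, generations = 500)
#' @export
simulation_params <- function(u = 0.1, v = 0, x = 0, t = 1,
                              model = c("linear", "exponential",
                                        "cluster_neutral"),
                              N = 1000, n_seed = 10, generations = 500,
                              replicates = 1, seed = NULL) {
  model <- match.arg(model)
  if (u < 0 || v < 0) stop("u and v must be >= 0")
  if (x < 0) stop("x must be >= 0")
  if (t < 1) stop("t must be >= 1")
  if (N < 1) stop("N must be >= 1")
  if (n_seed < 0) stop("n_seed must be >= 0")
  structure(list(u = u, v = v, u_net = u - v, x = x, t = t, model = model,
                 N = as.integer(N), n_seed = as.integer(n_seed),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates), seed = seed),
            class = "simulation_params")
}

#' @export
print.simulation_params <- function(x, ...) {
  cat(sprintf(
    "Simulation parameters: u=%g v=%g (u'=%g) x=%g t=%g model=%s\n",
    x$u, x$v, x$u_net, x$x, x$t, x$model))
  cat(sprintf("  N=%d, n_seed=%d, generations=%d, replicates=%d\n",
              x$N, x$n_seed, x$generations, x$replicates))
  invisible(x)
}

#' Advance a population by one generation
#'
#' Executes one full generation cycle: (1) two parents per offspring are
#' drawn with probability proportional to fitness, (2) each parent
#' contributes one recombinant gamete, (3) excisions and (4) novel
#' transpositions are applied to gametes of active (unsilenced) parents,
#' (5) the zygote is the union of the two gametes.  Silencing is dominant
#' and trans-acting: a parent carrying at least one cluster insertion
#' produces gametes without any new transposition or excision events.
#'
#' @param pop a `te_population`.
#' @param arch the matching architecture.
#' @param params a [simulation_params()] object.
#' @return list with the next `population` (generation index incremented)
#'   and `novel_insertions`, the count of insertions added at the
#'   transposition step across the whole population.
#' @export
step_generation <- function(pop, arch, params) {
  res <- cpp_step_generation(arch_for_cpp(arch), pop$haplotypes,
                             params$u, params$v, params$x, params$t,
                             model_code(params$model))
  list(population = new_population(res$population, pop$generation + 1L),
       novel_insertions = res$novel_insertions)
}

#' Run a single TE invasion
#'
#' Simulates one invasion for `params$generations` generations (or until
#' the TE is lost or the population goes extinct), recording per-generation
#' population summaries.
#'
#' @param arch a [build_architecture()] object.
#' @param params a [simulation_params()] object.
#' @param seed optional seed applied with [set.seed()] before the run;
#'   the same seed reproduces the trajectory exactly.
#' @param stop_total_copies stop early (status `"completed"`) once the
#'   population-wide copy number exceeds this value; `Inf` disables.
#' @param post_fixation_generations stop this many generations after the
#'   first cluster insertion fixes; `NULL` disables.
#' @param full_stats_interval compute the (relatively expensive)
#'   segregating-site counts only every this many generations; the other
#'   summaries are recorded every generation.
#' @param return_population keep the final population in the result.
#' @return An object of class `te_trajectory`: list with `records` (a
#'   data.frame with one row per recorded generation and columns
#'   `generation`, `mean_n` (mean diploid copy number), `mean_cluster`,
#'   `mean_ref`, `frac_cluster`, `fixed_cluster`, `seg_cluster`,
#'   `seg_genomic`, `seg_ref`, `mean_w`, `novel_per_ind`), terminal
#'   `status` (`"completed"`, `"lost"` or `"extinct"`), the `params`, and
#'   optionally `final_population`.
#' @examples
#' arch <- build_architecture(rep(10, 5), 4, rep(300, 5))
#' p <- simulation_params(u = 0.1, N = 100, n_seed = 10, generations = 50)
#' traj <- run_invasion(arch, p, seed = 1)
#' tail(traj$records$mean_n, 1)
#' @export
run_invasion <- function(arch, params, seed = NULL,
                         stop_total_copies = Inf,
                         post_fixation_generations = NULL,
                         full_stats_interval = 1L,
                         return_population = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pop <- init_population(arch, params$N, params$n_seed)
  res <- cpp_run_invasion(arch_for_cpp(arch), pop$haplotypes,
                          params$u, params$v, params$x, params$t,
                          model_code(params$model), params$generations,
                          stop_total_copies,
                          if (is.null(post_fixation_generations)) -1L
                          else as.integer(post_fixation_generations),
                          as.integer(full_stats_interval),
                          return_population)
  records <- as.data.frame(res$records)
  status <- c("completed", "lost", "extinct")[res$status + 1L]
  traj <- list(records = records, status = status, params = params,
               seed = seed)
  if (return_population) {
    traj$final_population <- new_population(
      res$population, records$generation[nrow(records)])
  }
  class(traj) <- "te_trajectory"
  traj
}

#' @export
print.te_trajectory <- function(x, ...) {
  last <- x$records[nrow(x$records), ]
  cat(sprintf(
    "TE invasion trajectory: %d generations recorded, status '%s'\n",
    nrow(x$records), x$status))
  cat(sprintf(
    "  final: %.1f copies/diploid, %.2f cluster ins./diploid, %d fixed cluster site(s)\n",
    last$mean_n, last$mean_cluster, last$fixed_cluster))
  invisible(x)
}

#' Run replicate invasions
#'
#' Runs independent replicate invasions with per-replicate seeds derived
#' from a master seed by a counter scheme, so replicate `k` is reproducible
#' in isolation and results do not depend on execution order.
#'
#' @inheritParams run_invasion
#' @param replicates number of replicates (defaults to
#'   `params$replicates`).
#' @param seed master seed.
#' @param established_only drop replicates whose TE was lost (an invasion
#'   counts as established if any copies remain at the end of its run).
#' @param ... passed to [run_invasion()] (early-stop options etc.).
#' @return object of class `te_replicates`: a list of `te_trajectory`
#'   objects with attribute `replicate_seeds`.
#' @export
run_replicates <- function(arch, params, replicates = NULL, seed = 1,
                           established_only = FALSE, ...) {
  if (is.null(replicates)) replicates <- params$replicates
  seeds <- replicate_seed(seed, seq_len(replicates))
  trajs <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    trajs[[k]] <- run_invasion(arch, params, seed = seeds[k], ...)
    trajs[[k]]$replicate <- k
  }
  if (established_only) {
    keep <- vapply(trajs, function(tr) tr$status != "lost", logical(1))
    trajs <- trajs[keep]
    seeds <- seeds[keep]
  }
  structure(trajs, replicate_seeds = seeds, class = "te_replicates")
}

#' Derive a per-replicate seed from a master seed
#'
#' Counter-based derivation: `(seed + 104729 * k) mod (2^31 - 1)`, kept in
#' the 32-bit integer range accepted by [set.seed()].
#'
#' @param seed master seed (integer).
#' @param k replicate index (vectorised).
#' @return integer vector of seeds.
#' @export
replicate_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

#' @export
print.te_replicates <- function(x, ...) {
  st <- table(vapply(x, function(tr) tr$status, character(1)))
  cat(sprintf("TE invasion replicates: %d run(s) [%s]\n", length(x),
              paste(names(st), st, sep = ": ", collapse = ", ")))
  invisible(x)
}
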
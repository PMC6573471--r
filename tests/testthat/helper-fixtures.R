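# Shared fixtures, built in code.

default_arch <- function() build_architecture(rep(10, 5), 4, rep(300, 5))

# tiny two-chromosome genome for brute-force site classification
tiny_arch <- function() {
  build_architecture(chrom_mb = c(0.005, 0.004), rr_cm_mb = c(4, 0),
                     cluster_kb = c(1, 0.5), ref_kb = c(2, 1))
}

# population in which a single cluster site segregates at exactly p,
# assigned to haplotypes at random (Hardy-Weinberg random union)
one_site_population <- function(arch, N, p, site = 0L) {
  carriers <- sample(c(rep(TRUE, round(2 * N * p)),
                       rep(FALSE, 2 * N - round(2 * N * p))))
  haps <- lapply(carriers, function(cc) if (cc) as.integer(site) else integer(0))
  pirnatrap:::new_population(haps)
}

# population where every individual is homozygous for one fixed site
fixed_site_population <- function(N, site = 0L) {
  pirnatrap:::new_population(rep(list(as.integer(site)), 2 * N))
}

# build a population directly from a list of per-haplotype site vectors
population_from_haplotypes <- function(haps) {
  pirnatrap:::new_population(lapply(haps, function(h) sort(as.integer(h))))
}

# memoised heavy runs shared by several acceptance checks:
# established neutral default invasions, u = 0.1, N = 1000, 500 generations
.acceptance_cache <- new.env(parent = emptyenv())

neutral_default_runs <- function() {
  if (!is.null(.acceptance_cache$runs)) return(.acceptance_cache$runs)
  arch <- default_arch()
  p <- simulation_params(u = 0.1, N = 1000, n_seed = 10, generations = 500)
  runs <- run_replicates(arch, p, replicates = 45, seed = 11,
                         established_only = TRUE,
                         full_stats_interval = 25L)
  .acceptance_cache$runs <- runs
  runs
}

record_at <- function(trajs, column, generation) {
  vapply(trajs, function(tr) {
    tr$records[[column]][tr$records$generation == generation]
  }, numeric(1))
}

cluster_at_onset <- function(trajs, threshold = 0.99) {
  vapply(trajs, function(tr) {
    i <- which(tr$records$frac_cluster >= threshold)[1]
    if (is.na(i)) NA_real_ else tr$records$mean_cluster[i]
  }, numeric(1))
}
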
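test_that("runs are deterministic given a seed and differ across seeds", {
  arch <- default_arch()
  p <- simulation_params(u = 0.1, N = 100, n_seed = 10, generations = 40)
  a <- run_invasion(arch, p, seed = 123)
  b <- run_invasion(arch, p, seed = 123)
  expect_identical(a$records, b$records)
  c <- run_invasion(arch, p, seed = 124)
  expect_false(identical(a$records, c$records))

  # replicate k in isolation reproduces replicate k of the batch
  batch <- run_replicates(arch, p, replicates = 3, seed = 7)
  solo <- run_invasion(arch, p, seed = replicate_seed(7, 2))
  expect_identical(batch[[2]]$records, solo$records)
})

test_that("a fixed site persists unchanged when all forces are off", {
  arch <- default_arch()
  N <- 60
  pop <- fixed_site_population(N, site = 0L)  # fixed cluster site
  p <- simulation_params(u = 0, v = 0, x = 0, N = N, n_seed = 0,
                         generations = 30)
  set.seed(9)
  for (g in 1:30) pop <- step_generation(pop, arch, p)$population
  af <- allele_frequencies(pop, arch)
  expect_equal(nrow(af), 1)
  expect_equal(af$freq, 1.0)
  expect_equal(total_copies(pop), 2 * N)
})

test_that("silenced parents produce gametes without transposition or excision", {
  arch <- default_arch()
  N <- 80
  set.seed(10)
  # every individual homozygous for a cluster site plus genomic cargo
  haps <- lapply(seq_len(2 * N), function(i)
    sort(c(0L, sample(400000:9000000, 5))))
  pop <- population_from_haplotypes(haps)
  p <- simulation_params(u = 0.5, v = 0.5, N = N, n_seed = 0,
                         generations = 1)
  res <- step_generation(pop, arch, p)
  expect_equal(res$novel_insertions, 0)
  # no excisions either: the fixed cluster site is still carried twice by
  # every individual (genomic cargo reassorts but is not created/destroyed)
  cl <- vapply(res$population$haplotypes, function(h)
    sum(h == 0L), numeric(1))
  expect_true(all(cl == 1))

  # an active population under the same rates does transpose
  pop2 <- population_from_haplotypes(
    lapply(seq_len(2 * N), function(i) sort(sample(400000:9000000, 5))))
  set.seed(11)
  res2 <- step_generation(pop2, arch, p)
  expect_gt(res2$novel_insertions, 0)
})

test_that("excision removes copies as an independent binomial thinning", {
  arch <- build_architecture(rep(10, 5), 4, rep(300, 5), rep(300, 5))
  acpp <- pirnatrap:::arch_for_cpp(arch)
  set.seed(12)
  g <- sort(sample(400000:9000000, 20000))  # genomic sites
  expect_identical(pirnatrap:::cpp_apply_excision(acpp, g, TRUE, 0), g)
  expect_identical(pirnatrap:::cpp_apply_excision(acpp, g, FALSE, 1), g)
  expect_length(pirnatrap:::cpp_apply_excision(acpp, g, TRUE, 1), 0)
  kept <- pirnatrap:::cpp_apply_excision(acpp, g, TRUE, 0.1)
  removed <- 1 - length(kept) / length(g)
  expect_lt(abs(removed - 0.1), 4 * sqrt(0.1 * 0.9 / length(g)))
  # reference-region copies are immune to excision
  refs <- sort(as.integer(1e7 - (1:1000)))
  expect_identical(pirnatrap:::cpp_apply_excision(acpp, refs, TRUE, 1), refs)
})

test_that("transposition is Poisson in the gamete's non-reference copies", {
  arch <- build_architecture(rep(10, 5), 4, rep(300, 5), rep(300, 5))
  acpp <- pirnatrap:::arch_for_cpp(arch)
  g10 <- as.integer(5e6 + (0:9))  # k = 10
  set.seed(13)
  n_new <- replicate(20000, pirnatrap:::cpp_apply_transposition(
    acpp, g10, TRUE, 0.1)$n_new)
  expect_lt(abs(mean(n_new) - 1.0), 4 * sqrt(1.0 / 20000))
  # silenced parent: never any insertions
  expect_true(all(replicate(50, pirnatrap:::cpp_apply_transposition(
    acpp, g10, FALSE, 0.5)$n_new) == 0))
  # reference copies are not a transposition source (k = 0)
  refs <- as.integer(1e7 - (1:10))
  expect_true(all(replicate(200, pirnatrap:::cpp_apply_transposition(
    acpp, refs, TRUE, 0.9)$n_new) == 0))
  # saturated one-site genome: every draw collides and is discarded
  arch1 <- build_architecture(1e-6, 0, 0)
  a1 <- pirnatrap:::arch_for_cpp(arch1)
  expect_true(all(replicate(200, pirnatrap:::cpp_apply_transposition(
    a1, 0L, TRUE, 1)$n_new) == 0))
})

test_that("gametes follow the recombination map", {
  # rr = 0: each chromosome is transmitted intact from one parent haplotype
  arch0 <- build_architecture(c(10, 10), 0, c(0, 0))
  a0 <- pirnatrap:::arch_for_cpp(arch0)
  h1 <- as.integer(c(1e6, 2e6, 11e6))       # chr1: {1,2} Mb, chr2: {11 Mb}
  h2 <- as.integer(c(3e6, 15e6, 16e6))      # chr1: {3} Mb, chr2: {15,16} Mb
  set.seed(14)
  for (i in 1:40) {
    g <- pirnatrap:::cpp_make_gamete(a0, h1, h2)
    chr1 <- g[g < 1e7]; chr2 <- g[g >= 1e7]
    expect_true(identical(chr1, c(1e6L, 2e6L)) || identical(chr1, 3e6L))
    expect_true(identical(chr2, 11e6L) || identical(chr2, c(15e6L, 16e6L)))
  }

  # 10 Mb at 4 cM/Mb: recombinant fraction between chromosome ends is
  # (1 - exp(-2 * 0.4)) / 2 under Poisson crossovers without interference
  arch <- build_architecture(10, 4, 0)
  acpp <- pirnatrap:::arch_for_cpp(arch)
  set.seed(15)
  rec <- replicate(20000, {
    g <- pirnatrap:::cpp_make_gamete(acpp, 0L, as.integer(1e7 - 1))
    length(g) != 1  # parental gametes carry exactly one of the two markers
  })
  r_expected <- (1 - exp(-0.8)) / 2
  expect_lt(abs(mean(rec) - r_expected),
            4 * sqrt(r_expected * (1 - r_expected) / 20000))

  # independent assortment: two linked-in-cis markers on different
  # chromosomes co-transmit with probability 1/4
  arch2 <- build_architecture(c(10, 10), 0, c(0, 0))
  a2 <- pirnatrap:::arch_for_cpp(arch2)
  set.seed(16)
  both <- replicate(20000, {
    g <- pirnatrap:::cpp_make_gamete(a2, as.integer(c(5e6, 15e6)), integer(0))
    length(g) == 2
  })
  expect_lt(abs(mean(both) - 0.25), 4 * sqrt(0.25 * 0.75 / 20000))

  # a non-recombining cluster is inherited as a block
  archf <- build_architecture(2, 4, 1000, cluster_recombining = FALSE)
  af <- pirnatrap:::arch_for_cpp(archf)
  cl_sites <- as.integer(c(0, 500000, 999999))
  set.seed(17)
  for (i in 1:60) {
    g <- pirnatrap:::cpp_make_gamete(af, cl_sites, integer(0))
    gc <- g[g < 1e6]
    expect_true(length(gc) == 0 || identical(gc, cl_sites))
  }
})

test_that("selection weights parents in proportion to fitness", {
  arch <- default_arch()
  N <- 2
  # individual 1: no copies (w = 1); individual 2: homozygous for 5 genomic
  # sites (10 copies, x = 0.07 -> w = 0.3), so each of its gametes carries
  # exactly 5 copies whatever the crossovers; offspring share 1 : 0.3
  sites2 <- as.integer(5e6 + 0:4)
  haps <- list(integer(0), integer(0), sites2, sites2)
  pop <- population_from_haplotypes(haps)
  p <- simulation_params(u = 0, v = 0, x = 0.07, N = N, n_seed = 0,
                         generations = 1)
  set.seed(18)
  draws <- numeric(0)
  for (i in 1:400) {
    nxt <- step_generation(pop, arch, p)$population
    draws <- c(draws, total_copies(nxt) / 5)  # gametes from ind. 2
  }
  # each of the 4 gamete draws comes from parent 2 with prob 0.3/1.3
  p2 <- 0.3 / 1.3
  expect_lt(abs(mean(draws) / 4 - p2),
            4 * sqrt(p2 * (1 - p2) / (4 * 400)))

  # zero total fitness signals extinction rather than dividing by zero
  dead <- population_from_haplotypes(
    list(as.integer(5e6 + 0:19), as.integer(6e6 + 0:19)))
  pdead <- simulation_params(u = 0, x = 0.1, N = 1, n_seed = 0,
                             generations = 1)
  expect_error(step_generation(dead, arch, pdead), "extinct")
})

test_that("copy numbers grow by (1 + u') per generation without clusters", {
  arch0 <- build_architecture(rep(10, 5), 4, rep(0, 5))
  p <- simulation_params(u = 0.12, v = 0.02, x = 0, N = 500, n_seed = 500,
                         generations = 50)
  tr <- run_invasion(arch0, p, seed = 19, full_stats_interval = 10L)
  fit <- stats::lm(log(mean_n) ~ generation, data = tr$records)
  rate <- exp(unname(stats::coef(fit)[2]))
  expect_lt(abs(rate - (1 + p$u_net)), 0.01)
})

test_that("single-copy loss probability approaches 1 - 2u for small u", {
  arch <- default_arch()
  u <- 0.02
  p <- simulation_params(u = u, N = 200, n_seed = 1, generations = 400)
  lost <- 0
  reps <- 2500
  for (k in seq_len(reps)) {
    tr <- run_invasion(arch, p, seed = replicate_seed(21, k),
                       stop_total_copies = 60, full_stats_interval = 1000L)
    if (tr$status == "lost") lost <- lost + 1
  }
  expect_lt(abs(lost / reps - (1 - 2 * u)), 0.015)
})

test_that("terminal statuses are assigned correctly", {
  arch <- default_arch()
  # loss: no transposition, one seed copy almost surely drifts out
  p <- simulation_params(u = 0, N = 20, n_seed = 1, generations = 2000)
  tr <- run_invasion(arch, p, seed = 22)
  expect_equal(tr$status, "lost")
  expect_equal(tail(tr$records$mean_n, 1), 0)

  # extinction: overwhelming load drives mean fitness below 0.1
  pext <- simulation_params(u = 0, x = 0.2, N = 50, n_seed = 1500,
                            generations = 50)
  tr <- run_invasion(arch, pext, seed = 23)
  expect_equal(tr$status, "extinct")
  expect_lt(tail(tr$records$mean_w, 1), 0.1)

  # completed with early stop once the invasion is clearly established
  pok <- simulation_params(u = 0.1, N = 200, n_seed = 50, generations = 300)
  tr <- run_invasion(arch, pok, seed = 24, stop_total_copies = 400)
  expect_equal(tr$status, "completed")
  expect_gt(tail(tr$records$mean_n, 1) * 200, 400)

  # established_only drops lost replicates
  pl <- simulation_params(u = 0.01, N = 100, n_seed = 1, generations = 100)
  reps <- run_replicates(arch, pl, replicates = 20, seed = 25,
                         established_only = TRUE)
  expect_true(all(vapply(reps, function(x) x$status != "lost", logical(1))))
})

test_that("cached summaries match recomputation from the raw population", {
  arch <- build_architecture(rep(10, 5), 4, rep(300, 5), rep(300, 5))
  p <- simulation_params(u = 0.2, v = 0.02, N = 120, n_seed = 60,
                         generations = 50)
  tr <- run_invasion(arch, p, seed = 26, return_population = TRUE)
  pop <- tr$final_population
  last <- tr$records[nrow(tr$records), ]
  expect_equal(last$mean_n, total_copies(pop) / pop$N)
  expect_equal(last$frac_cluster, fraction_with_cluster(pop, arch))
  cls <- unlist(lapply(pop$haplotypes, function(h) classify_site_safe(arch, h)))
  expect_equal(last$mean_cluster, sum(cls == "CLUSTER") / pop$N)
  expect_equal(last$mean_ref, sum(cls == "REFERENCE") / pop$N)
  af <- allele_frequencies(pop, arch)
  expect_equal(last$fixed_cluster,
               sum(af$freq == 1 & af$class == "CLUSTER"))
  expect_equal(last$seg_cluster,
               sum(af$freq < 1 & af$class == "CLUSTER"))
  expect_equal(last$seg_genomic,
               sum(af$freq < 1 & af$class == "GENOMIC"))
})
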
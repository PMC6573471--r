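#' Initialise a population with seed insertions
#'
#' Creates a diploid population of `N` individuals carrying `n_seed` TE
#' insertions.  Each insertion is placed at a distinct, uniformly drawn
#' genomic site, on one uniformly drawn haplotype of one uniformly drawn
#' individual, so every seeded site starts at population frequency
#' `1/(2N)`.
#'
#' @param arch a [build_architecture()] object.
#' @param N population size (diploid individuals).
#' @param n_seed number of seed insertions.
#' @return An object of class `te_population`: a list with `haplotypes`
#'   (2N sorted integer vectors of occupied sites; individual `i` owns
#'   haplotypes `2i-1` and `2i`), `N`, and `generation`.
#' @examples
#' arch <- build_architecture(rep(10, 5), 4, rep(300, 5))
#' set.seed(1)
#' pop <- init_population(arch, N = 1000, n_seed = 10)
#' total_copies(pop)  # 10
#' @export
init_population <- function(arch, N, n_seed = 10) {
  if (N < 1) stop("N must be >= 1")
  if (n_seed < 0) stop("n_seed must be >= 0")
  if (n_seed > arch$total_bp) stop("n_seed exceeds the number of sites")
  haplotypes <- rep(list(integer(0)), 2 * N)
  if (n_seed > 0) {
    sites <- sample.int(arch$total_bp, n_seed, replace = FALSE) - 1L
    haps <- sample.int(2 * N, n_seed, replace = TRUE)
    for (j in seq_len(n_seed)) {
      h <- haps[j]
      haplotypes[[h]] <- sort(c(haplotypes[[h]], as.integer(sites[j])))
    }
  }
  new_population(haplotypes, generation = 0L)
}

new_population <- function(haplotypes, generation = 0L) {
  structure(list(haplotypes = haplotypes,
                 N = length(haplotypes) %/% 2L,
                 generation = as.integer(generation)),
            class = "te_population")
}

#' @export
print.te_population <- function(x, ...) {
  cat(sprintf("TE population: N = %d, generation %d, %d TE copies\n",
              x$N, x$generation, total_copies(x)))
  invisible(x)
}

#' Total TE copies in a population
#' @param pop a `te_population`.
#' @return integer: summed copy number over all haplotypes.
#' @export
total_copies <- function(pop) {
  sum(lengths(pop$haplotypes))
}

#' Extract one individual
#' @param pop a `te_population`.
#' @param i individual index in `1:N`.
#' @return list with integer vectors `hap1` and `hap2`.
#' @export
get_individual <- function(pop, i) {
  if (i < 1 || i > pop$N) stop("individual index out of range")
  list(hap1 = pop$haplotypes[[2 * i - 1]], hap2 = pop$haplotypes[[2 * i]])
}

#' Population allele frequencies
#'
#' Tabulates every occupied site with its population allele frequency
#' `p = carriers / (2N)` (haplotype count) and its site class.  A fixed
#' site has `p = 1`.
#'
#' @param pop a `te_population`.
#' @param arch the matching [build_architecture()] object.
#' @return data.frame with columns `site`, `count`, `freq`, `class`.
#' @export
allele_frequencies <- function(pop, arch) {
  all_sites <- unlist(pop$haplotypes, use.names = FALSE)
  if (length(all_sites) == 0)
    return(data.frame(site = numeric(0), count = integer(0),
                      freq = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  tab <- table(all_sites)
  site <- as.numeric(names(tab))
  count <- as.integer(tab)
  data.frame(site = site, count = count, freq = count / (2 * pop$N),
             class = classify_site(arch, site), stringsAsFactors = FALSE)
}

#' Does an individual carry a cluster insertion?
#'
#' A single heterozygous piRNA-cluster insertion silences the TE family in
#' trans (dominant effect), so an individual is silenced as soon as either
#' haplotype carries a CLUSTER-class site.  REFERENCE-class insertions
#' never silence.
#'
#' @param ind an individual as returned by [get_individual()] (any list
#'   with `hap1`/`hap2` integer site vectors).
#' @param arch the matching architecture.
#' @return logical.
#' @export
has_cluster_insertion <- function(ind, arch) {
  sites <- c(ind$hap1, ind$hap2)
  if (length(sites) == 0) return(FALSE)
  any(classify_site(arch, sites) == "CLUSTER")
}

#' Fraction of individuals carrying at least one cluster insertion
#'
#' The complement of the fraction of individuals in which the TE is still
#' active; the invasion enters the shotgun phase when this reaches 0.99.
#'
#' @param pop a `te_population`.
#' @param arch the matching architecture.
#' @return proportion in \[0, 1\].
#' @export
fraction_with_cluster <- function(pop, arch) {
  n_cl <- per_individual_cluster_count(pop, arch)
  mean(n_cl > 0)
}

per_individual_cluster_count <- function(pop, arch) {
  cl_per_hap <- vapply(pop$haplotypes, function(h) {
    if (length(h) == 0) 0L else sum(classify_site(arch, h) == "CLUSTER")
  }, integer(1))
  cl_per_hap[seq(1, 2 * pop$N, by = 2)] + cl_per_hap[seq(2, 2 * pop$N, by = 2)]
}

#' Zygosity breakdown of cluster insertions
#'
#' For every cluster site, carriers are split into heterozygous (site on
#' one haplotype) and homozygous (site on both haplotypes) individuals;
#' counts are aggregated over sites.
#'
#' @param pop a `te_population`.
#' @param arch the matching architecture.
#' @return named numeric vector with fractions `heterozygous` and
#'   `homozygous` (summing to 1; both `NaN` if there are no cluster
#'   insertions).
#' @export
zygosity_breakdown <- function(pop, arch) {
  n_het <- 0L
  n_hom <- 0L
  for (i in seq_len(pop$N)) {
    h1 <- pop$haplotypes[[2 * i - 1]]
    h2 <- pop$haplotypes[[2 * i]]
    c1 <- h1[classify_site_safe(arch, h1) == "CLUSTER"]
    c2 <- h2[classify_site_safe(arch, h2) == "CLUSTER"]
    hom <- length(intersect(c1, c2))
    n_hom <- n_hom + hom
    n_het <- n_het + length(c1) + length(c2) - 2L * hom
  }
  tot <- n_het + n_hom
  c(heterozygous = n_het / tot, homozygous = n_hom / tot)
}

classify_site_safe <- function(arch, sites) {
  if (length(sites) == 0) character(0) else classify_site(arch, sites)
}

#' Site frequency spectrum
#'
#' Bins the allele frequencies of all occupied sites of a class (or all
#' classes) into a partition of (0, 1].
#'
#' @param pop a `te_population`.
#' @param arch the matching architecture.
#' @param site_class one of `"CLUSTER"`, `"REFERENCE"`, `"GENOMIC"`, or
#'   `"ALL"`.
#' @param bins increasing numeric vector of bin edges partitioning (0, 1];
#'   bin `k` covers `(bins[k], bins[k+1]]`.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
sfs <- function(pop, arch, site_class = "CLUSTER",
                bins = seq(0, 1, by = 0.1)) {
  if (any(diff(bins) <= 0) || bins[1] != 0 || bins[length(bins)] != 1)
    stop("'bins' must partition (0, 1]")
  af <- allele_frequencies(pop, arch)
  if (site_class != "ALL") af <- af[af$class == site_class, , drop = FALSE]
  cuts <- cut(af$freq, breaks = bins, include.lowest = FALSE)
  data.frame(lower = bins[-length(bins)], upper = bins[-1],
             count = as.integer(table(cuts)))
}

#' Write / read a population snapshot
#'
#' Serialises a population to a plain TSV with one row per occupied site
#' and columns `replicate`, `generation`, `individual`, `haplotype`,
#' `site`, `site_class`.  [read_population()] restores an identical
#' population (the number of individuals is taken from the header line).
#'
#' @param pop a `te_population`.
#' @param arch the matching architecture.
#' @param file path of the TSV file.
#' @param replicate replicate id recorded in the file.
#' @return `write_population()` returns `file` invisibly;
#'   `read_population()` returns a `te_population`.
#' @export
write_population <- function(pop, arch, file, replicate = 1L) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# N\t%d", pop$N), con)
  writeLines(sprintf("# generation\t%d", pop$generation), con)
  rows <- list()
  for (i in seq_len(pop$N)) {
    for (h in 1:2) {
      sites <- pop$haplotypes[[2 * (i - 1) + h]]
      if (length(sites) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = replicate, generation = pop$generation, individual = i,
        haplotype = h, site = sites,
        site_class = classify_site(arch, sites), stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicate = integer(0), generation = integer(0),
               individual = integer(0), haplotype = integer(0),
               site = integer(0), site_class = character(0))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^# ", lines, value = TRUE)
  N <- as.integer(sub("^# N\t", "", grep("^# N\t", hdr, value = TRUE)))
  gen <- as.integer(sub("^# generation\t", "",
                        grep("^# generation\t", hdr, value = TRUE)))
  body <- lines[!grepl("^# ", lines)]
  haplotypes <- rep(list(integer(0)), 2 * N)
  if (length(body) > 1) {
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    for (k in seq_len(nrow(df))) {
      idx <- 2L * (df$individual[k] - 1L) + df$haplotype[k]
      haplotypes[[idx]] <- c(haplotypes[[idx]], as.integer(df$site[k]))
    }
    haplotypes <- lapply(haplotypes, sort)
  }
  new_population(haplotypes, generation = gen)
}
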
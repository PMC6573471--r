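#' Build a genome architecture
#'
#' Defines the simulated genome: an ordered set of chromosomes, each with a
#' constant recombination rate, an optional piRNA cluster at the chromosome
#' start and an optional neutral reference region at the chromosome end.
#' Genomic coordinates are 0-based, half-open, at single-bp resolution;
#' every bp is a potential insertion site and global site indices run
#' consecutively across chromosomes.
#'
#' @param chrom_mb numeric vector of chromosome sizes in Mb (1 Mb = 1e6 bp).
#' @param rr_cm_mb numeric vector of per-chromosome recombination rates in
#'   cM/Mb; recycled if of length 1.
#' @param cluster_kb numeric vector of per-chromosome piRNA-cluster sizes in
#'   kb (1 kb = 1e3 bp), clusters sit at chromosome starts; recycled if of
#'   length 1.
#' @param ref_kb per-chromosome neutral reference-region sizes in kb,
#'   placed at chromosome ends.  `NULL` or an empty vector means no
#'   reference regions.  TEs inserted in reference regions do not silence
#'   the TE, do not transpose and do not affect fitness; they are inherited
#'   and recombine like any other insertion.
#' @param cluster_recombining logical; may crossovers fall inside the
#'   cluster intervals?  When `FALSE` each cluster is inherited as a block
#'   and does not contribute to the chromosome map length (a
#'   non-recombining cluster, as for the \emph{flamenco} locus).  Scalar or
#'   per-chromosome vector.
#'
#' @return An object of class `genome_architecture`: a list with the
#'   per-chromosome specification and derived totals (`total_bp`,
#'   `total_cluster_bp`, `total_ref_bp`, `cluster_fraction`, global
#'   chromosome offsets).
#' @examples
#' arch <- build_architecture(rep(10, 5), 4, rep(300, 5))
#' arch$total_bp          # 50,000,000
#' arch$cluster_fraction  # 0.03
#' @export
build_architecture <- function(chrom_mb, rr_cm_mb = 4, cluster_kb = 0,
                               ref_kb = NULL, cluster_recombining = TRUE) {
  nc <- length(chrom_mb)
  if (nc < 1) stop("at least one chromosome is required")
  rr_cm_mb <- recycle_arg(rr_cm_mb, nc, "rr_cm_mb")
  cluster_kb <- recycle_arg(cluster_kb, nc, "cluster_kb")
  if (is.null(ref_kb) || length(ref_kb) == 0) ref_kb <- rep(0, nc)
  ref_kb <- recycle_arg(ref_kb, nc, "ref_kb")
  cluster_recombining <- recycle_arg(cluster_recombining, nc,
                                     "cluster_recombining")

  length_bp <- round(chrom_mb * 1e6)
  cluster_len_bp <- round(cluster_kb * 1e3)
  ref_len_bp <- round(ref_kb * 1e3)

  if (any(length_bp <= 0)) stop("chromosome lengths must be positive")
  if (any(rr_cm_mb < 0)) stop("recombination rates must be non-negative")
  if (any(cluster_len_bp < 0) || any(ref_len_bp < 0))
    stop("cluster and reference sizes must be non-negative")
  if (any(cluster_len_bp + ref_len_bp > length_bp))
    stop("cluster + reference region exceed chromosome length")

  offset_bp <- cumsum(c(0, length_bp[-nc]))
  arch <- list(
    length_bp = as.numeric(length_bp),
    recomb_rate = as.numeric(rr_cm_mb),
    cluster_len_bp = as.numeric(cluster_len_bp),
    ref_len_bp = as.numeric(ref_len_bp),
    cluster_recombining = as.logical(cluster_recombining),
    offset_bp = as.numeric(offset_bp),
    total_bp = sum(length_bp),
    total_cluster_bp = sum(cluster_len_bp),
    total_ref_bp = sum(ref_len_bp)
  )
  arch$cluster_fraction <- arch$total_cluster_bp / arch$total_bp
  if (arch$total_bp > 2^31 - 2)
    stop("total genome size exceeds the supported maximum (2^31-2 bp)")
  class(arch) <- "genome_architecture"
  arch
}

recycle_arg <- function(x, n, name) {
  if (length(x) == 1) x <- rep(x, n)
  if (length(x) != n)
    stop(sprintf("'%s' must have length 1 or %d", name, n))
  x
}

#' @export
print.genome_architecture <- function(x, ...) {
  cat(sprintf("Genome architecture: %d chromosome(s), %.3f Mb total\n",
              length(x$length_bp), x$total_bp / 1e6))
  cat(sprintf("  piRNA clusters: %.1f kb total (%.3f%% of genome)%s\n",
              x$total_cluster_bp / 1e3, 100 * x$cluster_fraction,
              if (all(x$cluster_recombining)) "" else ", non-recombining"))
  if (x$total_ref_bp > 0)
    cat(sprintf("  reference regions: %.1f kb total\n", x$total_ref_bp / 1e3))
  cat(sprintf("  recombination: %s cM/Mb\n",
              paste(format(x$recomb_rate), collapse = ", ")))
  invisible(x)
}

#' Classify genomic sites
#'
#' Maps global 0-based site indices to their site class: `"CLUSTER"` for
#' sites inside a piRNA cluster (half-open interval at the chromosome
#' start), `"REFERENCE"` for sites inside a neutral reference region at the
#' chromosome end, `"GENOMIC"` otherwise.
#'
#' @param arch a [build_architecture()] object.
#' @param site vector of global site indices, `0 <= site < total_bp`.
#' @return character vector of site classes.
#' @examples
#' arch <- build_architecture(rep(10, 5), 4, rep(300, 5))
#' classify_site(arch, c(0, 299999, 300000))
#' @export
classify_site <- function(arch, site) {
  site <- as.numeric(site)
  if (any(is.na(site)) || any(site < 0) || any(site >= arch$total_bp))
    stop("site index out of range")
  chrom <- findInterval(site, arch$offset_bp)
  off <- site - arch$offset_bp[chrom]
  cls <- rep("GENOMIC", length(site))
  cls[off < arch$cluster_len_bp[chrom]] <- "CLUSTER"
  cls[off >= arch$length_bp[chrom] - arch$ref_len_bp[chrom]] <- "REFERENCE"
  cls
}

#' Sample uniform insertion sites
#'
#' Draws insertion target sites uniformly over all `total_bp` sites of the
#' genome (every bp is an equally likely target, so a class is hit in
#' proportion to its share of the genome).
#'
#' @param arch a [build_architecture()] object.
#' @param n number of sites to draw (with replacement).
#' @return numeric vector of global site indices.
#' @export
sample_insertion_site <- function(arch, n = 1) {
  floor(stats::runif(n, min = 0, max = arch$total_bp))
}

#' Predefined simulation scenarios
#'
#' Returns named genome architectures together with matching default
#' simulation parameters:
#' \describe{
#'   \item{default}{five 10 Mb chromosomes at 4 cM/Mb, a 300 kb cluster at
#'     the start of each (3\% of the genome), N = 1000, u = 0.1, neutral
#'     insertions, 10 seed insertions.}
#'   \item{flamenco}{five 2 Mb chromosomes, a single non-recombining 1 Mb
#'     cluster (10\% of the genome) on the first chromosome: the somatic
#'     piRNA pathway architecture.}
#'   \item{flamenco_recombining}{as `flamenco` but crossovers may occur
#'     inside the cluster.}
#'   \item{germline}{five 2 Mb chromosomes, a non-recombining 200 kb
#'     cluster on each (same 1 Mb total): the germline pathway
#'     architecture of clusters distributed over chromosomes.}
#'   \item{germline_recombining}{as `germline` with recombining clusters.}
#'   \item{dmel_germline}{a 200 Mb genome (five 40 Mb chromosomes) with
#'     germline clusters on all five chromosomes totalling 3.5\% of the
#'     genome, as in \emph{D. melanogaster}.}
#'   \item{dmel_somatic}{the same 200 Mb genome with a single
#'     non-recombining 300 kb cluster (0.15\% of the genome), matching the
#'     \emph{flamenco} locus.}
#' }
#'
#' @param name scenario name (see above).
#' @return list with elements `architecture` and `params` (a
#'   [simulation_params()] object).
#' @examples
#' sc <- predefined_scenario("flamenco")
#' sc$architecture$cluster_fraction  # 0.10
#' @export
predefined_scenario <- function(name = c("default", "flamenco",
                                         "flamenco_recombining", "germline",
                                         "germline_recombining",
                                         "dmel_germline", "dmel_somatic")) {
  name <- match.arg(name)
  arch <- switch(name,
    default = build_architecture(rep(10, 5), 4, rep(300, 5)),
    flamenco = build_architecture(rep(2, 5), 4, c(1000, 0, 0, 0, 0),
                                  cluster_recombining = FALSE),
    flamenco_recombining = build_architecture(rep(2, 5), 4,
                                              c(1000, 0, 0, 0, 0),
                                              cluster_recombining = TRUE),
    germline = build_architecture(rep(2, 5), 4, rep(200, 5),
                                  cluster_recombining = FALSE),
    germline_recombining = build_architecture(rep(2, 5), 4, rep(200, 5),
                                              cluster_recombining = TRUE),
    dmel_germline = build_architecture(rep(40, 5), 4, rep(1400, 5),
                                       cluster_recombining = FALSE),
    dmel_somatic = build_architecture(rep(40, 5), 4, c(300, 0, 0, 0, 0),
                                      cluster_recombining = FALSE)
  )
  params <- simulation_params(u = 0.1, v = 0, x = 0, N = 1000, n_seed = 10,
                              generations = 500)
  list(name = name, architecture = arch, params = params)
}

#' List the available predefined scenarios
#' @return character vector of scenario names.
#' @export
list_scenarios <- function() {
  c("default", "flamenco", "flamenco_recombining", "germline",
    "germline_recombining", "dmel_germline", "dmel_somatic")
}

# architecture as a plain list for the C++ engine
arch_for_cpp <- function(arch) {
  stopifnot(inherits(arch, "genome_architecture"))
  unclass(arch)
}
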
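#' Define a fitness model
#'
#' Three models for the fitness cost of TE copies in a diploid individual
#' with copy number `n` (reference-region copies never count):
#' \describe{
#'   \item{linear}{`w = 1 - x * n`, all non-reference copies (cluster
#'     copies included) are equally deleterious.}
#'   \item{exponential}{`w = 1 - x * n^t`, with epistasis exponent
#'     `t >= 1`; `t = 1` recovers the linear model.  Motivated by ectopic
#'     recombination whose rate grows faster than linearly with copy
#'     number.}
#'   \item{cluster_neutral}{`w = 1 - x * n_genomic`: cluster insertions
#'     (and reference insertions) are cost-free, only ordinary genomic
#'     copies are deleterious.}
#' }
#' Fitness is floored at 0; individuals with `w = 0` never reproduce.
#'
#' @param kind one of `"linear"`, `"exponential"`, `"cluster_neutral"`.
#' @param x per-copy fitness cost (>= 0).
#' @param t epistasis exponent (exponential model only, >= 1).
#' @return object of class `fitness_model`.
#' @export
fitness_model <- function(kind = c("linear", "exponential",
                                   "cluster_neutral"), x = 0, t = 1) {
  kind <- match.arg(kind)
  if (x < 0) stop("x must be >= 0")
  if (t < 1) stop("t must be >= 1")
  structure(list(kind = kind, x = x, t = t), class = "fitness_model")
}

# integer code used by the C++ engine
model_code <- function(kind) {
  match(kind, c("linear", "exponential", "cluster_neutral")) - 1L
}

#' Fitness of an individual
#'
#' Evaluates the fitness model on one individual's copy numbers.
#'
#' @param ind an individual ([get_individual()]) or a list with `hap1`,
#'   `hap2` site vectors.
#' @param arch the matching [build_architecture()] object.
#' @param model a [fitness_model()].
#' @return fitness `w` in \[0, 1\].
#' @examples
#' arch <- build_architecture(10, 4, 300)
#' ind <- list(hap1 = as.integer(5e6 + 0:4), hap2 = as.integer(6e6 + 0:4))
#' fitness(ind, arch, fitness_model("linear", x = 0.01))  # 0.9
#' @export
fitness <- function(ind, arch, model) {
  sites <- c(ind$hap1, ind$hap2)
  cls <- classify_site_safe(arch, sites)
  n_nonref <- sum(cls != "REFERENCE")
  n_genomic <- sum(cls == "GENOMIC")
  w <- switch(model$kind,
    linear = 1 - model$x * n_nonref,
    exponential = 1 - model$x * n_nonref^model$t,
    cluster_neutral = 1 - model$x * n_genomic
  )
  max(0, w)
}
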
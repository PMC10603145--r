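#' @useDynLib sexrolesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# draw an engine seed from R's RNG so that set.seed() governs the wrappers
random_engine_seed <- function() {
  sample.int(.Machine$integer.max, 1L)
}

#' Genome representation
#'
#' Every individual is haploid and carries four loci regardless of sex:
#' `careF` (care duration, expressed in females only), `careM` (expressed in
#' males only), `pref` (female mating preference) and `orn` (male ornament
#' size). Care alleles are non-negative integers; the continuous alleles are
#' real-valued.
#'
#' @param careF,careM non-negative integer care alleles (days).
#' @param pref,orn continuous preference and ornament alleles.
#' @return A named numeric vector of length 4 with class `sexrole_genome`.
#' @examples
#' genome(careF = 20, careM = 20)
#' @export
genome <- function(careF, careM, pref = 0, orn = 0) {
  if (careF < 0 || careM < 0 || careF != round(careF) || careM != round(careM)) {
    stop("care alleles must be non-negative integers")
  }
  g <- c(careF = as.numeric(careF), careM = as.numeric(careM),
         pref = as.numeric(pref), orn = as.numeric(orn))
  class(g) <- "sexrole_genome"
  g
}

#' Mendelian transmission with mutation
#'
#' Each child locus is copied from the mother or the father with probability
#' one half, independently per locus, and then mutates with probability `mu`
#' per locus: care loci step up or down by one day (clamped at 0), the
#' continuous loci receive a Cauchy-distributed step clipped to
#' `[-eps_max, eps_max]`.
#'
#' @param mother,father genomes as returned by [genome()] (or any numeric
#'   vector of the four alleles in order `careF, careM, pref, orn`).
#' @param n number of children to draw.
#' @param mu per-locus mutation probability.
#' @param cauchy_scale,eps_max continuous mutation kernel scale and cap.
#' @param ornament_floor clamp the ornament allele at 0.
#' @param seed optional engine seed; drawn from R's RNG when missing.
#' @return A data frame with columns `careF, careM, pref, orn`, one row per
#'   child.
#' @examples
#' set.seed(1)
#' make_child_genome(genome(10, 0), genome(20, 5), n = 3, mu = 0)
#' @export
make_child_genome <- function(mother, father, n = 1, mu = 0.005,
                              cauchy_scale = 0.01, eps_max = 0.05,
                              ornament_floor = TRUE, seed = NULL) {
  stopifnot(length(mother) == 4, length(father) == 4, n >= 1)
  if (is.null(seed)) seed <- random_engine_seed()
  m <- cpp_make_children(as.numeric(mother), as.numeric(father), as.integer(n),
                         mu, cauchy_scale, eps_max, isTRUE(ornament_floor),
                         seed)
  out <- as.data.frame(m)
  names(out) <- c("careF", "careM", "pref", "orn")
  out
}

#' Care-locus mutation kernel
#'
#' A mutated care allele moves up or down by exactly one day with equal
#' probability; a step below zero is clamped to zero. The mutation *event*
#' (probability `mu`) is decided by the caller; this function applies the
#' step.
#'
#' @param allele integer vector of care alleles.
#' @param seed optional engine seed; drawn from R's RNG when missing.
#' @return Integer vector of mutated alleles.
#' @examples
#' set.seed(1)
#' table(mutate_care_allele(rep(20L, 1000)))
#' @export
mutate_care_allele <- function(allele, seed = NULL) {
  if (any(allele < 0) || any(allele != round(allele))) {
    stop("care alleles must be non-negative integers")
  }
  if (is.null(seed)) seed <- random_engine_seed()
  cpp_mutate_care(as.integer(allele), seed)
}

#' Continuous-locus mutation kernel
#'
#' Adds a Cauchy(0, `scale`) step, clipped to `[-cap, cap]`, to each allele.
#' The heavy-tailed kernel allows occasional larger steps; the cap bounds the
#' per-event change.
#'
#' @param allele numeric vector of preference or ornament alleles.
#' @param scale Cauchy scale parameter.
#' @param cap maximum absolute step.
#' @param seed optional engine seed; drawn from R's RNG when missing.
#' @return Numeric vector of mutated alleles.
#' @examples
#' set.seed(1)
#' range(mutate_continuous_allele(rep(0, 1000)) )  # within +/- 0.05
#' @export
mutate_continuous_allele <- function(allele, scale = 0.01, cap = 0.05,
                                     seed = NULL) {
  stopifnot(scale > 0, cap > 0)
  if (is.null(seed)) seed <- random_engine_seed()
  cpp_mutate_continuous(as.numeric(allele), scale, cap, seed)
}

#' Random sex assignment
#'
#' Offspring sex is female or male with equal probability.
#'
#' @param n number of draws.
#' @param seed optional engine seed; drawn from R's RNG when missing.
#' @return A factor with levels `F`, `M`.
#' @examples
#' set.seed(1)
#' table(assign_sex(1000))
#' @export
assign_sex <- function(n, seed = NULL) {
  if (is.null(seed)) seed <- random_engine_seed()
  factor(c("F", "M")[cpp_assign_sex(as.integer(n), seed) + 1L],
         levels = c("F", "M"))
}
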
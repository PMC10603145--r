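#' Total parental effort
#'
#' Combined effect of female and male care on the offspring,
#' `Tf + Tm + sigma * Tf * Tm`. With `sigma = 0` the parents contribute
#' additively; positive `sigma` rewards biparental care synergistically.
#'
#' @param Tf,Tm non-negative care durations in days (vectorised).
#' @param sigma non-negative synergy coefficient.
#' @return Total effective care in days.
#' @examples
#' total_care(5, 5, 0.2)  # 15
#' @export
total_care <- function(Tf, Tm, sigma = 0) {
  if (any(!is.finite(Tf)) || any(!is.finite(Tm)) || !all(is.finite(sigma))) {
    stop("care durations and sigma must be finite")
  }
  if (any(Tf < 0) || any(Tm < 0)) stop("care durations must be non-negative")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  Tf + Tm + sigma * Tf * Tm
}

#' Offspring survival as a function of total care
#'
#' The saturating survival curve `S(T) = T^2 / (T^2 + B^2)`: sigmoidal in
#' total care, 0 at no care, 1/2 at `T = B`, approaching 1 for long care.
#'
#' @param Ttot non-negative total care in days (vectorised).
#' @param B positive half-saturation constant in days.
#' @return Survival proportion in `[0, 1)`.
#' @examples
#' offspring_survival(20, 20)  # 0.5
#' @export
offspring_survival <- function(Ttot, B = 20) {
  if (any(!is.finite(Ttot)) || any(Ttot < 0)) {
    stop("Ttot must be finite and non-negative")
  }
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be positive")
  Ttot^2 / (Ttot^2 + B^2)
}

#' Density-dependent recruitment factor
#'
#' Offspring survival is multiplied by `1 / (1 + gamma * N)`, where `N` is the
#' current population size; this regulates the population without altering
#' relative fitness.
#'
#' @param N non-negative population size (vectorised).
#' @param gamma non-negative density-dependence coefficient.
#' @return Multiplier in `(0, 1]`.
#' @examples
#' density_factor(4000, 0.003)  # 1/13
#' @export
density_factor <- function(N, gamma = 0.003) {
  if (any(N < 0)) stop("N must be non-negative")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  1 / (1 + gamma * N)
}

#' Mate-acceptance probability
#'
#' Probability that a female with preference `p` accepts an encountered male
#' with ornament size `s`: `1 / (1 + kappa * exp(alpha * (p - s)))`. For any
#' non-negative preference the probability increases with `s`, and females
#' with larger `p` discriminate more strongly against small ornaments. At the
#' default scaling, a plain male (`s = 0`) is accepted with probability 0.98
#' by a non-choosy female (`p = 0`) and 0.48 by a female with `p = 2`.
#'
#' @param p female preference (vectorised).
#' @param s male ornament size (vectorised).
#' @param kappa,alpha positive scaling constants.
#' @return Acceptance probability in `(0, 1)`.
#' @examples
#' round(acceptance_probability(0, 0), 2)  # 0.98
#' round(acceptance_probability(2, 0), 2)  # 0.48
#' @export
acceptance_probability <- function(p, s, kappa = 0.02, alpha = 2) {
  stopifnot(all(is.finite(p)), all(is.finite(s)), kappa > 0, alpha > 0)
  1 / (1 + kappa * exp(alpha * (p - s)))
}

#' Ornament viability cost multiplier
#'
#' A male with ornament size `s` has his per-day survival probability
#' multiplied by `1 - beta * s^2`. Values that would fall below 0 are clamped
#' to 0 with a warning.
#'
#' @param s ornament size (vectorised).
#' @param beta non-negative cost coefficient.
#' @return Survival multiplier in `[0, 1]`.
#' @examples
#' ornament_cost_multiplier(100, 1e-6)  # 0.99
#' @export
ornament_cost_multiplier <- function(s, beta = 1e-6) {
  if (any(beta < 0)) stop("beta must be non-negative")
  m <- 1 - beta * s^2
  if (any(m < 0)) {
    warning("ornament cost exceeds 1; survival multiplier clamped to 0")
    m <- pmax(m, 0)
  }
  m
}

#' Lifetime reproductive success under uniparental care
#'
#' With no pre-mating period, a lone caring parent re-mates immediately after
#' each care bout, so its expected number of matings is proportional to `1/T`
#' and its lifetime reproductive success to
#' `W(T) = S(T) / T = T / (T^2 + B^2)`, maximised at `T = B`. This makes `B`
#' the benchmark care duration for uniparental care.
#'
#' @param T positive care duration in days (vectorised).
#' @param B positive half-saturation constant in days.
#' @return Fitness-proportional value.
#' @examples
#' uniparental_lrs(20, 20)  # 0.025
#' which.max(uniparental_lrs(1:100, 20))  # 20
#' @export
uniparental_lrs <- function(T, B = 20) {
  if (any(!is.finite(T)) || any(T <= 0)) stop("T must be positive")
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be positive")
  T / (T^2 + B^2)
}
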
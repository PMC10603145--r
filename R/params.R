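#' Simulation parameters
#'
#' Constructs and validates the full parameter set of the model. Defaults
#' correspond to the baseline scenario: equal mortalities of 0.001 per day in
#' every state and sex (expected lifespan 1000 days, equated with one
#' "generation"), offspring-survival benchmark `B = 20` days, no parental
#' synergy, density regulation `gamma = 0.003` (population equilibrates around
#' 2000 females and 2000 males), mutation probability 0.005 per locus, and
#' random mating (the preference and ornament loci are carried but not
#' expressed unless `mate_choice = TRUE`).
#'
#' @param mortality per-day mortality probabilities, a 2 x 4 matrix with rows
#'   `c("F","M")` and columns `c("juvenile","premating","search","caring")`,
#'   or a single number used everywhere.
#' @param B half-saturation constant of the offspring-survival curve, in days
#'   of total care. Equals the optimal uniparental care duration.
#' @param sigma synergy coefficient: total effort is
#'   `Tf + Tm + sigma * Tf * Tm`.
#' @param gamma density-dependence coefficient per individual; offspring
#'   survival is divided by `1 + gamma * N`.
#' @param mu mutation probability per locus per offspring.
#' @param cauchy_scale scale of the Cauchy kernel for the continuous
#'   (preference/ornament) loci.
#' @param eps_max cap on the absolute continuous mutation step.
#' @param kappa,alpha scaling constants of the logistic mate-acceptance
#'   function.
#' @param beta ornament viability cost coefficient: a male of trait size `s`
#'   has his per-day survival multiplied by `1 - beta * s^2`.
#' @param maturation_days juvenile maturation time in days, length-2
#'   `c(F, M)` or a single number. Must be at least 1.
#' @param premating_days pre-mating period in days, length-2 `c(F, M)` or a
#'   single number; 0 means individuals pass straight into mate search.
#' @param clutch_size offspring per mating.
#' @param mate_choice logical; if `FALSE` (random mating) every encounter
#'   results in mating, if `TRUE` the female accepts with the logistic
#'   probability.
#' @param init_careF,init_careM initial monomorphic care alleles (days).
#' @param init_pref,init_orn initial preference and ornament alleles.
#' @param n0_per_sex initial number of adults per sex (all start in the mate
#'   search state).
#' @param seed integer seed for the engine's internal RNG stream.
#' @param generation_days reporting unit; 1000 days of the default mortality
#'   equal one expected lifespan.
#' @param ornament_floor logical; clamp the ornament allele at 0 (a physical
#'   size). The preference allele is unbounded either way.
#' @param survival_scale proportionality constant applied to offspring
#'   survival (1 by default, so survival probability equals
#'   `S(Ttot) / (1 + gamma * N)`).
#' @param hist_max top bin of the recorded care-allele histograms; larger
#'   alleles are counted in this bin.
#'
#' @return An object of class `sexrole_params` (a named list).
#' @examples
#' p <- sim_params(seed = 1, init_careF = 20, init_careM = 20)
#' p$B
#' @export
sim_params <- function(mortality = 0.001,
                       B = 20,
                       sigma = 0,
                       gamma = 0.003,
                       mu = 0.005,
                       cauchy_scale = 0.01,
                       eps_max = 0.05,
                       kappa = 0.02,
                       alpha = 2,
                       beta = 1e-6,
                       maturation_days = 20,
                       premating_days = 0,
                       clutch_size = 1,
                       mate_choice = FALSE,
                       init_careF = 20,
                       init_careM = 20,
                       init_pref = 0,
                       init_orn = 0,
                       n0_per_sex = 1000,
                       seed = 1,
                       generation_days = 1000,
                       ornament_floor = TRUE,
                       survival_scale = 1,
                       hist_max = 80) {
  if (is.null(dim(mortality))) {
    if (length(mortality) == 1) {
      mortality <- matrix(mortality, 2, 4)
    } else {
      stop("`mortality` must be a single number or a 2 x 4 matrix")
    }
  }
  mortality <- as.matrix(mortality)
  if (!all(dim(mortality) == c(2, 4))) {
    stop("`mortality` must be 2 x 4 (sex F/M by state juv/pre/search/care)")
  }
  dimnames(mortality) <- list(c("F", "M"),
                              c("juvenile", "premating", "search", "caring"))
  stopifnot(
    all(is.finite(mortality)), all(mortality >= 0), all(mortality <= 1),
    is.finite(B), B > 0,
    is.finite(sigma), sigma >= 0,
    is.finite(gamma), gamma >= 0,
    mu >= 0, mu <= 1,
    cauchy_scale > 0, eps_max > 0,
    kappa > 0, alpha > 0, beta >= 0,
    clutch_size >= 1,
    n0_per_sex >= 1,
    generation_days >= 1,
    survival_scale > 0, survival_scale <= 1,
    hist_max >= 1
  )
  maturation_days <- rep_len(as.integer(maturation_days), 2)
  premating_days <- rep_len(as.integer(premating_days), 2)
  if (any(maturation_days < 1)) stop("`maturation_days` must be >= 1")
  if (any(premating_days < 0)) stop("`premating_days` must be >= 0")
  if (init_careF < 0 || init_careM < 0 ||
      init_careF != round(init_careF) || init_careM != round(init_careM)) {
    stop("initial care alleles must be non-negative integers")
  }
  p <- list(
    mortality = mortality, B = B, sigma = sigma, gamma = gamma, mu = mu,
    cauchy_scale = cauchy_scale, eps_max = eps_max,
    kappa = kappa, alpha = alpha, beta = beta,
    maturation_days = maturation_days, premating_days = premating_days,
    clutch_size = as.integer(clutch_size),
    mate_choice = isTRUE(mate_choice),
    init_careF = as.integer(init_careF), init_careM = as.integer(init_careM),
    init_pref = init_pref, init_orn = init_orn,
    n0_per_sex = as.integer(n0_per_sex),
    seed = as.integer(seed),
    generation_days = as.integer(generation_days),
    ornament_floor = isTRUE(ornament_floor),
    survival_scale = survival_scale,
    hist_max = as.integer(hist_max)
  )
  class(p) <- "sexrole_params"
  p
}

#' @export
print.sexrole_params <- function(x, ...) {
  cat("<sexrole_params>\n")
  cat(sprintf("  B = %g, sigma = %g, gamma = %g, mu = %g\n",
              x$B, x$sigma, x$gamma, x$mu))
  cat(sprintf("  mating: %s (kappa = %g, alpha = %g, beta = %g)\n",
              if (x$mate_choice) "female choice" else "random", x$kappa,
              x$alpha, x$beta))
  cat(sprintf("  maturation F/M: %d/%d d, pre-mating F/M: %d/%d d\n",
              x$maturation_days[1], x$maturation_days[2],
              x$premating_days[1], x$premating_days[2]))
  cat(sprintf("  init care (F, M) = (%d, %d), n0 = %d per sex, seed = %d\n",
              x$init_careF, x$init_careM, x$n0_per_sex, x$seed))
  mr <- unique(as.vector(x$mortality))
  if (length(mr) == 1) {
    cat(sprintf("  mortality: %g per day in all states\n", mr))
  } else {
    cat("  mortality per day:\n")
    print(x$mortality)
  }
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running the
#' full validation.
#'
#' @param params a `sexrole_params` object.
#' @param ... fields to replace, as in [sim_params()].
#' @return A new `sexrole_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sexrole_params"))
  dots <- list(...)
  p <- unclass(params)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown parameter: ", nm)
    p[[nm]] <- dots[[nm]]
  }
  do.call(sim_params, p)
}
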
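# Scenario presets and replicate management.

#' Scenario configuration
#'
#' Bundles a named preset, parameter overrides, the desk-scale factor and
#' replicate bookkeeping. Presets:
#'
#' * `baseline`: random mating, no synergy — bistable sex-biased care
#'   reached through a transient within-sex polymorphism.
#' * `synergy`: biparental synergy (`sigma`, default 0.05) — fluctuating
#'   polymorphism at weak synergy, inefficient egalitarian care at
#'   `sigma = 0.2`.
#' * `lability`: baseline plus a 1-day pre-mating period in both sexes —
#'   long-run switches between the two biased regimes.
#' * `sexsel`: female choice switched on — joint evolution of care,
#'   preference and ornament.
#' * `premating`: a sex-specific pre-mating period (duration and pre-mating
#'   mortality configurable) — pre-mating investment shapes which sex cares.
#'
#' The scale factor multiplies `gamma`, shrinking the stationary population
#' (scale 8 gives roughly 250 individuals per sex at baseline) so that runs
#' finish at desk scale; the full-size population corresponds to
#' `scale = 1`.
#'
#' @param scenario preset name.
#' @param sigma synergy coefficient (synergy preset).
#' @param premating_sex which sex has the pre-mating period
#'   (premating preset).
#' @param premating_duration pre-mating period length in days
#'   (premating preset).
#' @param premating_mortality per-day mortality in the pre-mating state
#'   (premating preset).
#' @param scale density scale factor applied to `gamma`.
#' @param horizon_gen run length in generations (used by [run_scenario()]
#'   when `to_equilibrium = FALSE`, and as the generation cap otherwise).
#' @param replicates number of replicate simulations.
#' @param base_seed replicate `r` runs with seed `base_seed + r - 1`.
#' @param ... further [sim_params()] overrides (e.g. `init_careF`).
#' @return A `sexrole_scenario` list with `$params` fully resolved.
#' @examples
#' cfg <- scenario_config("baseline", scale = 8, horizon_gen = 50,
#'                        replicates = 2, base_seed = 1, n0_per_sex = 100)
#' @export
scenario_config <- function(scenario = c("baseline", "synergy", "lability",
                                         "sexsel", "premating"),
                            sigma = 0.05,
                            premating_sex = c("F", "M"),
                            premating_duration = 5,
                            premating_mortality = 0.001,
                            scale = 8, horizon_gen = 3000, replicates = 1,
                            base_seed = 1, ...) {
  scenario <- match.arg(scenario)
  premating_sex <- match.arg(premating_sex)
  over <- list(...)
  if (!"n0_per_sex" %in% names(over)) {
    # start near the scaled stationary size
    over$n0_per_sex <- max(50L, as.integer(round(2000 / scale)))
  }
  p <- do.call(sim_params, over)
  p <- update_params(p, gamma = p$gamma * scale)
  p <- switch(scenario,
    baseline = p,
    synergy = update_params(p, sigma = sigma),
    lability = update_params(p, premating_days = c(1, 1)),
    sexsel = update_params(p, mate_choice = TRUE),
    premating = {
      pre <- c(0L, 0L)
      pre[if (premating_sex == "F") 1 else 2] <- as.integer(premating_duration)
      m <- p$mortality
      m[, "premating"] <- premating_mortality
      update_params(p, premating_days = pre, mortality = m)
    })
  structure(list(scenario = scenario, params = p, scale = scale,
                 horizon_gen = horizon_gen, replicates = replicates,
                 base_seed = base_seed),
            class = "sexrole_scenario")
}

#' Run a scenario's replicates
#'
#' Runs `replicates` simulations with derived seeds `base_seed + 0, 1, ...`
#' and collects the trajectories and an outcome table. With
#' `to_equilibrium = TRUE` (default) each replicate runs through
#' [run_to_equilibrium()], stopping once a stable sex-biased regime has been
#' reached (or at the generation cap); otherwise each replicate runs for the
#' fixed horizon.
#'
#' @param config a [scenario_config()] object.
#' @param to_equilibrium stop replicates at a stable biased regime.
#' @param verbose print per-replicate progress lines.
#' @param ... passed to [run_to_equilibrium()].
#' @return A `sexrole_experiment` list: `$runs` (trajectories) and
#'   `$outcomes` (see [outcome_table()]).
#' @export
run_scenario <- function(config, to_equilibrium = TRUE, verbose = FALSE,
                         ...) {
  stopifnot(inherits(config, "sexrole_scenario"))
  runs <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    seed <- config$base_seed + r - 1
    p <- update_params(config$params, seed = seed)
    runs[[r]] <- if (to_equilibrium) {
      run_to_equilibrium(p, max_gen = config$horizon_gen, ...)
    } else {
      run_simulation(p, generations = config$horizon_gen)
    }
    runs[[r]]$pop <- NULL  # drop live engine state from stored replicates
    if (verbose) {
      cl <- classify_equilibrium(runs[[r]])
      message(sprintf("replicate %d/%d (seed %d): %s after %d generations",
                      r, config$replicates, seed, cl$label,
                      nrow(runs[[r]]$summary)))
    }
  }
  structure(list(config = config, runs = runs,
                 outcomes = outcome_table(runs)),
            class = "sexrole_experiment")
}

#' Replicate outcome table
#'
#' One row per replicate: seed, final regime label, final-window mean care
#' levels, the generation at which the mean care of the sexes first diverged
#' (NA when they never did), the number of persistent switches, and the
#' extinction flag.
#'
#' @param runs a list of `sexrole_traj` objects.
#' @param window trailing window (generations) for the final label and means.
#' @param diverge_gap absolute difference in mean care that counts as
#'   diverged.
#' @param persistence persistence window (generations) for switch counting.
#' @return A data frame.
#' @export
outcome_table <- function(runs, window = 50, diverge_gap = 5,
                          persistence = 100) {
  rows <- lapply(seq_along(runs), function(r) {
    tr <- runs[[r]]
    s <- tr$summary
    cl <- classify_equilibrium(tr, window = window)
    gap <- abs(s$care_f_mean - s$care_m_mean)
    div <- which(gap >= diverge_gap)
    labs <- label_trajectory(tr, window = min(10, max(1, nrow(s) %/% 10)))
    sw <- detect_switches(labs, persistence = persistence)
    data.frame(replicate = r, seed = tr$params$seed, label = cl$label,
               Tf = cl$Tf, Tm = cl$Tm,
               diverged_gen = if (length(div)) s$gen[div[1]] else NA_real_,
               switches = nrow(sw), extinct = tr$extinct)
  })
  do.call(rbind, rows)
}

#' @export
print.sexrole_experiment <- function(x, ...) {
  cat(sprintf("<sexrole_experiment> scenario '%s', %d replicates\n",
              x$config$scenario, x$config$replicates))
  print(table(x$outcomes$label))
  invisible(x)
}
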
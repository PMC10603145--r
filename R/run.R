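# High-level trajectory runs.

new_trajectory <- function(params, summary, hist_f, hist_m, extinct,
                           final_day, pop = NULL) {
  structure(list(params = params, summary = summary,
                 hist_f = hist_f, hist_m = hist_m,
                 extinct = extinct, final_day = final_day, pop = pop),
            class = "sexrole_traj")
}

#' Run an evolutionary simulation
#'
#' Initialises a population (monomorphic at the configured alleles, all
#' adults in the mate search state) and iterates the daily cycle for the
#' requested number of generations, recording per-generation summaries:
#' counts per sex and state, means/variances and integer histograms of the
#' expressed care alleles per sex, mean preference and ornament, and the
#' interval totals of matings, recruits, deaths and searcher-days.
#'
#' @param params a [sim_params()] object.
#' @param generations run length in generations (one generation =
#'   `params$generation_days` days).
#' @param record_every recording cadence in days; defaults to one generation.
#' @param keep_pop keep the live population in the returned object (for
#'   probing, snapshots or continued stepping).
#' @return A `sexrole_traj` object: `$summary` (data frame, one row per
#'   recording interval), `$hist_f`/`$hist_m` (per-interval care-allele
#'   histograms, one row per interval, bins `0:hist_max`), `$extinct`,
#'   `$final_day`, and optionally `$pop`.
#' @examples
#' tr <- run_simulation(sim_params(n0_per_sex = 60, gamma = 0.05, seed = 1),
#'                      generations = 2)
#' tail(tr$summary[, c("gen", "n", "care_f_mean", "care_m_mean")])
#' @export
run_simulation <- function(params, generations, record_every = NULL,
                           keep_pop = FALSE) {
  stopifnot(inherits(params, "sexrole_params"), generations >= 1)
  if (is.null(record_every)) record_every <- params$generation_days
  pop <- new_population(params)
  step_days(pop, days = generations * params$generation_days,
            record_every = record_every)
  rec <- collect_records(pop)
  new_trajectory(params, rec$summary, rec$hist_f, rec$hist_m,
                 extinct = is_extinct(pop), final_day = current_day(pop),
                 pop = if (keep_pop) pop else NULL)
}

#' Continue a simulation until a sex-biased regime is reached
#'
#' Steps the population in blocks and checks the equilibrium classifier on a
#' trailing window; once a stable female- or male-biased regime is detected
#' (or the generation cap is hit), runs `settle_gen` further generations so
#' that equilibrium quantities can be averaged over an equilibrated window.
#'
#' @param params a [sim_params()] object.
#' @param max_gen generation cap.
#' @param check_every classifier cadence in generations.
#' @param label_window trailing window (generations) handed to
#'   [classify_equilibrium()].
#' @param settle_gen extra generations run after detection.
#' @param bias_threshold absolute care-bias index above which a window counts
#'   as sex-biased.
#' @return A `sexrole_traj` with additional fields `$label` (the final
#'   [classify_equilibrium()] label over the last `label_window` generations)
#'   and `$reached_bias` (logical).
#' @export
run_to_equilibrium <- function(params, max_gen = 4000, check_every = 100,
                               label_window = 100, settle_gen = 200,
                               bias_threshold = 0.5) {
  stopifnot(inherits(params, "sexrole_params"))
  gd <- params$generation_days
  pop <- new_population(params)
  gen <- 0
  reached <- FALSE
  hits <- 0         # consecutive biased checks with a consistent sign
  last_sign <- 0
  while (gen < max_gen) {
    block <- min(check_every, max_gen - gen)
    step_days(pop, days = block * gd, record_every = gd)
    gen <- gen + block
    if (is_extinct(pop)) break
    if (gen >= label_window) {
      rec <- collect_records(pop, clear = FALSE)
      s <- rec$summary
      w <- s[s$gen > gen - label_window, , drop = FALSE]
      b <- care_bias(mean(w$care_f_mean), mean(w$care_m_mean))
      if (is.finite(b) && abs(b) > bias_threshold &&
          (hits == 0 || sign(b) == last_sign)) {
        hits <- hits + 1
        last_sign <- sign(b)
      } else {
        hits <- 0
        last_sign <- 0
      }
      # a regime counts as stable when two consecutive windows agree
      if (hits >= 2) {
        reached <- TRUE
        break
      }
    }
  }
  if (reached && settle_gen > 0 && !is_extinct(pop)) {
    step_days(pop, days = settle_gen * gd, record_every = gd)
  }
  rec <- collect_records(pop)
  tr <- new_trajectory(params, rec$summary, rec$hist_f, rec$hist_m,
                       extinct = is_extinct(pop), final_day = current_day(pop),
                       pop = pop)
  tr$reached_bias <- reached
  # the detected regime is the label; at small population sizes the
  # trajectory may already be wandering again by the end of the settle window
  tr$label <- if (reached) {
    if (last_sign > 0) "female_biased" else "male_biased"
  } else {
    tryCatch(classify_equilibrium(tr, window = label_window)$label,
             error = function(e) NA_character_)
  }
  tr
}

#' @export
print.sexrole_traj <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sexrole_traj> %d generations recorded%s\n",
              nrow(s), if (x$extinct) " (extinct)" else ""))
  if (nrow(s) > 0) {
    last <- s[nrow(s), ]
    cat(sprintf("  final: N = %d, mean care (F, M) = (%.2f, %.2f)\n",
                as.integer(last$n), last$care_f_mean, last$care_m_mean))
    if (x$params$mate_choice) {
      cat(sprintf("  mean preference %.3f, mean ornament %.3f\n",
                  last$pref_mean, last$orn_mean))
    }
  }
  invisible(x)
}

#' Plot care trajectories
#'
#' Mean female (solid) and male (dashed) care allele against generation.
#'
#' @param x a `sexrole_traj` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sexrole_traj <- function(x, ...) {
  s <- x$summary
  graphics::matplot(s$gen, cbind(s$care_f_mean, s$care_m_mean), type = "l",
                    lty = c(1, 2), col = c("firebrick", "steelblue"),
                    xlab = "generation", ylab = "mean care (days)", ...)
  graphics::legend("topright", c("female", "male"), lty = c(1, 2),
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Write a trajectory summary to CSV
#'
#' One row per recording interval, with the documented summary columns.
#'
#' @param traj a `sexrole_traj` object.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$summary, path, row.names = FALSE)
  invisible(path)
}
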
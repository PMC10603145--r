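# Population objects: thin R handles around the compiled engine state.

SEX_LEVELS <- c("F", "M")
STATE_LEVELS <- c("juvenile", "premating", "search", "caring")

#' Create a population
#'
#' Builds a fresh engine state from a parameter set. By default the
#' population is initialised with `n0_per_sex` adults of each sex, all in the
#' mate search state and monomorphic at the initial allele values. Pass
#' `individuals` to start from an explicit table instead (useful for fixtures
#' and restarts).
#'
#' @param params a [sim_params()] object. `params$seed` seeds the engine's
#'   RNG stream.
#' @param individuals optional data frame with columns `sex` (`"F"`/`"M"`),
#'   `state` (one of `"juvenile"`, `"premating"`, `"search"`, `"caring"`),
#'   `days_left`, `careF`, `careM`, `pref`, `orn`. Individuals in the caring
#'   state cannot be restored with live clutches; they are admitted only for
#'   low-level tests.
#' @return An object of class `sexrole_pop`.
#' @examples
#' pop <- new_population(sim_params(n0_per_sex = 50, seed = 1))
#' population_size(pop)
#' @export
new_population <- function(params, individuals = NULL) {
  stopifnot(inherits(params, "sexrole_params"))
  ptr <- cpp_pop_new(unclass(params), as.double(params$seed))
  if (is.null(individuals)) {
    cpp_pop_init_adults(ptr)
  } else {
    df <- individuals
    sex <- if (is.numeric(df$sex)) as.integer(df$sex) else
      match(as.character(df$sex), SEX_LEVELS) - 1L
    state <- if (is.numeric(df$state)) as.integer(df$state) else
      match(as.character(df$state), STATE_LEVELS) - 1L
    if (anyNA(sex) || anyNA(state)) stop("invalid sex or state codes")
    cpp_pop_set_individuals(ptr, sex, state,
                            as.integer(df$days_left),
                            as.integer(df$careF), as.integer(df$careM),
                            as.numeric(df$pref), as.numeric(df$orn))
  }
  structure(list(ptr = ptr, params = params), class = "sexrole_pop")
}

#' Step a population forward
#'
#' Runs the daily cycle (mortality, state advancement, clutch resolution,
#' mating) for `days` days, recording a summary every `record_every` days
#' (0 disables recording). Stops early if the population goes extinct.
#'
#' @param pop a `sexrole_pop` object (modified in place).
#' @param days number of days to simulate.
#' @param record_every recording cadence in days.
#' @return `pop`, invisibly.
#' @export
step_days <- function(pop, days, record_every = 0) {
  stopifnot(inherits(pop, "sexrole_pop"))
  cpp_pop_run(pop$ptr, as.integer(days), as.integer(record_every))
  invisible(pop)
}

#' Run a single phase of the daily cycle
#'
#' Low-level access for tracing the engine one phase at a time:
#' `"mortality"` (also increments the day counter), `"advance"`,
#' `"resolve"`, `"mating"`, or `"day"` for the complete cycle. Normal use
#' goes through [step_days()] or [run_simulation()].
#'
#' @param pop a `sexrole_pop` object.
#' @param phase one of `"day"`, `"mortality"`, `"advance"`, `"resolve"`,
#'   `"mating"`.
#' @return `pop`, invisibly.
#' @export
step_phase <- function(pop, phase = c("day", "mortality", "advance",
                                      "resolve", "mating")) {
  phase <- match.arg(phase)
  code <- match(phase, c("day", "mortality", "advance", "resolve", "mating")) - 1L
  cpp_pop_step_phase(pop$ptr, code)
  invisible(pop)
}

#' Individual table of a population
#'
#' @param pop a `sexrole_pop` object.
#' @return A data frame with one row per living individual: `id`, `sex`,
#'   `state`, `days_left`, the four alleles, and the clutch link (-1 when not
#'   caring).
#' @export
get_individuals <- function(pop) {
  df <- cpp_pop_individuals(pop$ptr)
  df$sex <- factor(SEX_LEVELS[df$sex + 1L], levels = SEX_LEVELS)
  df$state <- factor(STATE_LEVELS[df$state + 1L], levels = STATE_LEVELS)
  df
}

#' Unresolved clutch table of a population
#'
#' @param pop a `sexrole_pop` object.
#' @return A data frame of unresolved clutches with intended and (once a
#'   parent has stopped) realized care per parent; realized care is -1 while
#'   the parent is still caring.
#' @export
get_clutches <- function(pop) {
  cpp_pop_clutches(pop$ptr)
}

#' @rdname get_individuals
#' @export
population_size <- function(pop) cpp_pop_state(pop$ptr)$n

#' @rdname get_individuals
#' @export
current_day <- function(pop) cpp_pop_state(pop$ptr)$day

#' @rdname get_individuals
#' @export
is_extinct <- function(pop) cpp_pop_state(pop$ptr)$extinct

#' @export
print.sexrole_pop <- function(x, ...) {
  st <- cpp_pop_state(x$ptr)
  cat(sprintf("<sexrole_pop> day %d, %d individuals%s\n", st$day, st$n,
              if (st$extinct) " (extinct)" else ""))
  invisible(x)
}

# pull accumulated records into a tidy summary + histogram matrices
collect_records <- function(pop, clear = TRUE) {
  r <- cpp_pop_records(pop$ptr, clear)
  m <- r$summary
  colnames(m) <- c("day", "n", "n_f", "n_m",
                   "juv_f", "juv_m", "pre_f", "pre_m",
                   "search_f", "search_m", "care_f", "care_m",
                   "care_f_mean", "care_f_var", "care_m_mean", "care_m_var",
                   "pref_mean", "orn_mean",
                   "matings", "recruits", "deaths",
                   "search_days_f", "search_days_m")
  s <- as.data.frame(m)
  s$gen <- s$day / pop$params$generation_days
  list(summary = s, hist_f = r$hist_f, hist_m = r$hist_m)
}

#' Realized-care log
#'
#' The engine keeps a ring buffer (20,000 entries) of the realized female and
#' male care durations of resolved clutches, the empirical partner-strategy
#' distribution needed by the fitness-profile estimator.
#'
#' @param pop a `sexrole_pop` object.
#' @param min_day discard entries resolved before this day.
#' @return A data frame with columns `day`, `realizedF`, `realizedM`.
#' @export
clutch_log <- function(pop, min_day = 0) {
  df <- cpp_pop_clutch_log(pop$ptr)
  df[df$day >= min_day, , drop = FALSE]
}

#' Write and read population snapshots
#'
#' A snapshot is a CSV of the individual table plus a JSON sidecar holding the
#' full parameter set and the current day. Continuous alleles are written with
#' full precision, so a write/read round trip reproduces the table exactly.
#' Pending clutches are not serialized: snapshots are intended for populations
#' taken at a point where evolution is to be restarted (e.g. monomorphic or
#' search-state populations); caring individuals are restored in the
#' pre-mating state with their care clock cleared, and a note is emitted if
#' any were present.
#'
#' @param pop a `sexrole_pop` object.
#' @param path CSV file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_snapshot`: the path, invisibly. `read_snapshot`: a new
#'   `sexrole_pop`.
#' @export
write_snapshot <- function(pop, path) {
  df <- get_individuals(pop)
  df$clutch <- NULL
  df$probe <- NULL
  caring <- df$state == "caring"
  if (any(caring)) {
    message(sum(caring), " caring individuals written as pre-mating ",
            "(clutches are not serialized)")
    df$state[caring] <- "premating"
    df$days_left[caring] <- 1L
  }
  df$pref <- sprintf("%.17g", df$pref)
  df$orn <- sprintf("%.17g", df$orn)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- unclass(pop$params)
  meta$mortality <- as.vector(meta$mortality)
  jsonlite::write_json(list(day = current_day(pop), params = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_snapshot
#' @param params optional parameter set overriding the sidecar's.
#' @export
read_snapshot <- function(path, params = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(params)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    pl <- meta$params
    pl$mortality <- matrix(pl$mortality, 2, 4)
    params <- do.call(sim_params, pl)
  }
  new_population(params, individuals = df)
}
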
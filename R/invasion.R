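# Numerical adaptive dynamics: invasion fitness of a rare mutant care
# strategy against a monomorphic, sex-symmetric resident, and location of the
# singular (branching) strategy. Built from the same renewal estimator as the
# fitness profiles, with market statistics taken either from a short
# equilibrated simulation or from a deterministic balance of state flows.

#' Market statistics of a monomorphic resident
#'
#' For a sex-symmetric resident caring `resident_T` days, returns the
#' [market_stats()] needed by [invasion_fitness()], either
#' estimated from a short simulation at fixed alleles (`mode = "simulate"`,
#' mutation off, random mating) or from a deterministic self-consistent
#' balance of the flows between states (`mode = "balance"`).
#'
#' The balance mode iterates a fixed point: given the daily mating
#' probability `m`, the adult cycle length is `T + pre + 1/m` days; the
#' stationary population size follows from deaths = recruits under the
#' density rule; the expected searchers per sex per day set `m` anew via a
#' normal approximation to the expected matched fraction
#' `E[min(F, M)] / E[F]` of two equal near-Poisson searcher pools. The mode
#' assumes the mortalities of the baseline scenario are state- and
#' sex-uniform.
#'
#' @param resident_T resident care duration (days) of both sexes.
#' @param params a [sim_params()] object.
#' @param mode `"simulate"` or `"balance"`.
#' @param burnin_days,window_days simulate mode: days discarded and days
#'   measured.
#' @return A `sexrole_market` object (with `$extinct = TRUE` and NA entries
#'   when the resident cannot sustain a population).
#' @export
resident_market_stats <- function(resident_T, params,
                                  mode = c("simulate", "balance"),
                                  burnin_days = 3000, window_days = 3000) {
  mode <- match.arg(mode)
  stopifnot(resident_T >= 0)
  if (mode == "simulate") {
    p <- update_params(params, init_careF = resident_T,
                       init_careM = resident_T, mu = 0, mate_choice = FALSE)
    pop <- new_population(p)
    step_days(pop, burnin_days, record_every = 0)
    if (is_extinct(pop)) {
      return(structure(list(extinct = TRUE, m_f = NA, m_m = NA, N_bar = NA),
                       class = "sexrole_market"))
    }
    step_days(pop, window_days, record_every = p$generation_days)
    rec <- collect_records(pop)
    tr <- new_trajectory(p, rec$summary, rec$hist_f, rec$hist_m,
                         is_extinct(pop), current_day(pop), pop = pop)
    if (is_extinct(pop)) {
      return(structure(list(extinct = TRUE, m_f = NA, m_m = NA, N_bar = NA),
                       class = "sexrole_market"))
    }
    st <- market_stats(tr, window = nrow(rec$summary))
    st$extinct <- FALSE
    st
  } else {
    mu0 <- params$mortality[1, "search"]
    pre <- params$premating_days[1]
    mat <- params$maturation_days[1]
    S <- offspring_survival(total_care(resident_T, resident_T, params$sigma),
                            params$B)
    m <- 1
    N <- NA
    for (it in 1:50) {
      Lc <- resident_T + pre + 1 / m
      D <- S * params$survival_scale * params$clutch_size *
        (1 - mat * mu0) / (2 * Lc * mu0)
      if (!is.finite(D) || D <= 1) {
        return(structure(list(extinct = TRUE, m_f = NA, m_m = NA, N_bar = NA),
                         class = "sexrole_market"))
      }
      N <- (D - 1) / params$gamma
      A <- (N - mat * mu0 * N) / 2        # adults per sex
      lambda <- A / Lc / m                # searchers per sex per day
      m_new <- max(1e-6, 1 - 1 / sqrt(pi * lambda))
      if (abs(m_new - m) < 1e-10) { m <- m_new; break }
      m <- m_new
    }
    structure(list(
      extinct = FALSE, m_f = m, m_m = m, N_bar = N,
      pref_bar = 0, orn_bar = 0,
      partner_f = resident_T, partner_m = resident_T,
      window = NA
    ), class = "sexrole_market")
  }
}

#' Invasion fitness of a mutant care strategy
#'
#' Expected lifetime reproductive success of a rare mutant caring
#' `mutant_T` days in the market of a monomorphic resident caring
#' `resident_T` days, divided by the resident's own expected lifetime
#' reproductive success. Values above 1 mean the mutant can invade. Care is
#' treated as sex-independent, as an adaptive-dynamics analysis of this model
#' requires.
#'
#' @param mutant_T,resident_T mutant and resident care durations (days).
#' @param params a [sim_params()] object.
#' @param stats optional precomputed [resident_market_stats()]; computed in
#'   `"balance"` mode when missing.
#' @return Relative invasion fitness (1 on the diagonal up to estimator
#'   noise).
#' @export
invasion_fitness <- function(mutant_T, resident_T, params, stats = NULL) {
  if (is.null(stats)) {
    stats <- resident_market_stats(resident_T, params, mode = "balance")
  }
  if (isTRUE(stats$extinct)) return(NA_real_)
  pr <- estimate_fitness_profile(stats, sex = "F",
                                 grid = c(mutant_T, resident_T),
                                 params = params)
  pr$lrs[1] / pr$lrs[2]
}

#' Pairwise invasion grid
#'
#' Relative invasion fitness for every resident x mutant combination on an
#' integer grid; the raw material of a pairwise invasibility plot.
#'
#' @param params a [sim_params()] object.
#' @param residents,mutants integer strategy grids.
#' @param mode market-statistics mode, see [resident_market_stats()].
#' @param ... passed to [resident_market_stats()].
#' @return A matrix with residents in columns and mutants in rows, class
#'   `sexrole_invasion_grid`.
#' @export
invasion_grid <- function(params, residents = 0:20, mutants = residents,
                          mode = "balance", ...) {
  cols <- lapply(residents, function(rT) {
    st <- resident_market_stats(rT, params, mode = mode, ...)
    if (isTRUE(st$extinct)) return(rep(NA_real_, length(mutants)))
    pr <- estimate_fitness_profile(st, sex = "F", grid = c(mutants, rT),
                                   params = params)
    res_lrs <- pr$lrs[length(pr$lrs)]
    pr$lrs[seq_along(mutants)] / res_lrs
  })
  g <- do.call(cbind, cols)
  dimnames(g) <- list(mutant = mutants, resident = residents)
  class(g) <- c("sexrole_invasion_grid", class(g))
  g
}

#' Locate the singular care strategy
#'
#' Scans residents on an integer grid, computes the selection gradient by
#' one-sided finite differences (step 1 day, the mutational step size) and
#' reports where it changes sign from positive to negative coming from low
#' care. The singular strategy is classified as an evolutionary branching
#' point when the mutant fitness is locally convex there (both neighbouring
#' mutants invade relative to a flat profile), as an ESS otherwise, and as a
#' boundary outcome when the gradient never changes sign in the range.
#'
#' @param params a [sim_params()] object.
#' @param range integer vector of resident strategies to scan.
#' @param mode market-statistics mode, see [resident_market_stats()].
#' @param ... passed to [resident_market_stats()].
#' @return A list: `T_star` (singular strategy, grid resolution 1 day; NA for
#'   a boundary outcome), `type` (`"branching"`, `"ess"` or `"boundary"`),
#'   and `table` (per-resident gradient and curvature).
#' @export
find_singular_strategy <- function(params, range = 1:15, mode = "balance",
                                   ...) {
  range <- sort(unique(as.integer(range)))
  rows <- lapply(range, function(rT) {
    st <- resident_market_stats(rT, params, mode = mode, ...)
    if (isTRUE(st$extinct)) {
      return(data.frame(resident = rT, gradient = NA_real_,
                        curvature = NA_real_))
    }
    pr <- estimate_fitness_profile(st, sex = "F",
                                   grid = c(max(0, rT - 1), rT, rT + 1),
                                   params = params)
    lo <- pr$lrs[1]; mid <- pr$lrs[2]; hi <- pr$lrs[3]
    data.frame(resident = rT,
               gradient = (hi - lo) / (2 * mid),
               curvature = (hi + lo - 2 * mid) / mid)
  })
  tab <- do.call(rbind, rows)
  g <- tab$gradient
  T_star <- NA_real_
  type <- "boundary"
  for (i in seq_len(nrow(tab) - 1)) {
    if (is.na(g[i]) || is.na(g[i + 1])) next
    if (g[i] > 0 && g[i + 1] <= 0) {
      # sign change between residents i and i+1: take the one closer to zero
      T_star <- if (abs(g[i]) < abs(g[i + 1])) tab$resident[i] else
        tab$resident[i + 1]
      curv <- tab$curvature[tab$resident == T_star]
      type <- if (is.finite(curv) && curv > 0) "branching" else "ess"
      break
    }
  }
  list(T_star = T_star, type = type, table = tab)
}
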
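# Shared fixtures. Expensive simulations are memoised per test session so
# that several test files (and the acceptance checks) can share one run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# desk-scale study conditions: single trajectories at density scale 8
# (~250 individuals per sex), replicate ensembles at scale 16 (~125 per
# sex); the mutation rate is scaled by 8 in both so that the mutational
# input per generation stays comparable to the full-size population
scaled_params <- function(scale = 8, mu_scale = 8, ...) {
  sim_params(gamma = 0.003 * scale, mu = 0.005 * mu_scale,
             n0_per_sex = as.integer(round(2000 / scale)), ...)
}

# one baseline trajectory from egalitarian high care through branching and
# sex-role divergence (shared by the branching, equilibrium and profile
# checks)
baseline_run <- function() {
  fixture("baseline_run", function() {
    p <- scaled_params(seed = 1, init_careF = 20, init_careM = 20)
    run_to_equilibrium(p, max_gen = 4000)
  })
}

# ensemble of baseline replicates from the symmetric egalitarian start,
# run until the classifier assigns a stable biased regime
symmetric_ensemble <- function(n_rep = 30, base_seed = 1000) {
  fixture("symmetric_ensemble", function() {
    labels <- character(n_rep)
    for (r in seq_len(n_rep)) {
      p <- scaled_params(scale = 16, seed = base_seed + r - 1,
                        init_careF = 20, init_careM = 20)
      tr <- run_to_equilibrium(p, max_gen = 4000)
      labels[r] <- tr$label
    }
    labels
  })
}

# a small population table with every state represented, for hand-traced
# accounting tests
tiny_population <- function(n = 5) {
  data.frame(
    sex = c("F", "F", "M", "M", "F"),
    state = c("search", "juvenile", "search", "premating", "search"),
    days_left = c(0L, 3L, 0L, 2L, 0L),
    careF = c(10L, 12L, 14L, 16L, 18L),
    careM = c(1L, 2L, 3L, 4L, 5L),
    pref = 0, orn = 0
  )[seq_len(n), ]
}

# a two-individual population used for deterministic cycle traces
pair_population <- function(careF, careM) {
  data.frame(
    sex = c("F", "M"),
    state = "search", days_left = 0L,
    careF = as.integer(careF), careM = as.integer(careM),
    pref = 0, orn = 0
  )
}

# deathless parameters: mortality zero everywhere, no mutation
deathless_params <- function(...) {
  sim_params(mortality = 0, mu = 0, beta = 0, ...)
}
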
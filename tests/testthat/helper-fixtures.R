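# Shared fixtures, built in code and memoised across test files (kinetic
# simulations are the expensive part; every cache entry is deterministic).

.fx <- new.env(parent = emptyenv())

frob_diff <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)), 1e-300)

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_model <- function() fx("model", load_model())

fx_eq <- function() fx("eq", equilibrate_model(fx_model(), basal = 1e-4))

# standard comparison grid (hours)
fx_grid <- function() c(0, 0.5, 2, 4, 6, 12)

# moderate candidate grid containing the canonical ground-truth pulse
fx_candidates <- function() {
  fx("candidates", generate_candidates(
    peak_times = c(0.5, 2, 4, 6), peak_heights = c(0.05, 0.1, 0.2),
    decay_fractions = c(0.25, 0.5, 0.75), basal = 1e-4))
}

fx_truth <- function() {
  cands <- fx_candidates()
  ids <- vapply(cands, `[[`, "", "id")
  cands[[which(ids == "pk0.5_h0.1_d0.5")]]
}

fx_activities <- function() {
  fx("activities", candidate_activities(fx_model(), fx_candidates(), fx_grid()))
}

# forward-simulated relative NF-kB activity of the ground-truth IKK pulse
fx_truth_shape <- function() {
  fx("truth_shape", {
    traj <- simulate_model(fx_eq(), fx_truth(), t_end = max(fx_grid()),
                           equilibrate = FALSE)
    as.numeric(sim_to_activity(nfkb_activity(traj, fx_grid()),
                               total = moiety_total(fx_eq())))
  })
}

# canonical end-to-end bundle: default-size spec, noise 0.1, seed 0
fx_bundle <- function() {
  fx("bundle", gen_end_to_end(fx_truth(), fx_model(),
                              synthetic_spec(seed = 0, noise_sd = 0.1),
                              nfkb_shape = fx_truth_shape()))
}

fx_bundle_fit <- function() {
  fx("bundle_fit", fit_nca(fx_bundle()$expr, fx_bundle()$net, seed = 0))
}

# small identifiable two-TF instance for fast NCA tests
small_spec <- function(noise_sd = 0, seed = 3) {
  synthetic_spec(n_genes = 12, n_tfs = 2, n_edges = 17, noise_sd = noise_sd,
                 seed = seed, conditions = "c1", amplitudes = 1)
}

# tiny one-reaction model written to a temp YAML
write_tiny_model <- function(reactions_yaml, species_yaml = NULL) {
  if (is.null(species_yaml)) {
    species_yaml <- "
species:
  - {name: A, compartment: cytoplasm, init: 1}
  - {name: B, compartment: cytoplasm, init: 3}
  - {name: C, compartment: cytoplasm, init: 0}
"
  }
  path <- tempfile(fileext = ".yaml")
  writeLines(paste0("kv: 0.5\n", species_yaml, "\nreactions:\n", reactions_yaml), path)
  path
}
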
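# Shared fixtures: a CPV17-like cubic I23 toy experiment. Heavy objects
# (priors with their reflection-enumeration caches) are built once and
# reused across test files.

.fx <- new.env(parent = emptyenv())

toy_cell <- function() unit_cell(106.1)

toy_geometry <- function(distance_mm = 101.2)
  detector_geometry(distance_mm, c(512, 512), 0.11, 1024, 1024)

toy_beam <- function() beam(1.46, bandwidth = 6e-4)

toy_priors <- function() {
  if (is.null(.fx$priors))
    .fx$priors <- crystal_priors(toy_cell(), "I23", d_max = 0.08)
  .fx$priors
}

toy_spec <- function(...) {
  simulation_spec(geometry = toy_geometry(), beam = toy_beam(), ...)
}

toy_params <- function(...) {
  indexing_params(method = "network", d_max = 0.08, ...)
}

# A cached noise-free single-lattice image (used by several oracle tests).
toy_clean_sim <- function() {
  if (is.null(.fx$clean))
    .fx$clean <- simulate_image(toy_spec(jitter_px = 0, n_noise_spots = 0),
                                1, toy_priors())
  .fx$clean
}

# Hand-built spot_vectors object for small synthetic cases.
manual_vectors <- function(delta, matches = NULL, i = NULL, j = NULL) {
  n <- nrow(delta)
  structure(list(i = if (is.null(i)) seq_len(n) else i,
                 j = if (is.null(j)) seq_len(n) + n else j,
                 delta = delta, length = sqrt(rowSums(delta^2)),
                 matches = matches),
            class = "spot_vectors")
}
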
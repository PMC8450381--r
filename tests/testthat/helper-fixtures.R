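# Shared fixtures, built once per test run and memoised.
# - dev_grid: 8x8 (Cm, Cb) lattice at 5e3 photons/band -- cheap, noisy,
#   used by module-level behavioural tests.
# - acceptance_grid: 10x10 lattice at 1e5 photons/band -- the conditions
#   the headline regression statistics are quoted at; shared by the
#   acceptance blocks so it is simulated only once.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

dev_grid <- function() {
  memo("dev_grid", function() {
    build_training_grid(8, 8, photon_config(5e3, seed = 11))
  })
}

dev_assets <- function() {
  memo("dev_assets", function() pipeline_assets(dev_grid()))
}

acceptance_grid <- function() {
  memo("acceptance_grid", function() {
    build_training_grid(10, 10, photon_config(1e5, seed = 101))
  })
}

# 256-bin histogram Shannon entropy (the grid-search oracle criterion)
hist_entropy <- function(v, n_bins = 256) {
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1, 1), n_bins), n_bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

# brute-force entropy-maximizing gamma by grid scan
gamma_entropy_scan <- function(u, gammas = seq(0.1, 3, by = 0.001)) {
  ent <- vapply(gammas, function(g) hist_entropy(u^g), numeric(1))
  gammas[which.max(ent)]
}

# total variation of a 2-D field (sum of absolute forward differences)
total_variation <- function(m) {
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

dice_overlap <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
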
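# shared fixtures, built once per test run and cached
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small niche simulation: enough frames for coupling analyses, quick render
small_niche_cfg <- function(rng_seed = 7L, ...) {
  niche_config(field_length_px = 240, duration_min = 90, n_cells = 36,
               onset_boundary_start_px = 80, rng_seed = rng_seed, ...)
}

small_niche_truth <- function() fixture("niche_truth", function() {
  simulate_transcription(simulate_camp_field(small_niche_cfg()),
                         preset_carA())
})

small_render <- function() fixture("niche_render", function() {
  render_stack(small_niche_truth(), height_px = 48)
})

# reduced-size counts fixture for unit tests (full-size ones live in the
# acceptance suite)
small_counts_cfg <- function(rng_seed = 11L, ...) {
  counts_config(replicate_sizes = c(700L, 500L), rng_seed = rng_seed, ...)
}

small_counts_sim <- function() fixture("counts_sim", function() {
  simulate_counts(small_counts_cfg())
})

small_counts_norm <- function() fixture("counts_norm", function() {
  normalize_counts(small_counts_sim()$conditions$WT)
})

ribo_genes <- function(norm) grep("^ribo", rownames(norm$log_mat),
                                  value = TRUE)

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  (sij - expected) / ((ai + bj) / 2 - expected)
}

# greedy matching of detected events/spots to truth within tolerances
match_fraction <- function(det, truth, cols, tol) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    ok <- rep(TRUE, nrow(det))
    for (j in seq_along(cols)) {
      ok <- ok & abs(det[[cols[j]]] - truth[[cols[j]]][i]) <= tol[j]
    }
    any(ok)
  }, logical(1))
  mean(hit)
}
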
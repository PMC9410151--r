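# Shared fixtures, built once per test run and memoised. All rendering in the
# unit tests uses the tight field (grid bounding box + 8 mm margin) to keep
# the suite fast; full-field behaviour is covered by dimension checks.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) {
    .fixture_env[[name]] <- force(expr)
  }
  .fixture_env[[name]]
}

test_phantom <- function() {
  get_fixture("phantom", cdmam_phantom(corner_seed = 7))
}

# One noisy ST N-mode render + scored matrices
test_render_st <- function() {
  get_fixture("render_st", {
    render_phantom(test_phantom(), acquisition_config("TL", "ST", "N"),
                   seed = 101, field = "tight")
  })
}

test_dm_st <- function() {
  get_fixture("dm_st", score_image(test_render_st()$image, test_phantom()))
}

# Noise-free render (high-visibility limit for oracle checks)
test_render_noiseless <- function() {
  get_fixture("render_noiseless", {
    render_phantom(test_phantom(), acquisition_config("TL", "ST", "N"),
                   seed = 1, field = "tight", noiseless = TRUE)
  })
}

# Zero-contrast render (pure background; chance-level behaviour)
test_render_zero <- function() {
  get_fixture("render_zero", {
    render_phantom(test_phantom(),
                   acquisition_config("TL", "ST", "N", mu_gold = 0),
                   seed = 7, field = "tight")
  })
}
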
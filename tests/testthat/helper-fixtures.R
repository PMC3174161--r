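# Shared fixtures.  Expensive objects (a settled spiral) are prepared once
# per test session and cached; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The package's working-point spiral: alpha = 0.65, D = 0.0025 mm^2/ms
# (coupling 0.25/ms at h = 0.1 mm), 120 x 120 box.  Rotor with a slow
# circular tip orbit of radius ~5 cells and period ~1.9 s.
test_spiral <- function() {
  cached("spiral65", {
    sp <- prepare_spiral(alpha = 0.65, D = 0.0025, n = 120, settle = 800)
    stopifnot(sp$ok)
    sp
  })
}

test_spiral_mirror <- function() {
  cached("spiral65m", {
    sp <- prepare_spiral(alpha = 0.65, D = 0.0025, n = 120, settle = 800,
                         chirality = -1)
    stopifnot(sp$ok)
    sp
  })
}

# rest state at the default working point
test_rest <- function(alpha = 0) {
  cached(paste0("rest", alpha), find_rest_state(brp_params(alpha)))
}
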
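# Small deterministic fixtures shared across test files. All data are
# generated in code; nothing is read from disk.

tiny_grid <- function(d = c(6, 5, 4), voxdim = c(1, 1, 1)) {
  volume_grid(d[1], d[2], d[3], voxdim[1], voxdim[2], voxdim[3])
}

tiny_series <- function(d = c(6, 5, 4), nt = 40, tr = 1.6, seed = 1,
                        baseline = 100, sd = 1) {
  g <- tiny_grid(d)
  set.seed(seed)
  bold_series(array(rnorm(prod(d) * nt, baseline, sd), c(d, nt)), g, tr)
}

full_mask <- function(series) {
  brain_mask(array(TRUE, dim = series$grid$dim), series$grid)
}

# Phantom small enough for repeated denoising / ICA in tests.
test_phantom <- function(seed = 42, ...) {
  generate_phantom(phantom_spec(dim = c(16, 16, 4), n_frames = 120,
                                n_roi_per_hemi = 4, seed = seed, ...))
}
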
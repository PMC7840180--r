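# Shared fixtures, built once per test session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, .fixture_cache)) assign(key, fn(), .fixture_cache)
  get(key, .fixture_cache)
}

# small atlas phantom for fast unit tests
small_phantom <- function() {
  memo("small_phantom", function() {
    spec <- phantom_spec(shape = c(32, 32, 32), n_pois = 10, seed = 17)
    c(make_atlas_phantom(spec), list(spec = spec))
  })
}

# deformed sample with modality remap + noise on the 32^3 phantom
small_sample <- function() {
  memo("small_sample", function() {
    spec <- phantom_spec(shape = c(32, 32, 32), n_pois = 10,
                         deform_max = 3, noise_sd = 0.1, seed = 17)
    ap <- make_atlas_phantom(spec)
    c(make_sample_from_atlas(ap, spec), list(atlas = ap, spec = spec))
  })
}

# simple linear-ramp volume: slice j (0-based) has constant value j
ramp_volume <- function(nx = 8, ny = 8, nz = 21, spacing = c(1, 1, 10)) {
  Volume(array(rep(0:(nz - 1), each = nx * ny), dim = c(nx, ny, nz)),
         spacing = spacing)
}

grid_of <- function(vol) birdreg:::vol_grid(vol)

voxel_to_phys_pts <- function(g) {
  idx <- birdreg:::grid_index_matrix(g$shape)
  birdreg:::voxel_to_phys(idx, g)
}
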
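# Shared fixture builders. Everything is constructed in code; no data files.

# straight-line track with constant per-frame step
straight_track <- function(n_steps, step_um, dt = 5, id = 1L) {
  data.frame(
    track_id = id, frame = 0:n_steps, t_s = (0:n_steps) * dt,
    x_um = cumsum(c(0, rep(step_um, n_steps))), y_um = 0
  )
}

# track from explicit per-frame step lengths (all along +x)
track_from_steps <- function(steps, dt = 5, id = 1L) {
  data.frame(
    track_id = id, frame = seq(0, length(steps)), t_s = seq(0, length(steps)) * dt,
    x_um = cumsum(c(0, steps)), y_um = 0
  )
}

# minimal SWC node table builder
swc_nodes <- function(...) {
  m <- matrix(c(...), ncol = 7, byrow = TRUE)
  as_swc_morphology(data.frame(
    id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6], parent = m[, 7]
  ))
}

# unbranched radial neurite of given length along +x, 1 um node spacing
radial_neurite <- function(length_um, type = 2L) {
  n <- length_um
  as_swc_morphology(data.frame(
    id = 1:(n + 1), type = c(1L, rep(type, n)), x = 0:n, y = 0, z = 0,
    radius = c(1, rep(0.3, n)), parent = c(-1L, 1:n)
  ))
}

# random tree via the generator, varying seeds
random_morph <- function(seed, ba = 4, bd = 3) {
  gen_morphology(ba, bd, seed = seed)
}

# a voxel stack holding given positive voxel centers (um) on a unit grid
stack_with_positives <- function(centers_um, voxel_size = 1, dims = c(21, 21, 21),
                                 origin = c(-10, -10, -10)) {
  arr <- array(FALSE, dims)
  for (i in seq_len(nrow(centers_um))) {
    idx <- round((centers_um[i, ] - origin) / voxel_size) + 1
    arr[idx[1], idx[2], idx[3]] <- TRUE
  }
  voxel_stack(arr, voxel_size, origin)
}

expect_mitodyn_error <- function(expr) {
  expect_error(expr, class = "mitodyn_error")
}
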
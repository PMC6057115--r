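# Brute-force oracles and small fixture builders shared across tests.
# The oracles enumerate windows / runs / neighborhoods directly and stay
# independent of the package's log-space, shift-based implementations.

make_volume <- function(a, px = 100, sl = 70, name = "test") {
  image_volume(a, pixel_size_xy = px, slice_thickness = sl, channel_name = name)
}

prob_map <- function(values, stage = "punctum3d", px = 100, sl = 70,
                     name = "test") {
  synscreen:::new_probability_map(
    values, stage,
    list(pixel_size_xy = px, slice_thickness = sl, channel_name = name))
}

noise_volume <- function(dz, dy, dx, mean = 1000, sd = 100, seed = 1) {
  set.seed(seed)
  make_volume(pmax(array(rnorm(dz * dy * dx, mean, sd), c(dz, dy, dx)), 0))
}

# max over fully-interior wy x wx windows containing each pixel of the
# product over the window, slice by slice
bf_blob2d <- function(a, wy, wx) {
  d <- dim(a)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    best <- 0
    for (ay in max(1, y - wy + 1):min(y, d[2] - wy + 1))
      for (ax in max(1, x - wx + 1):min(x, d[3] - wx + 1)) {
        if (ay < 1 || ax < 1) next
        best <- max(best, prod(a[z, ay:(ay + wy - 1), ax:(ax + wx - 1)]))
      }
    out[z, y, x] <- best
  }
  out
}

# max over runs of s consecutive slices containing z of the product over the
# run, per (y, x) column
bf_span <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    best <- 0
    for (az in max(1, z - s + 1):min(z, d[1] - s + 1)) {
      if (az < 1) next
      best <- max(best, prod(a[az:(az + s - 1), y, x]))
    }
    out[z, y, x] <- best
  }
  out
}

# max over the clipped box neighborhood with in-plane reach (ry, rx) and
# slice reach rz
bf_assoc <- function(a, ry, rx, rz) {
  d <- dim(a)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    out[z, y, x] <- max(a[max(1, z - rz):min(d[1], z + rz),
                          max(1, y - ry):min(d[2], y + ry),
                          max(1, x - rx):min(d[3], x + rx)])
  out
}

# random probability volume with a mix of zeros, small and near-1 values
random_prob_array <- function(dz, dy, dx, seed) {
  set.seed(seed)
  a <- array(runif(dz * dy * dx), c(dz, dy, dx))
  a[sample(length(a), length(a) %/% 10)] <- 0
  a
}

default_synapse_query <- function(threshold = 0.9,
                                  kind = "adjacent",
                                  candidate_span_um = 0.14,
                                  reference_span_um = 0.14) {
  synapse_query(
    punctum_query("candidate", min_span_z_um = candidate_span_um),
    list(query = punctum_query("reference", min_span_z_um = reference_span_um),
         rel = relationship(kind)),
    threshold = threshold)
}
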
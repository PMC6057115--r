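test_that("relationship defaults follow the colocalized/adjacent windows", {
  co <- relationship("colocalized")
  ad <- relationship("adjacent")
  expect_identical(co$window_xy, c(2L, 2L)); expect_identical(co$z_reach, 0L)
  expect_identical(ad$window_xy, c(6L, 6L)); expect_identical(ad$z_reach, 1L)
  expect_error(relationship("adjacent", window_xy = 1), "at least")
  expect_error(synapse_query(punctum_query("a"), list()), "reference")
  expect_error(synapse_query(
    punctum_query("a"),
    list(query = punctum_query("a"), rel = co)), "distinct")
})

test_that("association factor is the neighborhood max, matching the oracle", {
  a <- array(0, c(5, 16, 16))
  expect_equal(association_factor(prob_map(a), relationship("adjacent"))$values,
               a)  # all zeros stay zero

  a[3, 8, 8] <- 0.95
  f <- association_factor(prob_map(a), relationship("adjacent"))
  # 6x6 window -> in-plane reach 3; z reach 1
  expect_equal(f$values[3, 8, 11], 0.95)
  expect_equal(f$values[3, 8, 12], 0)
  expect_equal(f$values[2, 11, 11], 0.95)
  expect_equal(f$values[1, 8, 8], 0)
  expect_equal(f$values, bf_assoc(a, 3, 3, 1))

  # brute-force equivalence on random maps, both relationship kinds
  for (seed in c(7, 8)) {
    r <- random_prob_array(5, 16, 16, seed)
    expect_equal(
      association_factor(prob_map(r), relationship("colocalized"))$values,
      bf_assoc(r, 1, 1, 0), tolerance = 1e-12)
    expect_equal(
      association_factor(prob_map(r), relationship("adjacent"))$values,
      bf_assoc(r, 3, 3, 1), tolerance = 1e-12)
    # colocalization searches a nested neighborhood
    expect_true(all(
      association_factor(prob_map(r), relationship("colocalized"))$values <=
        association_factor(prob_map(r), relationship("adjacent"))$values))
  }
  expect_error(association_factor(prob_map(array(0, c(2, 4, 4))),
                                  relationship("adjacent")), "extent")
})

test_that("synapse probability is the candidate map gated by the references", {
  ds <- generate_dataset(synthetic_spec(shape = c(6, 96, 96), n_candidate = 8,
                                        colocalization_fraction = 1, seed = 71))
  q <- default_synapse_query(kind = "colocalized")
  sp <- synapse_probability(ds$channels, q)
  expect_equal(sp$stage, "synapse")
  cand <- compute_punctum_probability(ds$channels$candidate, q$candidate)
  # product with factors in [0,1] can only shrink the candidate probability
  expect_true(all(sp$values <= cand$values + 1e-12))
  # a perfectly colocalized pair of roughly equal probability: p^2 at center
  i <- which(ds$truth$channel == "candidate")[1]
  ctr <- as.integer(ds$truth[i, c("z", "y", "x")])
  p <- cand$values[ctr[1], ctr[2], ctr[3]]
  expect_equal(sp$values[ctr[1], ctr[2], ctr[3]], p^2, tolerance = 0.01)
  # an extra reference with no puncta annihilates every detection
  set.seed(72)
  d <- dim(ds$channels$reference$intensities)
  ds$channels$nullref <- make_volume(
    pmax(array(rnorm(prod(d), 1000, 100), d), 0), name = "nullref")
  q2 <- synapse_query(q$candidate,
                      list(list(query = punctum_query("reference"),
                                rel = relationship("colocalized")),
                           list(query = punctum_query("nullref"),
                                rel = relationship("colocalized"))))
  sp2 <- synapse_probability(ds$channels, q2)
  s2 <- segment_puncta(sp2, 0.9)
  s1 <- segment_puncta(sp, 0.9)
  expect_equal(nrow(s2$puncta), 0L)        # adding a reference cannot add synapses
  expect_lte(nrow(s2$puncta), nrow(s1$puncta))
  expect_lt(max(sp2$values), 0.9)
})

test_that("misaligned channel shapes are refused", {
  ds <- generate_dataset(synthetic_spec(shape = c(4, 32, 32), n_candidate = 0,
                                        seed = 1))
  ds$channels$reference <- noise_volume(4, 32, 16, seed = 2)
  ds$channels$reference$channel_name <- "reference"
  expect_error(synapse_probability(ds$channels, default_synapse_query()),
               "not aligned")
})

test_that("offset pairs are found by adjacency but not colocalization", {
  # candidate at center, reference 5 px away in-plane: outside the 2x2
  # colocalization search (reach 1) but close enough for a punctum whose
  # footprint edge falls within the 6x6 adjacency search (reach 3)
  mk <- function(yoff) {
    a <- pmax(array(rnorm(6 * 64 * 64, 1000, 100), c(6, 64, 64)), 0)
    for (dz in 2:4) for (dy in -1:1) for (dx in -1:1)
      a[dz, 32 + dy + yoff, 32 + dx] <- a[dz, 32 + dy + yoff, 32 + dx] + 1000
    make_volume(a)
  }
  set.seed(81)
  chans <- list(candidate = mk(0), reference = mk(5))
  chans$candidate$channel_name <- "candidate"
  chans$reference$channel_name <- "reference"
  n_coloc <- nrow(detect_synapses(chans,
                                  default_synapse_query(kind = "colocalized"))$puncta)
  n_adj <- nrow(detect_synapses(chans,
                                default_synapse_query(kind = "adjacent"))$puncta)
  expect_equal(n_coloc, 0L)
  expect_equal(n_adj, 1L)
})

test_that("planted synapses are counted and monotone in query stringency", {
  ds <- generate_dataset(synthetic_spec(n_candidate = 50,
                                        adjacency_fraction = 0.6, seed = 91))
  syn <- detect_synapses(ds$channels, default_synapse_query())
  expect_s3_class(syn, "synapse_set")
  expect_equal(nrow(syn$puncta), 30L)      # 60% of 50 planted partners
  expect_identical(syn$query$threshold, 0.9)
  # span 2 is at least as strict as span 1
  n1 <- nrow(detect_synapses(ds$channels,
                             default_synapse_query(candidate_span_um = 0.07,
                                                   reference_span_um = 0.07))$puncta)
  expect_lte(nrow(syn$puncta), n1)
  # enlarging the search window never decreases the probability
  ref <- compute_punctum_probability(ds$channels$reference,
                                     punctum_query("reference"))
  f6 <- association_factor(ref, relationship("adjacent"))
  f8 <- association_factor(ref, relationship("adjacent", window_xy = 8))
  expect_true(all(f6$values <= f8$values + 1e-12))
})

test_that("swapping candidate and reference preserves colocalized counts", {
  ds <- generate_dataset(synthetic_spec(shape = c(6, 128, 128),
                                        n_candidate = 15,
                                        colocalization_fraction = 1,
                                        seed = 101))
  q_fwd <- default_synapse_query(kind = "colocalized")
  q_rev <- synapse_query(
    punctum_query("reference"),
    list(query = punctum_query("candidate"),
         rel = relationship("colocalized")))
  expect_equal(nrow(detect_synapses(ds$channels, q_fwd)$puncta),
               nrow(detect_synapses(ds$channels, q_rev)$puncta))
})
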
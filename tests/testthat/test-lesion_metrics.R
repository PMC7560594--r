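test_that("C1'-C1' series measures plain Euclidean distance per frame", {
  xyz <- rbind(c(0, 0, 0), c(10.5, 0, 0))
  st <- toy_structure(xyz, element = "C", chain = c("I", "J"),
                      resno = c(1L, 2L), name = c("C1'", "C1'"),
                      resname = "DA")
  tr <- toy_trajectory(st, list(xyz, xyz, xyz))
  spec <- site_spec(lesion = list(chain = "I", resno = 1),
                    facing = list(chain = "J", resno = 2),
                    section_i = list(chain = "I", from = 1, to = 1),
                    section_j = list(chain = "J", from = 2, to = 2))
  s <- c1p_distance_series(tr, spec)
  expect_equal(s$values, rep(10.5, 3))
  # canonical built pair stays in the B-DNA range every frame
  st2 <- fixture_duplex()
  d <- c1p_distance_series(as_trajectory(st2), duplex_site_spec(st2, 5))
  expect_true(all(d$values > 10 & d$values < 11))
  # missing C1' errors with the residue name
  st_no <- toy_structure(xyz, chain = c("I", "J"), resno = c(1L, 2L),
                         name = c("CA", "CA"))
  tr_no <- toy_trajectory(st_no, list(xyz))
  expect_error(c1p_distance_series(tr_no, spec), "I:1")
})

test_that("extrahelicity and ejection percentages follow strict thresholds", {
  mk <- function(v) ncptraj:::.distance_series(v, "test", "fixture")
  cfg <- threshold_config()
  expect_equal(extrahelicity_percent(mk(rep(12, 50)), cfg), 0)
  expect_equal(extrahelicity_percent(mk(rep(15, 50)), cfg), 100)
  expect_equal(extrahelicity_percent(mk(rep(14, 50)), cfg), 0)  # at-threshold
  expect_equal(extrahelicity_percent(mk(c(rep(15, 996), rep(12, 4))), cfg),
               99.6)
  expect_equal(ejection_fraction(mk(rep(6.8, 10)), cfg), 0)
  expect_equal(ejection_fraction(mk(rep(12, 10)), cfg), 100)
  # percentage-of-time semantics: invariant under frame permutation
  set.seed(42)
  v <- runif(200, 8, 20)
  expect_equal(extrahelicity_percent(mk(v), cfg),
               extrahelicity_percent(mk(sample(v)), cfg))
  # monotonicity: lowering the threshold never decreases the percent
  ths <- seq(18, 8, by = -0.5)
  pct <- vapply(ths, function(th) ncptraj:::.percent_above(mk(v), th), 0)
  expect_true(all(diff(pct) >= 0))
  expect_error(threshold_config(ejection_com_threshold = 5),
               "exceed the canonical")
})

test_that("COM distances are mass-weighted and subset-aware", {
  # single-atom residues: COM distance equals the atom distance
  xyz <- rbind(c(0, 0, 0), c(7.25, 0, 0))
  st <- toy_structure(xyz, element = "N", chain = c("I", "J"),
                      resno = c(1L, 2L), name = c("N1", "N1"),
                      resname = "DA")
  tr <- toy_trajectory(st, list(xyz))
  d <- com_distance_series(tr, list(chain = "I", resno = 1),
                           list(chain = "J", resno = 2), subset = "heavy")
  expect_equal(d$values, 7.25)
  # scaling all masses leaves COM distances unchanged
  st2 <- fixture_duplex()
  tr2 <- as_trajectory(st2)
  ref <- com_distance_series(tr2, list(chain = "I", resno = 5),
                             list(chain = "J", resno = 26))
  st2m <- st2; st2m$atoms$mass <- st2$atoms$mass * 2
  tr2m <- as_trajectory(st2m)
  dbl <- com_distance_series(tr2m, list(chain = "I", resno = 5),
                             list(chain = "J", resno = 26))
  expect_equal(dbl$values, ref$values, tolerance = 1e-12)
  # ejection-descriptor reference on the canonical pair
  expect_equal(ref$values, 6.8, tolerance = 0.3)
  # designed ejection occupancy is recovered exactly in exact_fraction mode
  st_ap <- fixture_lesioned("AP")
  orphan <- flip_spec(23, "J", name = "orphan", mode = "exact_fraction",
                      fraction = 0.25)
  trj <- simulate_flip_dynamics(st_ap, list(orphan), n_frames = 400,
                                seed = 3, noise_sigma = 0)
  ser <- com_distance_series(trj, list(chain = "J", resno = 23),
                             list(chain = "I", resno = 8))
  expect_equal(ejection_fraction(ser, threshold_config()), 25)
})

test_that("bend angle has a straight-limit of zero and is rigid-invariant", {
  st <- fixture_duplex()
  spec <- duplex_site_spec(st, 8)
  tr <- as_trajectory(st)
  expect_lt(bend_angle_series(tr, spec)$mean, 3)
  b27 <- bend_angle_series(as_trajectory(bend_arc(st, 27)), spec)
  expect_equal(b27$mean, 27, tolerance = 2)
  expect_true(all(b27$values >= 0 & b27$values < 180))
  # rotation/translation invariance
  set.seed(7)
  rt <- random_rigid_transform()
  bent <- bend_arc(st, 55)
  moved <- bent; moved$xyz <- apply_rigid(bent$xyz, rt)
  expect_equal(bend_angle_series(as_trajectory(moved), spec)$values,
               bend_angle_series(as_trajectory(bent), spec)$values,
               tolerance = 1e-8)
  # too-short sections are rejected
  st8 <- build_bdna(tetramer_sequence(8))
  expect_error(bend_angle_series(as_trajectory(st8),
                                 duplex_site_spec(st8, 4)), ">= 10")
})

test_that("phi coefficient matches the 2x2 closed form", {
  mk <- function(v) ncptraj:::.distance_series(v, "t", "f")
  hi <- 15; lo <- 10   # indicator: > 12
  a <- mk(c(rep(hi, 50), rep(lo, 50)))
  expect_equal(correlate_indicators(a, a, 12, 12), 1)
  b <- mk(c(rep(lo, 50), rep(hi, 50)))
  expect_equal(correlate_indicators(a, b, 12, 12), -1)
  # counts (n11, n10, n01, n00) = (40, 10, 10, 40) -> phi = 0.6
  va <- mk(c(rep(hi, 50), rep(lo, 50)))
  vb <- mk(c(rep(hi, 40), rep(lo, 10), rep(hi, 10), rep(lo, 40)))
  expect_equal(correlate_indicators(va, vb, 12, 12), 0.6)
  expect_warning(
    expect_true(is.na(correlate_indicators(mk(rep(hi, 100)), va, 12, 12))),
    "constant")
  expect_error(correlate_indicators(mk(rep(hi, 3)), mk(rep(hi, 4)), 12, 12),
               "lengths")
})

test_that("replicate aggregation reproduces printed-table arithmetic", {
  s <- aggregate_replicates(c(MD1 = 67.0, MD2 = 99.6, MD3 = 97.9))
  expect_equal(s$all_mean, 88.2)
  expect_equal(aggregate_replicates(c(4.5, 6.1, 7.5))$all_mean, 6.0)
  expect_equal(aggregate_replicates(c(MD1 = 42.7))$all_mean, 42.7)
  expect_equal(aggregate_replicates(c(5.0, 30.0, 24.8))$all_mean, 19.9)
  expect_error(aggregate_replicates(numeric(0)), "no replicates")
  expect_error(aggregate_replicates(c(12, 104)), "0, 100")
  # rounding is half-away-from-zero, applied last
  expect_equal(aggregate_replicates(c(10.04, 10.05, 10.06))$all_mean, 10.1)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  # wide-table export
  tab <- occupancy_table(list("AP (site2)" = s))
  expect_equal(tab$all, 88.2)
  expect_equal(tab$MD2, 99.6)
})
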
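test_that("canonical builder produces a Watson-Crick B-DNA duplex", {
  st <- build_bdna("AT")
  rt <- residue_table(st)
  expect_equal(nrow(rt), 4)
  # pairing: strand I 'A','T' faces strand J 'T','A' (resno 2n+1-i)
  expect_equal(rt$resname[rt$chain == "I"], c("DA", "DT"))
  expect_equal(rt$resname[rt$chain == "J" & rt$resno == 4], "DT")
  expect_equal(rt$resname[rt$chain == "J" & rt$resno == 3], "DA")
  expect_error(build_bdna("ATX"), "non-ACGT")

  # base-pair centers advance by the helical rise along the axis
  st10 <- build_bdna(tetramer_sequence(10))
  centers <- vapply(1:10, function(i) {
    idx <- which(st10$atoms$pair == i & st10$atoms$name == "C1'")
    colMeans(st10$xyz[idx, ])
  }, numeric(3))
  steps <- diff(centers[3, ])
  expect_equal(steps, rep(3.38, 9), tolerance = 1e-9)

  # C1'-C1' across any pair lies in the canonical range
  for (i in c(1, 4, 10)) {
    idx <- which(st10$atoms$pair == i & st10$atoms$name == "C1'")
    d <- sqrt(sum((st10$xyz[idx[1], ] - st10$xyz[idx[2], ])^2))
    expect_gt(d, 10.0); expect_lt(d, 11.0)
  }
  # determinism
  expect_identical(build_bdna("GATTACA")$xyz, build_bdna("GATTACA")$xyz)
})

test_that("lesion conversion removes the base and distinguishes AP from THF", {
  st <- fixture_duplex()
  base_ct <- length(select_atoms(st, chain = "I", resno = 8,
                                 base_only = TRUE))
  expect_equal(base_ct, 10)  # adenine heavy base atoms
  ap <- apply_lesion(st, 8, "AP")
  expect_length(select_atoms(ap, chain = "I", resno = 8, base_only = TRUE), 0)
  expect_length(select_atoms(ap, chain = "I", resno = 8, name = "C1'"), 1)
  expect_equal(unique(ap$atoms$resname[ap$atoms$chain == "I" &
                                         ap$atoms$resno == 8]), "AP")
  thf <- apply_lesion(st, 8, "THF")
  # identical atom sets except the O1' hydroxyl pseudo-atom of AP
  ap_names <- ap$atoms$name[ap$atoms$chain == "I" & ap$atoms$resno == 8]
  thf_names <- thf$atoms$name[thf$atoms$chain == "I" & thf$atoms$resno == 8]
  expect_setequal(setdiff(ap_names, thf_names), "O1'")
  expect_length(setdiff(thf_names, ap_names), 0)
  # atom count decreases by the base heavy-atom count (AP adds O1' back)
  expect_equal(nrow(st$atoms) - nrow(thf$atoms), base_ct)
  expect_equal(nrow(st$atoms) - nrow(ap$atoms), base_ct - 1)
  expect_error(apply_lesion(ap, 8, "AP"), "already abasic")
})

test_that("bend_arc is rigid per pair and recovers designed angles", {
  st <- fixture_duplex()
  expect_identical(bend_arc(st, 0)$xyz, st$xyz)
  expect_error(bend_arc(st, 190), "0, 180")
  expect_error(bend_arc(st, -3), "0, 180")
  bent <- bend_arc(st, 60)
  # within-pair geometry is preserved exactly (rigid pair transport)
  for (i in c(1, 8, 15)) {
    idx <- which(st$atoms$pair == i)
    d0 <- dist(st$xyz[idx, ])
    d1 <- dist(bent$xyz[idx, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  }
  spec <- duplex_site_spec(st, 8)
  expect_equal(bend_angle_series(as_trajectory(bent), spec)$mean, 60,
               tolerance = 2)
  expect_equal(bend_angle_series(as_trajectory(bend_arc(st, 55)),
                                 spec)$mean, 55, tolerance = 2)
})

test_that("state simulation honours kinetics, placement and seeding", {
  # absorbing intrahelical state
  f0 <- flip_spec(8, mode = "markov", p_out = 0, p_in = 0.1)
  s <- simulate_flip_states(list(f0), 500, seed = 4)
  expect_equal(sum(s), 0)
  # exact fraction: forced count, evenly spaced, non-contiguous
  fe <- flip_spec(8, mode = "exact_fraction", fraction = 0.5)
  s <- simulate_flip_states(list(fe), 10, seed = 1)
  expect_equal(sum(s), 5)
  expect_false(any(s[-10, 1] & s[-1, 1]))  # no two consecutive
  # bit-for-bit reproducibility; seeds change markov draws but not counts
  fm <- flip_spec(8, mode = "markov", p_out = 0.05, p_in = 0.1)
  expect_identical(simulate_flip_states(list(fm), 1000, seed = 9),
                   simulate_flip_states(list(fm), 1000, seed = 9))
  expect_identical(sum(simulate_flip_states(list(fe), 1000, seed = 1)),
                   sum(simulate_flip_states(list(fe), 1000, seed = 2)))
  # contract violations
  expect_error(flip_spec(8, mode = "exact_fraction"), "fraction")
  expect_error(flip_spec(8, mode = "markov", p_out = 1.2, p_in = 0.1),
               "\\[0, 1\\]")
  bad <- flip_spec(9, couple_to = "nonexistent")
  expect_error(simulate_flip_states(list(fe, bad), 10), "unknown site")
})

test_that("flip dynamics produce threshold-crossing conformers with labels", {
  st <- fixture_lesioned("AP")
  fl <- flip_spec(8, "I", name = "lesion", mode = "exact_fraction",
                  fraction = 0.3)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 50, seed = 2,
                               noise_sigma = 0)
  spec <- duplex_site_spec(st, 8)
  d <- c1p_distance_series(tr, spec)
  truth <- attr(tr$states, "wide")[, "lesion"]
  # zero noise: classification equals ground truth exactly, with >= 2 A margin
  expect_identical(d$values > 14, truth)
  expect_true(all(d$values[truth] > 16))
  expect_true(all(d$values[!truth] < 12))
  # ground-truth sidecar table round trips as CSV
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(tr, f)
  gt <- read.csv(f)
  expect_equal(nrow(gt), 50)
  expect_equal(sum(gt$state == "extra"), sum(truth))
})

test_that("generator labels agree with threshold classification under noise", {
  st <- fixture_lesioned("AP")
  fl <- flip_spec(8, "I", name = "lesion", mode = "markov",
                  p_out = 0.1, p_in = 0.15)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 400, seed = 5,
                               noise_sigma = 0.3)
  d <- c1p_distance_series(tr, duplex_site_spec(st, 8))
  truth <- attr(tr$states, "wide")[, "lesion"]
  agreement <- mean((d$values > 14) == truth)
  expect_gte(agreement, 0.99)
})

test_that("scripted tail probes hit exact residence occupancies", {
  st <- fixture_lesioned("AP")
  fl <- flip_spec(8, "I", mode = "exact_fraction", fraction = 0)
  tr <- simulate_flip_dynamics(st, list(fl), n_frames = 100, seed = 1)
  site_idx <- function(x) select_atoms(x$topology, chain = "I", resno = 8,
                                       heavy = TRUE)
  # one episode covering all frames at 3 A -> 100%
  tr_all <- add_tail_probe(tr, contact_script(
    data.frame(start = 1, end = 100, target_distance = 3)), 8)
  g <- find_charged_groups(tr_all$topology, "P")
  nz <- g[[which(vapply(g, function(x) x$kind, "") == "LYS_NZ")]]
  expect_equal(residence_frequency(tr_all, nz, site_idx(tr_all), 6), 100)
  # no episodes at 20 A off distance -> 0%
  tr_none <- add_tail_probe(tr, contact_script(
    data.frame(start = integer(), end = integer(),
               target_distance = numeric()), off_distance = 20), 8)
  g2 <- find_charged_groups(tr_none$topology, "P")
  nz2 <- g2[[which(vapply(g2, function(x) x$kind, "") == "LYS_NZ")]]
  expect_equal(residence_frequency(tr_none, nz2, site_idx(tr_none), 6), 0)
  # episode bookkeeping is exact: 19 of 100 frames at 4 A -> 19%
  tr19 <- add_tail_probe(tr, contact_script(
    data.frame(start = c(5, 40), end = c(14, 48), target_distance = 4)), 8)
  g3 <- find_charged_groups(tr19$topology, "P")
  nz3 <- g3[[which(vapply(g3, function(x) x$kind, "") == "LYS_NZ")]]
  expect_equal(residence_frequency(tr19, nz3, site_idx(tr19), 6), 19)
  # invalid scripts
  expect_error(contact_script(data.frame(start = 1, end = 5,
                                         target_distance = 25),
                              off_distance = 20), "smaller")
  expect_error(contact_script(data.frame(start = c(1, 3), end = c(4, 8),
                                         target_distance = 3)), "overlap")
})
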
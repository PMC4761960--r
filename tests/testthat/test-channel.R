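# Channel mouth geometry, per-frame blocking, onset, pooled statistic.

lining_expr <- "residue_id == 10 or residue_id == 11 or residue_id == 12"

test_that("mouth centroid is the lining C-alpha mean, rigid-invariant", {
  host <- toy_host()
  ch <- channel_spec("2e", lining_expr)
  m <- mouth_geometry(coords(host), host, ch)
  lining <- which(host$atoms$residue_id %in% 10:12 & host$atoms$name == "CA")
  expect_equal(m$centroid, colMeans(coords(host)[lining, ]), tolerance = 1e-12)
  expect_equal(sqrt(sum(m$outward^2)), 1, tolerance = 1e-12)

  shifted <- coords(host) + matrix(rep(c(1, 1, 1), each = n_atoms(host)),
                                   ncol = 3)
  m2 <- mouth_geometry(shifted, host, ch)
  expect_equal(m2$centroid, m$centroid + c(1, 1, 1), tolerance = 1e-12)
  expect_equal(m2$outward, m$outward, tolerance = 1e-12)
})

test_that("fewer than 3 lining residues is an error", {
  host <- toy_host()
  ch <- channel_spec("bad", "residue_id == 10 or residue_id == 11")
  expect_error(mouth_geometry(coords(host), host, ch), ">= 3 lining residues")
  expect_error(channel_spec("x", lining_expr, block_distance = 0),
               "radii must be > 0")
})

test_that("is_blocked: trivial positions and brute-force sweep oracle", {
  host <- toy_host()
  tube <- build_armchair_swcnt(nanotube_spec(n = 5, target_length = 1.0,
                                             carboxyl_count = 0))
  ch <- channel_spec("2e", lining_expr)
  sys <- merge_structures(host, tube$structure)
  cnt <- resolve_selection(sys, "group == cnt")
  m <- mouth_geometry(coords(host), host, ch)

  place_tube <- function(center) {
    xyz <- coords(sys)
    xyz[cnt$resolved, ] <- sweep(coords(tube$structure), 2, center, "+")
    xyz
  }
  # a tube atom exactly at the centroid
  at_mouth <- place_tube(m$centroid)
  expect_true(is_blocked(at_mouth, sys, ch, cnt))
  # nearest tube atom ~2 nm away
  far <- place_tube(m$centroid + c(2 + tube$diameter / 2 + 0.2, 0, 0))
  expect_false(is_blocked(far, sys, ch, cnt))

  # sweep of tube positions vs the exhaustive min-distance oracle
  for (dx in seq(0.2, 2.4, by = 0.2)) {
    xyz <- place_tube(m$centroid + c(dx, 0, 0))
    want <- oracle_min_dist(xyz, cnt$resolved, m$centroid) <= 0.7
    expect_equal(is_blocked(xyz, sys, ch, cnt), want)
  }
})

test_that("blocking_onset finds the persistent suffix start", {
  # scripted flags via a synthetic scenario: blocked frames 40..119 of 120
  spec <- scenario_spec(n_frames = 120, frame_spacing = 1000,
                        events = list(scenario_event("channel_block", 40, 120)),
                        seed = 1)
  scn <- generate_scenario(spec)
  prof <- blocking_onset(scn$trajectory, scn$channel,
                         resolve_selection(scn$system, "group == cnt"))
  expect_equal(prof$onset, 40)                    # ns
  expect_equal(prof$blocked_fraction, 80 / 120)
  expect_equal(prof$duration, 120)

  # never blocked
  spec0 <- scenario_spec(n_frames = 30, events = list(), seed = 1)
  prof0 <- blocking_onset(generate_scenario(spec0)$trajectory, scn$channel,
                          resolve_selection(scn$system, "group == cnt"))
  expect_true(is.na(prof0$onset))
  expect_equal(prof0$blocked_fraction, 0)
})

test_that("transient early blocks do not move the onset at persistence 1", {
  spec <- scenario_spec(n_frames = 40, frame_spacing = 1000,
                        events = list(scenario_event("channel_block", 5, 7),
                                      scenario_event("channel_block", 28, 40)),
                        seed = 1)
  scn <- generate_scenario(spec)
  prof <- blocking_onset(scn$trajectory, scn$channel,
                         resolve_selection(scn$system, "group == cnt"))
  expect_equal(prof$onset, 28)
  # brute-force scan over all candidate onsets agrees
  flags <- prof$per_frame_flags
  cand <- NA
  for (i in rev(seq_along(flags))) if (all(flags[i:length(flags)])) cand <- i
  expect_equal(prof$onset, (cand - 1) * 1)  # 1 ns/frame, 0-based time
  # relaxed persistence reaches back to the transient
  prof2 <- blocking_onset(scn$trajectory, scn$channel,
                          resolve_selection(scn$system, "group == cnt"),
                          persistence = 0.35)
  expect_lt(prof2$onset, prof$onset)
  expect_error(blocking_onset(scn$trajectory, scn$channel,
                              resolve_selection(scn$system, "group == cnt"),
                              persistence = 1.2), "persistence")
})

test_that("pooled statistic reproduces the three-run worked example", {
  profiles <- list(blocking_profile("run1", 120, 40),
                   blocking_profile("run2", 120, 10),
                   blocking_profile("run3", 120, 28))
  pooled <- pool_blocked_fraction(profiles)
  expect_equal(pooled$pooled_percent, 100 * (360 - 78) / 360, tolerance = 1e-12)
  expect_equal(round(pooled$pooled_percent, 2), 78.33)
  expect_gte(pooled$pooled_percent, 78.3)

  expect_equal(pool_blocked_fraction(list(
    blocking_profile("a", 50, 0)))$pooled_percent, 100)
  expect_equal(pool_blocked_fraction(list(
    blocking_profile("a", 50, NA)))$pooled_percent, 0)
  expect_error(pool_blocked_fraction(list()), "no blocking profiles")
})

test_that("pooled fraction equals per-frame flag counting (oracle identity)", {
  set.seed(21)
  for (rep in 1:5) {
    dts <- sample(c(0.5, 1, 2), 3, replace = TRUE)
    profs <- lapply(1:3, function(i) {
      nf <- sample(20:60, 1)
      onset_frame <- sample(0:nf, 1)
      p <- blocking_profile(paste0("r", i), nf * dts[i],
                            if (onset_frame == nf) NA else onset_frame * dts[i])
      p$flags_oracle <- c(rep(FALSE, onset_frame), rep(TRUE, nf - onset_frame))
      p$dt <- dts[i]
      p
    })
    pooled <- pool_blocked_fraction(profs)
    # oracle: concatenate flags weighted by each run's frame spacing
    blocked_time <- sum(vapply(profs, function(p) sum(p$flags_oracle) * p$dt, 1))
    total_time <- sum(vapply(profs, function(p) length(p$flags_oracle) * p$dt, 1))
    expect_equal(pooled$pooled_fraction, blocked_time / total_time,
                 tolerance = 1e-12)
  }
})

test_that("blocked fraction is monotone in block_distance", {
  spec <- scenario_spec(n_frames = 30, frame_spacing = 1000,
                        events = list(scenario_event("channel_block", 12, 30)),
                        jitter_sigma = 0.05, seed = 13)
  scn <- generate_scenario(spec)
  cnt <- resolve_selection(scn$system, "group == cnt")
  fracs <- vapply(c(0.3, 0.5, 0.7, 1.0, 1.5), function(bd) {
    ch <- channel_spec("2e", scn$channel$lining_residues, block_distance = bd)
    blocking_onset(scn$trajectory, ch, cnt)$blocked_fraction
  }, 1.0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("blocking flags are invariant under rigid motion of all frames", {
  spec <- scenario_spec(n_frames = 15, events = list(
    scenario_event("channel_block", 5, 15)), seed = 17)
  scn <- generate_scenario(spec)
  cnt <- resolve_selection(scn$system, "group == cnt")
  base <- blocking_onset(scn$trajectory, scn$channel, cnt)$per_frame_flags
  set.seed(31)
  rot <- random_rotation(); shift <- stats::rnorm(3, 0, 4)
  moved <- scn$trajectory
  moved$frames <- lapply(moved$frames, apply_rigid, rot = rot, shift = shift)
  expect_equal(blocking_onset(moved, scn$channel, cnt)$per_frame_flags, base)
})
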
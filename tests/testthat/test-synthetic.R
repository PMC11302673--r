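test_that("config validation enforces the generative invariants", {
  expect_error(tiny_config(n_regions = 8), "out of range")
  expect_error(synthetic_study_config(
    rings = list(list(regions = 1:3, within_rest = 0.3, within_task = 0.6,
                      cross = 0.1))), "3-clique")
  expect_error(synthetic_study_config(
    rings = list(list(regions = 1:5, within_rest = 0.3, within_task = 0.6,
                      cross = 0.4))), "below the within-ring")
  expect_error(synthetic_study_config(duration_meg = 8), ">= 12 s")
  expect_error(synthetic_study_config(chi_rest = -1), "positive")
  expect_error(synthetic_study_config(
    peaks = list(list(center = 200, amplitude = 1, bandwidth = 1))), "fs/2")
  expect_error(synthetic_study_config(coupling_strength = 2), "0, 1")
  cfg <- tiny_config()
  expect_equal(cfg$modulation[1:5], rep(1, 5))
  expect_equal(cfg$modulation[6:10], rep(-1, 5))
  expect_equal(cfg$modulation[15], 0)
})

test_that("generators are bit-deterministic given the seed and split streams", {
  cfg <- tiny_config(seed = 44)
  b1 <- generate_bold_like(cfg, "taskA")
  b2 <- generate_bold_like(cfg, "taskA")
  expect_identical(b1$data, b2$data)
  m1 <- generate_meg_like(cfg, "rest")
  m2 <- generate_meg_like(cfg, "rest")
  expect_identical(m1$data, m2$data)
  # different subjects/conditions draw from different streams
  expect_false(identical(b1$data[1, 1, , ], b1$data[2, 1, , ]))
  expect_false(identical(generate_bold_like(cfg, "rest")$data, b1$data))
  # unknown condition rejected
  expect_error(generate_bold_like(cfg, "nope"), "unknown condition")
})

test_that("planted ring edges dominate chords in the empirical connectome", {
  cfg <- synthetic_study_config(
    n_subjects = 1, n_regions = 8, n_timepoints_bold = 400,
    conditions = c("rest", "task"),
    rings = list(list(regions = 1:6, within_rest = 0.8, within_task = 0.8,
                      cross = 0.1)),
    dc_confound = NULL, seed = 1)
  wins <- 0L
  for (seed in 1:100) {
    cfg$seed <- seed
    fc <- compute_fc(generate_bold_like(cfg, "rest"), 1, "rest")
    ring_idx <- cbind(1:6, c(2:6, 1))
    ring_r <- fc$r[ring_idx]
    chord_r <- fc$r[rbind(c(1, 3), c(1, 4), c(1, 5), c(2, 4), c(2, 5),
                          c(2, 6), c(3, 5), c(3, 6), c(4, 6))]
    if (min(ring_r) > max(chord_r)) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("short BOLD series trigger the unstable-FC warning", {
  cfg <- tiny_config()
  cfg$n_timepoints_bold <- 30L
  expect_warning(generate_bold_like(cfg, "rest"), "unstable")
})

test_that("planted aperiodic-exponent shift follows the PC modulation sign", {
  cfg <- tiny_config(seed = 60, coupling = 1, n_subjects = 1)
  rest <- generate_meg_like(cfg, "rest")
  task <- generate_meg_like(cfg, "taskA")
  dec_r <- suppressWarnings(irasa(t(rest$data[1, 1, , ]), cfg$fs_meg))
  dec_t <- suppressWarnings(irasa(t(task$data[1, 1, , ]), cfg$fs_meg))
  bpr_r <- band_power_ratio(dec_r, rbind(thetaalpha = c(4, 12)))
  bpr_t <- band_power_ratio(dec_t, rbind(thetaalpha = c(4, 12)))
  dbpr <- unclass(bpr_t) - unclass(bpr_r)
  mod <- cfg$modulation != 0
  agree <- sign(dbpr[mod, 1]) == sign(cfg$modulation[mod])
  expect_gte(mean(agree), 0.9)
  # and the exponents themselves move in the planted direction
  chi_r <- aperiodic_exponent(dec_r)
  chi_t <- aperiodic_exponent(dec_t)
  expect_lt(mean(chi_t[1:5] - chi_r[1:5]), 0)    # positive modulation: chi down
  expect_gt(mean(chi_t[6:10] - chi_r[6:10]), 0)
})

test_that("zero coupling leaves Delta BPR and Delta PC unaligned", {
  # scaled-down null calibration: the study-level check runs in acceptance
  coss <- c()
  for (seed in 1:6) {
    cfg <- tiny_config(seed = 300 + seed, coupling = 0, n_subjects = 1,
                       conditions = c("rest", "taskA"), n_regions = 30)
    cfg$rings <- list(list(regions = 1:6, within_rest = 0.3, within_task = 0.6,
                           cross = 0.1),
                      list(regions = 7:12, within_rest = 0.6, within_task = 0.3,
                           cross = 0.1))
    cfg$dc_confound <- list(regions = 13:20, r_rest = 0.15, r_task = 0.45)
    pc <- lapply(c("rest", "taskA"), function(cond) {
      persistence_centrality(
        topology_from_fc(compute_fc(generate_bold_like(cfg, cond), 1, cond),
                         cond)$scaffold)
    })
    dbpr <- local({
      decs <- lapply(c("rest", "taskA"), function(cond)
        suppressWarnings(irasa(t(generate_meg_like(cfg, cond)$data[1, 1, , ]),
                               cfg$fs_meg, hset = cfg$hset)))
      b <- lapply(decs, band_power_ratio, band_edges = rbind(c(4, 12)))
      unclass(b[[2]]) - unclass(b[[1]])
    })
    coss <- c(coss, abs(cosine_similarity(dbpr[, 1],
                                          as.numeric(pc[[2]]) - as.numeric(pc[[1]]))))
  }
  expect_lt(mean(coss), 0.2)
})

test_that("ring fixture matrix layout and rejection rules", {
  G <- fixture_ring_connectome(6, 0.6, 0.2)
  expect_true(isSymmetric(G$r))
  expect_equal(diag(G$r), setNames(rep(1, 6), G$labels))
  for (i in 1:6) {
    expect_equal(sort(unname(G$r[i, -i])), c(rep(0.2, 3), 0.6, 0.6))
  }
  expect_error(fixture_ring_connectome(3, 0.6, 0.2), "n >= 4")
  expect_error(fixture_ring_connectome(4, 0.4, 0.4), "chord_r < ring_r")
})
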
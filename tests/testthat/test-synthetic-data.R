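test_that("analytic profiles carry correct closed-form ground truth", {
  gp <- generate_flight_path(path_profile("circle", speed = 1.2,
                                          radius = 0.4, duration = 1.5,
                                          start = c(3, 1.25, 1.2)))
  expect_equal(gp$truth$flight_curvature, 1 / 0.4)
  expect_equal(gp$truth$turning_rate, 1.2 / 0.4)
  expect_equal(gp$truth$turning_acceleration, 1.2^2 / 0.4)
  expect_equal(gp$truth$mean_velocity, 1.2)
  gp <- generate_flight_path(path_profile("straight", speed = 2,
                                          duration = 1,
                                          start = c(1, 1, 1.2)))
  expect_equal(gp$truth$flight_curvature, 0)
  expect_equal(gp$truth$sinuosity, 1)
})

test_that("ground truth agrees with the kinematics module on noiseless data", {
  profiles <- list(
    path_profile("circle", speed = 1.3, radius = 0.5, duration = 2,
                 start = c(3, 1.25, 1.2)),
    path_profile("helix", speed = 1.6, radius = 0.5, pitch = 0.08,
                 duration = 2, start = c(3, 1.25, 1.0)),
    path_profile("flutter", speed = 1.5, duration = 2,
                 start = c(1.5, 1.0, 1.2)))
  for (pf in profiles) {
    gp <- generate_flight_path(pf)
    sm <- kalman_smooth(gp$traj, q = 1e4, r = 1e-10)
    fs <- summarize_flight(sm, NULL)
    for (fld in c("mean_velocity", "mean_acceleration", "flight_curvature",
                  "turning_rate", "turning_acceleration"))
      expect_equal(fs[[fld]], gp$truth[[fld]], tolerance = 0.01,
                   label = paste(pf$kind, fld))
  }
})

test_that("stochastic paths are bit-reproducible from their seed", {
  pf <- path_profile("crw", speed = 1.2, duration = 1, seed = 77,
                     start = c(3, 1.25, 1.2))
  g1 <- generate_flight_path(pf)
  g2 <- generate_flight_path(pf)
  expect_identical(g1$traj$xyz, g2$traj$xyz)
  g3 <- generate_flight_path(path_profile("crw", speed = 1.2, duration = 1,
                                          seed = 78, start = c(3, 1.25, 1.2)))
  expect_false(identical(g1$traj$xyz, g3$traj$xyz))
})

test_that("rendering round-trips exactly without noise and flags dropout", {
  sc <- scene_config()
  pf <- path_profile("helix", speed = 1.4, radius = 0.5, pitch = 0.1,
                     duration = 1.5, start = c(3, 1.25, 1.2))
  gp <- generate_flight_path(pf)
  tks <- render_pixel_tracks(gp$traj, sc, seed = 1)
  tr <- triangulate(tks[[1]], tks[[2]], sc$cameras[[1]], sc$cameras[[2]])
  expect_lt(max(abs(tr$xyz[tr$valid, ] - gp$traj$xyz[tr$valid, ])), 1e-9)

  # dropout 0.05 on 360 frames: invalid counts inside the binomial 99% CI
  sc2 <- scene_config(dropout = 0.05)
  gp2 <- generate_flight_path(path_profile("helix", speed = 1.4,
                                           radius = 0.5, pitch = 0.1,
                                           duration = 3,
                                           start = c(3, 1.25, 1.2)))
  n <- sum(gp2$traj$valid)
  lo <- qbinom(5e-4, n, 0.05); hi <- qbinom(1 - 5e-4, n, 0.05)
  for (s in 1:5) {
    tks2 <- render_pixel_tracks(gp2$traj, sc2, seed = s)
    for (tk in tks2) {
      dropped <- sum(gp2$traj$valid & !tk$valid)
      expect_gte(dropped, lo); expect_lte(dropped, hi)
    }
  }
})

test_that("points behind a camera are flagged invalid, not projected", {
  sc <- scene_config()
  xyz <- rbind(c(3, 1.25, 1.2), c(3, -5, 1.2), c(3, 1.25, 1.0))
  traj <- trajectory3d(0:2, xyz)   # second point is behind camera 1
  suppressWarnings(tks <- render_pixel_tracks(traj, sc, seed = 1))
  expect_false(tks[[1]]$valid[2])
  expect_true(all(tks[[1]]$valid[c(1, 3)]))
})

test_that("wand sweeps are rigid, seeded and default to the 24 cm wand", {
  sc <- scene_config()
  o1 <- generate_wand_sweep(sc, n_poses = 40, seed = 5)
  o2 <- generate_wand_sweep(sc, n_poses = 40, seed = 5)
  expect_identical(o1$cam1_a, o2$cam1_a)
  expect_equal(o1$wand_length, 0.24)
  # noiseless endpoint reconstruction through the true cameras
  lens <- vapply(which(o1$usable), function(i) {
    a <- pierisflight:::triangulate_point(o1$cam1_a[i, ], o1$cam2_a[i, ],
                                          sc$cameras[[1]], sc$cameras[[2]])
    b <- pierisflight:::triangulate_point(o1$cam1_b[i, ], o1$cam2_b[i, ],
                                          sc$cameras[[1]], sc$cameras[[2]])
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_lt(max(abs(lens - 0.24)), 0.001 * 0.24)
})

test_that("wing landmark cohorts hit the configured seasonal means", {
  n <- 300
  for (grp in list(list(form = "summer", oe = 1.080, oe_se = 0.006 * sqrt(18)),
                   list(form = "spring", oe = 1.11, oe_se = 0.012 * sqrt(8)))) {
    lms <- generate_wing_landmarks(n, "napi", grp$form, seed = 42)
    oe <- vapply(lms, outer_edge_index, numeric(1))
    expect_lt(abs(mean(oe) - grp$oe), 2 * grp$oe_se / sqrt(n))
  }
  # zero-variance configuration produces identical specimens
  tg <- list(area = c(250, 0), wl = c(0.02, 0), ar = c(1.75, 0),
             oe = c(1.09, 0), mr = c(0.7, 0))
  lms <- generate_wing_landmarks(3, targets = tg, seed = 1)
  expect_identical(lms[[1]]$landmarks, lms[[2]]$landmarks)
  expect_identical(lms[[2]]$landmarks, lms[[3]]$landmarks)
  # infeasible targets are rejected with the conflicting value named
  bad <- list(area = c(250, 0), wl = c(0.02, 0), ar = c(1.75, 0),
              oe = c(0.9, 0), mr = c(0.7, 0))
  expect_error(generate_wing_landmarks(1, targets = bad), "infeasible|< 1")
})

test_that("cohorts reproduce the study structure and configured effects", {
  ch <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(ch$specimens), 31)
  expect_equal(nrow(ch$tracks), 106)
  expect_equal(sum(ch$tracks$form == "spring"), 26)
  expect_equal(sum(ch$tracks$form == "summer"), 80)
  expect_equal(sum(ch$specimens$species == "napi"), 17)
  expect_true(all(ch$specimens$n_tracks >= 1 & ch$specimens$n_tracks <= 6))
  expect_equal(sum(is.na(ch$wingbeats$n_wingbeats)), 4)
  expect_true(all(ch$temperatures$temp_c >= 14 & ch$temperatures$temp_c <= 36))

  # large cohort: geometric-mean spring velocity near the configured
  # 1.2 m/s (within twice the reported SE)
  big <- cohort_config(seed = 8)
  big$individuals$n <- big$individuals$n * 8
  big$tracks_per_form <- c(spring = 26, summer = 80) * 8
  chb <- generate_cohort(big)
  gm <- exp(mean(log(chb$tracks$mean_velocity[chb$tracks$form == "spring"])))
  expect_lt(abs(gm - 1.2), 2 * 0.124)

  # zero variance: every track carries its group mean exactly
  ch0 <- generate_cohort(cohort_config(sd_individual = 0, sd_residual = 0,
                                       seed = 2))
  v <- ch0$tracks$mean_velocity
  expect_true(all(abs(v[ch0$tracks$form == "spring"] - 1.2) < 1e-12))
  expect_true(all(abs(v[ch0$tracks$form == "summer"] - 1.7) < 1e-12))

  # generation is a pure function of the seed
  expect_identical(generate_cohort(cohort_config(seed = 3))$tracks$mean_velocity,
                   ch$tracks$mean_velocity)
})
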
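test_that("covered distance sums consecutive displacements", {
  # 10 straight steps of 0.2 m
  pos <- cbind(seq(0, 2, by = 0.2), 0, 1)
  st <- analytic_states(function(t) c(t, 0, 1), function(t) c(1, 0, 0),
                        function(t) c(0, 0, 0), duration = 1, dt = 0.1)
  st$position <- pos
  expect_equal(covered_distance(st, burn_in = 0), 2.0)
  # full circle at 120 fps: arc length within 0.1% of 2*pi
  st <- circle_states(1, 2 * pi, duration = 1)   # one revolution per second
  expect_equal(covered_distance(st, burn_in = 0), 2 * pi, tolerance = 1e-3)
  st$position <- st$position[1, , drop = FALSE]
  st$frame_index <- 0L
  expect_error(covered_distance(st, burn_in = 0), "fewer than 2")
})

test_that("mean velocity and acceleration follow the Kalman state", {
  st <- analytic_states(function(t) c(1.7 * t, 0, 1),
                        function(t) c(1.7, 0, 0), function(t) c(0, 0, 0))
  expect_equal(mean_velocity(st), 1.7)
  expect_equal(mean_acceleration(st), 0)
  st <- circle_states(0.5, 1.0)
  expect_equal(mean_acceleration(st), 2.0, tolerance = 1e-12)  # v^2/r
})

test_that("advance ratio propagates missing wingbeat frequencies", {
  expect_equal(advance_ratio(1.2, 10), 0.12)
  expect_equal(advance_ratio(0, 8), 0)
  expect_true(is.na(advance_ratio(1.5, NA)))
  expect_true(is.na(advance_ratio(1.5, 0)))
})

test_that("turning acceleration isolates the centripetal component", {
  # straight line with purely tangential acceleration
  st <- analytic_states(function(t) c(t + 1.5 * t^2, 0, 1),
                        function(t) c(1 + 3 * t, 0, 0),
                        function(t) c(3, 0, 0))
  expect_equal(turning_acceleration(st), 0)
  st <- circle_states(0.5, 1.0)
  expect_equal(turning_acceleration(st), 2.0, tolerance = 1e-12)
})

test_that("turning rate matches angular speed and hand-built turns", {
  st <- analytic_states(function(t) c(t, 0, 1), function(t) c(1, 0, 0),
                        function(t) c(0, 0, 0))
  expect_equal(turning_rate(st), 0)
  st <- circle_states(0.5, 1.0)
  expect_equal(turning_rate(st), 2.0, tolerance = 1e-9)
  expect_equal(turning_rate(st, degrees = TRUE), 2.0 * 180 / pi,
               tolerance = 1e-9)
  # 90-degree instantaneous turn between two straight legs at 120 fps:
  # one velocity pair contributes (pi/2)/dt, the rest zero
  dt <- 1 / 120
  n <- 41
  vel <- rbind(matrix(rep(c(1, 0, 0), 20), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), 21), ncol = 3, byrow = TRUE))
  pos <- apply(vel * dt, 2, cumsum)
  st <- analytic_states(function(t) c(0, 0, 0), function(t) c(1, 0, 0),
                        function(t) c(0, 0, 0), duration = (n - 1) * dt,
                        dt = dt)
  st$position <- pos; st$velocity <- vel
  expected <- (pi / 2) / dt / (n - 1)   # hand computation over n-1 pairs
  expect_equal(turning_rate(st, burn_in = 0), expected, tolerance = 1e-12)
})

test_that("sinuosity is straight distance over covered distance", {
  st <- analytic_states(function(t) c(2 * t, t, 1), function(t) c(2, 1, 0),
                        function(t) c(0, 0, 0))
  expect_equal(sinuosity(st, burn_in = 0), 1.0)
  st <- circle_states(1, pi, duration = 1)  # half revolution in 1 s
  expect_equal(sinuosity(st, burn_in = 0), 2 / pi, tolerance = 1e-3)
  st <- circle_states(1, 2 * pi, duration = 1)  # closed loop
  expect_equal(sinuosity(st, burn_in = 0), 0, tolerance = 1e-2)
})

test_that("flight curvature equals differential-geometric curvature", {
  st <- circle_states(0.25, 1.0)
  expect_equal(flight_curvature(st), 4.0, tolerance = 1e-12)
  st <- analytic_states(function(t) c(t, 0, 1), function(t) c(1, 0, 0),
                        function(t) c(0, 0, 0))
  expect_equal(flight_curvature(st), 0)
  a <- 0.5; b <- 0.15
  st <- helix_states(a, b, 1.5)
  expect_equal(flight_curvature(st), a / (a^2 + b^2), tolerance = 1e-9)
})

test_that("ascent angle is the signed elevation of the velocity", {
  st <- circle_states(0.5, 1.0)
  expect_equal(ascent_angle(st), 0)
  st <- analytic_states(function(t) c(t, 0, t), function(t) c(1, 0, 1),
                        function(t) c(0, 0, 0))
  expect_equal(ascent_angle(st), 45)
  st <- analytic_states(function(t) c(0, 0, t), function(t) c(0, 0, 1),
                        function(t) c(0, 0, 0))
  expect_equal(ascent_angle(st), 90)
  st <- analytic_states(function(t) c(t, 0, -t), function(t) c(1, 0, -1),
                        function(t) c(0, 0, 0))
  expect_equal(ascent_angle(st), -45)
  expect_equal(ascent_angle(st, absolute = TRUE), 45)
})

test_that("wingbeat frequency comes from counts over duration", {
  expect_equal(wingbeat_frequency(wingbeat_record("t", 36, 3.0)), 12)
  expect_equal(wingbeat_frequency(wingbeat_record("t", 0, 2.0)), 0)
  expect_true(is.na(wingbeat_frequency(wingbeat_record("t", NA, 2.0))))
  expect_error(wingbeat_record("t", 10, 0), "duration")
})

test_that("the full flight summary matches helix closed forms within 1%", {
  a <- 0.5; b <- 0.1; v <- 1.5
  om <- v / sqrt(a^2 + b^2)
  st <- helix_states(a, b, v, duration = 3)
  fs <- summarize_flight(st, wingbeat_record("h", 33, 3))
  expect_equal(fs$mean_velocity, v, tolerance = 0.01)
  expect_equal(fs$mean_acceleration, om^2 * a, tolerance = 0.01)
  expect_equal(fs$turning_acceleration, om^2 * a, tolerance = 0.01)
  expect_equal(fs$flight_curvature, a / (a^2 + b^2), tolerance = 0.01)
  expect_equal(fs$turning_rate, om * a / sqrt(a^2 + b^2), tolerance = 0.01)
  expect_equal(fs$ascent_angle, asin(b / sqrt(a^2 + b^2)) * 180 / pi,
               tolerance = 0.01)
  expect_equal(fs$wingbeat_frequency, 11)
  expect_equal(fs$advance_ratio, fs$mean_velocity / 11, tolerance = 1e-12)
})

test_that("a horizontal straight flight gives the composite trivial summary", {
  v <- 1.4; T <- 2
  st <- analytic_states(function(t) c(v * t, 0.5, 1), function(t) c(v, 0, 0),
                        function(t) c(0, 0, 0), duration = T)
  fs <- summarize_flight(st, wingbeat_record("s", 20, T), burn_in = 0)
  expect_equal(fs$covered_distance, v * T, tolerance = 1e-9)
  expect_equal(fs$flight_height, 1.0)
  expect_equal(fs$mean_velocity, v)
  expect_equal(fs$mean_acceleration, 0)
  expect_equal(fs$advance_ratio, v / 10)
  expect_equal(fs$turning_acceleration, 0)
  expect_equal(fs$turning_rate, 0)
  expect_equal(fs$sinuosity, 1)
  expect_equal(fs$flight_curvature, 0)
  expect_equal(fs$ascent_angle, 0)
})

test_that("kinematics are invariant to rigid motion and scale with time", {
  st <- helix_states(0.5, 0.12, 1.6, duration = 2)
  fs <- summarize_flight(st, wingbeat_record("h", 22, 2))
  # rotation about z plus translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  st2 <- st
  st2$position <- sweep(st$position %*% t(R), 2, c(1.2, -0.7, 0), `+`)
  st2$velocity <- st$velocity %*% t(R)
  st2$acceleration <- st$acceleration %*% t(R)
  fs2 <- summarize_flight(st2, wingbeat_record("h", 22, 2))
  for (col in c("covered_distance", "mean_velocity", "mean_acceleration",
                "turning_acceleration", "turning_rate", "sinuosity",
                "flight_curvature", "ascent_angle"))
    expect_equal(fs2[[col]], fs[[col]], tolerance = 1e-9)
  # time dilation t -> c t: velocity / c, acceleration / c^2, geometry fixed
  cfac <- 2
  st3 <- helix_states(0.5, 0.12, 1.6 / cfac, duration = 2 * cfac)
  fs3 <- summarize_flight(st3, NULL)
  expect_equal(fs3$mean_velocity, fs$mean_velocity / cfac, tolerance = 1e-6)
  expect_equal(fs3$turning_rate, fs$turning_rate / cfac, tolerance = 1e-3)
  expect_equal(fs3$mean_acceleration, fs$mean_acceleration / cfac^2,
               tolerance = 1e-6)
  expect_equal(fs3$turning_acceleration, fs$turning_acceleration / cfac^2,
               tolerance = 1e-6)
  expect_equal(fs3$flight_curvature, fs$flight_curvature, tolerance = 1e-3)
  # compare path lengths over the full (untrimmed) frame range: the
  # burn-in trim removes a different time fraction at different dt
  expect_equal(covered_distance(st3, burn_in = 0),
               covered_distance(st, burn_in = 0), tolerance = 1e-3)
})

test_that("circle identities hold within discretisation tolerance", {
  for (r in c(0.3, 0.5, 1.0)) for (v in c(0.8, 1.5)) {
    st <- circle_states(r, v, duration = 1.5)
    fs <- summarize_flight(st, NULL)
    expect_equal(fs$turning_acceleration, fs$mean_velocity * fs$turning_rate,
                 tolerance = 0.005)
    expect_equal(fs$flight_curvature, fs$turning_rate / fs$mean_velocity,
                 tolerance = 0.005)
  }
})
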
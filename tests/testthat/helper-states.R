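# Build a smoothed_states object directly from analytic position, velocity
# and acceleration functions of time - used to unit-test the kinematic
# formulas independently of the Kalman pipeline.
analytic_states <- function(pos_fn, vel_fn, acc_fn, duration = 2,
                            dt = 1 / 120) {
  tt <- seq(0, duration, by = dt)
  structure(list(dt = dt, frame_index = seq_along(tt) - 1L,
                 position = t(vapply(tt, pos_fn, numeric(3))),
                 velocity = t(vapply(tt, vel_fn, numeric(3))),
                 acceleration = t(vapply(tt, acc_fn, numeric(3))),
                 estimated = rep(FALSE, length(tt)),
                 var_trace = rep(0, length(tt)), q = 1, r = 1),
            class = "smoothed_states")
}

# analytic horizontal circle: radius r, speed v, height z0
circle_states <- function(r, v, z0 = 1, duration = 2, dt = 1 / 120) {
  om <- v / r
  analytic_states(
    function(t) c(r * cos(om * t), r * sin(om * t), z0),
    function(t) c(-r * om * sin(om * t), r * om * cos(om * t), 0),
    function(t) c(-r * om^2 * cos(om * t), -r * om^2 * sin(om * t), 0),
    duration = duration, dt = dt)
}

# analytic helix: radius a, pitch b (m per radian), speed v
helix_states <- function(a, b, v, duration = 2, dt = 1 / 120) {
  om <- v / sqrt(a^2 + b^2)
  analytic_states(
    function(t) c(a * cos(om * t), a * sin(om * t), b * om * t),
    function(t) c(-a * om * sin(om * t), a * om * cos(om * t), b * om),
    function(t) c(-a * om^2 * cos(om * t), -a * om^2 * sin(om * t), 0),
    duration = duration, dt = dt)
}

# track-level data frame with known mixed-model structure, for the
# statistics tests (log-normal responses around group means, individual
# random intercepts)
simulate_tracks <- function(n_ind = 30, tracks_per = 4, mu_by_form = NULL,
                            sd_ind = 0.25, sd_res = 0.25, seed = 1) {
  set.seed(seed)
  if (is.null(mu_by_form)) mu_by_form <- c(spring = 1.45, summer = 1.45)
  ind <- data.frame(
    individual_id = sprintf("i%02d", seq_len(n_ind)),
    form = rep(names(mu_by_form), length.out = n_ind),
    species = rep(c("napi", "rapae"), each = ceiling(n_ind / 2))[seq_len(n_ind)],
    sex = rep(c("male", "male", "female"), length.out = n_ind),
    b = rnorm(n_ind, 0, sd_ind))
  rows <- ind[rep(seq_len(n_ind), each = tracks_per), ]
  rows$mean_velocity <- exp(log(mu_by_form[rows$form]) + rows$b +
                              rnorm(nrow(rows), 0, sd_res))
  rows$covered_distance <- exp(rnorm(nrow(rows), log(4), 0.4))
  rows$b <- NULL
  rownames(rows) <- NULL
  rows
}

# attach per-individual log-normal morphology, optionally with a true
# effect of one variable on mean_velocity (log-log slope beta)
join_morpho <- function(tracks, beta = 0, seed = 1,
                        effect_var = "outer_edge_index") {
  set.seed(seed + 5000)
  ids <- unique(tracks$individual_id)
  m <- data.frame(individual_id = ids,
                  forewing_area = exp(rnorm(length(ids), log(2.5), 0.12)),
                  aspect_ratio = exp(rnorm(length(ids), log(1.75), 0.03)),
                  wing_loading = exp(rnorm(length(ids), log(0.02), 0.1)),
                  outer_edge_index = exp(rnorm(length(ids), log(1.09), 0.02)),
                  marginal_region_index = exp(rnorm(length(ids), log(0.7),
                                                    0.03)))
  out <- merge(tracks, m, by = "individual_id")
  out$mean_velocity <- out$mean_velocity *
    exp(beta * (log(out[[effect_var]]) - log(1.09)))
  out
}
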
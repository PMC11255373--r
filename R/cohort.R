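## Group-structured generators: per-specimen wing landmark configurations
## whose population means match the study's morphology table (by species x
## seasonal form x sex), and full cohorts of flight-parameter records with
## the study's group means, individual random intercepts and track-level
## residuals.

## Morphology targets by group. Means and SEs follow the published group
## summaries (male rows; the female wing-loading cells are inconsistent in
## scale and are not emulated). SDs are SE * sqrt(n of the summarised
## group).
morph_targets <- function(species = c("napi", "rapae"),
                          form = c("spring", "summer")) {
  species <- match.arg(species); form <- match.arg(form)
  f <- list(
    spring = list(area = c(225.6, 8.29 * sqrt(8)),
                  wl = c(0.0249, 0.00242 * sqrt(8)),
                  ar = c(1.77, 0.02 * sqrt(8)),
                  oe = c(1.11, 0.012 * sqrt(8))),
    summer = list(area = c(256.3, 7.93 * sqrt(18)),
                  wl = c(0.0209, 0.00156 * sqrt(18)),
                  ar = c(1.73, 0.01 * sqrt(18)),
                  oe = c(1.080, 0.006 * sqrt(18))))[[form]]
  mr <- list(napi = c(0.72, 0.008 * sqrt(14)),
             rapae = c(0.68, 0.007 * sqrt(12)))[[species]]
  c(f, list(mr = mr))
}

## Build one forewing geometry hitting the targets exactly:
## area (mm^2), aspect ratio (length/width), outer-edge index, marginal
## index. Constructed at unit forewing length then uniformly scaled to the
## target area; the design width parameter is fixed-pointed so the outline
## extent perpendicular to the 1->13 axis equals length/ar exactly.
build_forewing <- function(area, ar, oe, mr) {
  if (oe < 1 + 1e-6)
    stop("generation error: outer-edge index target ", oe, " < 1 infeasible")
  if (mr <= 0 || mr >= 1)
    stop("generation error: marginal index target ", mr, " outside (0,1)")
  if (area <= 0 || ar <= 1)
    stop("generation error: area/aspect-ratio targets infeasible")
  w_target <- 1 / ar
  shape_at <- function(wd) {
    lm <- matrix(NA_real_, 19, 2)
    lm[1, ] <- c(0, 0)
    lm[13, ] <- c(1, 0)
    lm[19, ] <- c(0.18, -0.80 * wd)
    chord <- lm[19, ] - lm[13, ]
    clen <- sqrt(sum(chord^2))
    nrm <- unit(c(chord[2], -chord[1]))
    if (sum(nrm * c(0.3, -1)) < 0) nrm <- -nrm   # bulge away from interior
    edge_pts <- function(b) {
      tpar <- (1:5) / 6
      base <- outer(1 - tpar, lm[13, ]) + outer(tpar, lm[19, ])
      base + outer(sin(pi * tpar) * b * clen, nrm)
    }
    oe_of <- function(b) {
      pts <- rbind(lm[13, ], edge_pts(b), lm[19, ])
      sum(sqrt(rowSums(diff(pts)^2))) / clen
    }
    beta <- stats::uniroot(function(b) oe_of(b) - oe, c(0, 0.6),
                           tol = 1e-13)$root
    lm[14:18, ] <- edge_pts(beta)
    tc <- seq(0, 1, length.out = 10)
    costal <- cbind(tc, 0.15 * wd * sin(pi * tc))
    ti <- seq(0, 1, length.out = 6)[2:5]
    inner <- outer(1 - ti, lm[19, ]) + outer(ti, lm[1, ])
    inner[, 2] <- inner[, 2] - 0.05 * wd * sin(pi * ti)
    outline <- rbind(costal[-10, ], lm[13, , drop = FALSE], lm[14:18, ],
                     lm[19, , drop = FALSE], inner)
    list(lm = lm, outline = outline,
         extent = max(outline[, 2]) - min(outline[, 2]))
  }
  wd <- w_target
  sh <- shape_at(wd)
  for (iter in 1:30) {
    if (abs(sh$extent - w_target) < 1e-12) break
    wd <- wd * w_target / sh$extent
    sh <- shape_at(wd)
  }
  lm <- sh$lm
  lm[9, ] <- c(mr, 0)
  ## remaining vein landmarks (unused by measurements): fixed template
  lm[2:8, ] <- cbind(seq(0.15, 0.95, length.out = 7),
                     0.12 * wd * sin(pi * seq(0.15, 0.95, length.out = 7)))
  lm[10:12, ] <- cbind(c(0.3, 0.5, 0.7), -0.35 * wd * c(0.8, 1, 0.8))
  a_now <- polygon_area(sh$outline) * 100   # shape area in mm^2 units
  s <- sqrt(area / a_now)
  list(landmarks = lm * s, outline = sh$outline * s)
}

## n-gon ellipse outline (mm) with exact polygon area `area`
ellipse_outline <- function(area, axis_ratio = 0.8, n = 36L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(cos(th), axis_ratio * sin(th))
  a_now <- polygon_area(p) * 100
  p * sqrt(area / a_now)
}

#' Generate synthetic wing landmark configurations for a group
#'
#' Draws per-specimen morphology targets (forewing area, aspect ratio,
#' outer-edge index, marginal-region index, wing loading) from Gaussian
#' group distributions whose means/SDs emulate the published group
#' summaries, then builds each specimen's 19-landmark forewing geometry,
#' outlines and thorax dimensions so that every derived measurement hits
#' its drawn target exactly. Population means therefore match the
#' configured group means without bias.
#'
#' @param n Number of specimens.
#' @param species `"napi"` or `"rapae"`.
#' @param form `"spring"` or `"summer"`.
#' @param sex `"male"` or `"female"` (labelling only).
#' @param seed RNG seed.
#' @param targets Optional override list with elements `area`, `wl`, `ar`,
#'   `oe`, `mr`, each `c(mean, sd)` (set sd = 0 for identical specimens).
#' @param area_ar_cor Correlation between the drawn forewing area and
#'   aspect ratio (larger wings tend to be relatively rounder; the study
#'   cohorts show about -0.40).
#' @param hindwing_ratio Hindwing/forewing area ratio.
#' @return A list of [wing_landmarks()] objects.
#' @export
generate_wing_landmarks <- function(n, species = "napi", form = "summer",
                                    sex = "male", seed = 1L, targets = NULL,
                                    area_ar_cor = -0.40,
                                    hindwing_ratio = 0.75) {
  if (is.null(targets)) targets <- morph_targets(species, form)
  if (targets$oe[1] < 1 + 1e-6 || targets$mr[1] <= 0 || targets$mr[1] >= 1 ||
      targets$area[1] <= 0 || targets$ar[1] <= 1 || targets$wl[1] <= 0)
    stop("generation error: infeasible target combination (",
         "oe = ", targets$oe[1], ", mr = ", targets$mr[1],
         ", area = ", targets$area[1], ", ar = ", targets$ar[1], ")")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw <- function(tg, lo, hi)
    pmin(hi, pmax(lo, stats::rnorm(n, tg[1], tg[2])))
  z1 <- stats::rnorm(n)
  z2 <- area_ar_cor * z1 + sqrt(1 - area_ar_cor^2) * stats::rnorm(n)
  area <- pmin(600, pmax(60, targets$area[1] + targets$area[2] * z1))
  ar <- pmin(2.6, pmax(1.2, targets$ar[1] + targets$ar[2] * z2))
  oe <- draw(targets$oe, 1.001, 1.6)
  mr <- draw(targets$mr, 0.3, 0.95)
  wl <- draw(targets$wl, 0.004, 0.08)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fw <- build_forewing(area[i], ar[i], oe[i], mr[i])
    hw <- ellipse_outline(hindwing_ratio * area[i])
    total_mm2 <- 2 * area[i] + 2 * hindwing_ratio * area[i]
    vol_mm3 <- wl[i] * total_mm2
    w_th <- (2 * vol_mm3 / pi)^(1 / 3)   # cylinder with length = 2 * width
    out[[i]] <- wing_landmarks(
      specimen_id = sprintf("%s_%s_%s_%02d", species, form,
                            substr(sex, 1, 1), i),
      landmarks = fw$landmarks, forewing_outline = fw$outline,
      hindwing_outline = hw, thorax_length = 2 * w_th, thorax_width = w_th,
      scale_mm_per_px = 0.05)
  }
  out
}

#' Cohort configuration
#'
#' Group structure and effect sizes for [generate_cohort()]. Defaults
#' mirror the study: 31 individuals (9 spring, 22 summer; 17 P. napi, 14
#' P. rapae; 5 females) with 106 tracks (26 spring, 80 summer), group mean
#' flight parameters equal to the published spring/summer marginal means
#' (velocity 1.2/1.7 m/s, acceleration 2.31/3.43 m/s^2, advance ratio
#' 0.10/0.14 m, turning acceleration 1.30/2.34 m/s^2, curvature 3.80/1.53
#' 1/m), log-scale individual and residual SDs calibrated to the printed
#' marginal-mean SEs, and ambient temperatures on the recorded 14-36 C
#' range with mean near 19 C and zero true effect on flight.
#'
#' @param individuals Data frame with columns species, form, sex, n
#'   (individuals per cell); default = the study cells.
#' @param tracks_per_form Named total track counts c(spring = , summer = ).
#' @param means_spring,means_summer Named group means (response scale).
#' @param sd_individual,sd_residual Log-scale between-individual and
#'   track-level SDs (ascent angle uses them in degrees x 10).
#' @param n_missing_wingbeats Tracks with the wingbeat count left missing.
#' @param temp_range Ambient temperature range (C).
#' @param seed RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(individuals = NULL,
                          tracks_per_form = c(spring = 26, summer = 80),
                          means_spring = NULL, means_summer = NULL,
                          sd_individual = 0.25, sd_residual = 0.25,
                          n_missing_wingbeats = 4L,
                          temp_range = c(14, 36), seed = 1L) {
  if (is.null(individuals))
    individuals <- data.frame(
      species = rep(c("napi", "rapae"), each = 4),
      form = rep(c("spring", "summer"), 4),
      sex = rep(rep(c("male", "female"), each = 2), 2),
      n = c(3, 11, 1, 2, 5, 7, 0, 2))
  defaults <- function(v, acc, tacc, curv, overrides) {
    base <- c(wingbeat_frequency = 11, flight_height = 1.1,
              mean_velocity = v, mean_acceleration = acc,
              turning_acceleration = tacc, turning_rate = 3.5,
              sinuosity = 0.75, flight_curvature = curv, ascent_angle = 2)
    if (!is.null(overrides)) base[names(overrides)] <- overrides
    base
  }
  means_spring <- defaults(1.2, 2.31, 1.30, 3.80, means_spring)
  means_summer <- defaults(1.7, 3.43, 2.34, 1.53, means_summer)
  structure(list(individuals = individuals,
                 tracks_per_form = tracks_per_form,
                 means = list(spring = means_spring, summer = means_summer),
                 sd_individual = sd_individual, sd_residual = sd_residual,
                 n_missing_wingbeats = as.integer(n_missing_wingbeats),
                 temp_range = temp_range, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic flight cohort
#'
#' Hierarchical generation of a full study cohort: individuals per species
#' x form x sex cell, per-individual random intercepts (log scale), then
#' per-track flight parameters drawn around the group means, each track
#' paired with a path profile (a helix whose closed-form speed and
#' curvature equal the track's drawn values) that can regenerate a 3D
#' trajectory. Wingbeat counts follow from the drawn frequency and
#' duration, with a configurable number left missing; ambient temperatures
#' are drawn per recording day with zero true effect.
#'
#' @param cfg A [cohort_config()].
#' @return A list of data frames: `specimens`, `tracks` (one row per
#'   trajectory with the eleven parameters and profile columns),
#'   `wingbeats`, `temperatures`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  cells <- cfg$individuals[cfg$individuals$n > 0, ]
  specimens <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(species = cells$species[i], form = cells$form[i],
               sex = cells$sex[i], idx = seq_len(cells$n[i]))
  }))
  specimens$individual_id <- sprintf("%s_%s_%s_%02d", specimens$species,
                                     specimens$form,
                                     substr(specimens$sex, 1, 1),
                                     specimens$idx)
  specimens$idx <- NULL
  n_ind <- nrow(specimens)
  specimens$day <- sample(rep(seq_len(12), length.out = n_ind))

  ## allocate track counts per individual within each form (1..6 each)
  specimens$n_tracks <- 0L
  for (f in names(cfg$tracks_per_form)) {
    ids <- which(specimens$form == f)
    total <- cfg$tracks_per_form[[f]]
    base <- total %/% length(ids)
    extra <- total %% length(ids)
    nt <- rep(base, length(ids))
    if (extra > 0) nt[seq_len(extra)] <- nt[seq_len(extra)] + 1L
    if (any(nt < 1 | nt > 6))
      stop("generate_cohort: per-individual track counts outside 1..6")
    specimens$n_tracks[ids] <- nt
  }

  params <- names(cfg$means$spring)
  if (any(unlist(cfg$means) <= 0))
    stop("generate_cohort: unsatisfiable kinematic target (non-positive mean)")
  ## individual random intercepts, one per parameter (log scale)
  b <- matrix(stats::rnorm(n_ind * length(params), 0, cfg$sd_individual),
              n_ind, length(params), dimnames = list(NULL, params))

  rows <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    nt <- specimens$n_tracks[i]
    mu <- cfg$means[[specimens$form[i]]]
    e <- matrix(stats::rnorm(nt * length(params), 0, cfg$sd_residual),
                nt, length(params), dimnames = list(NULL, params))
    tr <- as.data.frame(sapply(params, function(p) {
      if (p == "ascent_angle")
        mu[[p]] + (b[i, p] + e[, p]) * 10
      else if (p == "sinuosity")
        stats::plogis(stats::qlogis(mu[[p]]) + b[i, p] + e[, p])
      else
        exp(log(mu[[p]]) + b[i, p] + e[, p])
    }, simplify = FALSE))
    tr$covered_distance <- exp(stats::rnorm(nt, log(4), 0.4))
    tr$individual_id <- specimens$individual_id[i]
    rows[[i]] <- tr
  }
  tracks <- do.call(rbind, rows)
  tracks <- merge(tracks, specimens[, c("individual_id", "species", "form",
                                        "sex", "day")],
                  by = "individual_id", sort = FALSE)
  tracks$trajectory_id <- sprintf("tr%03d", seq_len(nrow(tracks)))
  tracks$duration_s <- tracks$covered_distance / tracks$mean_velocity
  tracks$advance_ratio <- tracks$mean_velocity / tracks$wingbeat_frequency

  ## path profile matching the drawn speed and curvature: helix with
  ## radius chosen so kappa = a/(a^2+b^2) at pitch b = 0.05 a
  a <- 1 / (tracks$flight_curvature * (1 + 0.05^2))
  tracks$profile_kind <- "helix"
  tracks$profile_radius <- a
  tracks$profile_pitch <- 0.05 * a
  tracks$profile_speed <- tracks$mean_velocity
  tracks$profile_duration <- pmax(20 / 120, tracks$duration_s)

  wing_n <- round(tracks$wingbeat_frequency * tracks$duration_s)
  miss <- sample(nrow(tracks), min(cfg$n_missing_wingbeats, nrow(tracks)))
  wing_n[miss] <- NA
  wingbeats <- data.frame(trajectory_id = tracks$trajectory_id,
                          n_wingbeats = wing_n,
                          duration_s = tracks$duration_s)
  tracks$wingbeat_frequency[miss] <- NA
  tracks$advance_ratio[miss] <- NA

  days <- sort(unique(specimens$day))
  temperatures <- data.frame(
    day = days,
    temp_c = cfg$temp_range[1] + diff(cfg$temp_range) *
      stats::rbeta(length(days), 1.5, 5.1))

  list(specimens = specimens, tracks = tracks, wingbeats = wingbeats,
       temperatures = temperatures)
}

#' Generate per-specimen morphology for a cohort
#'
#' One wing-landmark configuration per specimen row, drawn from the
#' specimen's species x form group targets, summarised into the derived
#' morphometric table.
#'
#' @param specimens The `specimens` data frame from [generate_cohort()].
#' @param seed RNG seed.
#' @return A data frame: one `morpho_summary` row per specimen, plus the
#'   grouping columns.
#' @export
cohort_morphology <- function(specimens, seed = 1L) {
  out <- vector("list", nrow(specimens))
  for (i in seq_len(nrow(specimens))) {
    lml <- generate_wing_landmarks(1, specimens$species[i],
                                   specimens$form[i], specimens$sex[i],
                                   seed = seed + i)
    ms <- summarize_morphology(lml[[1]])
    ms$specimen_id <- specimens$individual_id[i]
    out[[i]] <- cbind(ms, specimens[i, c("species", "form", "sex")],
                      row.names = NULL)
  }
  do.call(rbind, out)
}
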
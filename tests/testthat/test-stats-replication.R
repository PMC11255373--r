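test_that("pairwise correlations recover known structure", {
  set.seed(1)
  n <- 1000
  null_tab <- data.frame(forewing_area = rnorm(n), aspect_ratio = rnorm(n),
                         wing_loading = rnorm(n),
                         outer_edge_index = rnorm(n),
                         marginal_region_index = rnorm(n))
  pc <- pairwise_correlations(null_tab)
  expect_equal(diag(pc$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(nrow(pc$pairs), choose(5, 2))
  # independent columns: |r| essentially always < 0.1 at n = 1000
  frac_small <- mean(vapply(1:20, function(s) {
    set.seed(s)
    tab <- as.data.frame(matrix(rnorm(5 * n), ncol = 5))
    names(tab) <- names(null_tab)
    all(abs(pairwise_correlations(tab)$pairs$r) < 0.1)
  }, logical(1)))
  expect_gte(frac_small, 0.9)
  # the generator's built-in area/aspect-ratio correlation (-0.40) is
  # recovered within its sampling CI
  lms <- generate_wing_landmarks(200, "napi", "summer", seed = 6)
  ms <- do.call(rbind, lapply(lms, summarize_morphology))
  ct <- cor.test(ms$forewing_area, ms$aspect_ratio)
  expect_true(-0.40 > ct$conf.int[1] && -0.40 < ct$conf.int[2])
  const <- null_tab; const$wing_loading <- 1
  expect_error(pairwise_correlations(const), "constant")
})

test_that("morphology ANOVA is calibrated under the null and powered under the gap", {
  make_tab <- function(n_per, mu_by_form, seed) {
    set.seed(seed)
    g <- expand.grid(species = c("napi", "rapae"),
                     form = c("spring", "summer"))
    do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      data.frame(species = g$species[i], form = g$form[i],
                 forewing_area = rnorm(n_per, mu_by_form[[as.character(
                   g$form[i])]], 30),
                 aspect_ratio = rnorm(n_per, 1.75, 0.05),
                 wing_loading = rnorm(n_per, 0.02, 0.005),
                 outer_edge_index = rnorm(n_per, 1.09, 0.03),
                 marginal_region_index = rnorm(n_per, 0.7, 0.03))
    }))
  }
  # null: form p-values roughly uniform over seeded replicates
  ps <- vapply(1:60, function(s) {
    tab <- make_tab(8, list(spring = 240, summer = 240), s)
    an <- anova_morphology(tab)
    an$p[an$variable == "forewing_area" & an$term == "form"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # the tabulated seasonal gap (225.6 vs 256.3 mm^2) at n = 200 is
  # detected essentially always
  rej <- vapply(1:40, function(s) {
    tab <- make_tab(50, list(spring = 225.6, summer = 256.3), s)
    an <- anova_morphology(tab)
    an$p[an$variable == "forewing_area" & an$term == "form"] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.95)
  # degenerate designs are refused
  one <- make_tab(1, list(spring = 240, summer = 240), 1)
  expect_error(anova_morphology(one), "single observation")
})

test_that("EM-PCA imputation reduces to plain PCA and completes low-rank data", {
  set.seed(4)
  full <- as.data.frame(matrix(rnorm(200), 40, 5))
  out <- pca_with_imputation(full)
  ref <- prcomp(full, center = TRUE, scale. = TRUE)
  for (j in 1:5)
    expect_equal(abs(out$loadings[, j]), abs(ref$rotation[, j]),
                 tolerance = 1e-9)
  expect_equal(sum(out$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(out$n_imputed, 0)

  # exact rank-2 matrix with 10% holes is recovered to machine-ish level
  U <- matrix(rnorm(120), 60, 2); V <- matrix(rnorm(12), 6, 2)
  M <- U %*% t(V)
  holes <- sample(length(M), 0.1 * length(M))
  Mm <- M; Mm[holes] <- NA
  imp <- pierisflight:::impute_pca_em(Mm, ncp = 2, tol = 1e-12,
                                      max_iter = 5000)
  expect_lt(sqrt(mean((imp[holes] - M[holes])^2)), 1e-6)
  allna <- as.data.frame(Mm); allna[[1]] <- NA_real_
  expect_error(pierisflight:::impute_pca_em(allna), "all-missing")
})

test_that("the flight LMM matches OLS when the random variance is zero", {
  tracks <- simulate_tracks(n_ind = 16, tracks_per = 1, sd_ind = 0,
                            sd_res = 0.3, seed = 5)
  # one track per individual: the individual variance is unidentifiable,
  # must be flagged singular and refit as a fixed-effect model
  fit <- suppressWarnings(fit_flight_lmm("mean_velocity", tracks))
  expect_true(fit$singular)
  ref <- lm(log(mean_velocity) ~ species + form + sex +
              log(covered_distance), data = tracks)
  expect_equal(unname(coef(fit$model)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("marginal means equal raw group means in balanced designs", {
  set.seed(6)
  per <- 13
  cd <- exp(rnorm(per, log(4), 0.3))
  d <- data.frame(individual_id = sprintf("i%02d", 1:(3 * per)),
                  site = rep(c("a", "b", "c"), each = per),
                  covered_distance = rep(cd, 3))  # covariate balanced
  d$mean_velocity <- exp(rnorm(3 * per, log(1.5) + 0.2 * (d$site == "b"),
                               0.2))
  fit <- suppressWarnings(fit_flight_lmm("mean_velocity", d,
                                         fixed = "site"))
  mm <- marginal_means(fit, "site")
  raw <- tapply(log(d$mean_velocity), d$site, mean)
  expect_equal(mm$means$emmean, as.numeric(raw[mm$means$level]),
               tolerance = 1e-9)
  expect_equal(nrow(mm$contrasts), 3)   # k(k-1)/2 for k = 3
  # Tukey adjustment can only increase p
  raw_p <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit$model, "site"), method = "pairwise",
    adjust = "none"))$p.value
  expect_true(all(mm$contrasts$p.value >= raw_p - 1e-12))
  expect_error(marginal_means(fit, "species"), "not in the model")
})

test_that("back-transformed marginal means recover the generator's seasonal gap", {
  ch <- generate_cohort(cohort_config(seed = 10))
  fit <- fit_flight_lmm("mean_velocity", ch$tracks)
  mm <- marginal_means(fit, "form")
  sp <- mm$means[mm$means$level == "spring", ]
  su <- mm$means[mm$means$level == "summer", ]
  expect_lt(abs(sp$response_mean - 1.2), 2 * sp$response_SE)
  expect_lt(abs(su$response_mean - 1.7), 2 * su$response_SE)
})

test_that("Cohen's d is the coefficient/SE ratio", {
  expect_equal(cohens_d_from_fit(0, 2), 0)
  expect_equal(cohens_d_from_fit(c(1, -3), c(2, 2)), c(0.5, -1.5))
  expect_error(cohens_d_from_fit(1, 0), "SE")
})

test_that("stepwise backward selection keeps real predictors and drops noise", {
  # strong true effect of the outer-edge index (about 5 SE at this n)
  keep <- vapply(1:10, function(s) {
    tr <- simulate_tracks(n_ind = 50, tracks_per = 4, sd_ind = 0.15,
                          sd_res = 0.2, seed = s)
    d <- join_morpho(tr, beta = 8, seed = s)
    sel <- stepwise_backward("mean_velocity", d)
    "outer_edge_index" %in% sel$retained
  }, logical(1))
  expect_gte(mean(keep), 0.9)
  # all-null predictors retained only at about the alpha rate
  n_kept <- vapply(1:20, function(s) {
    tr <- simulate_tracks(n_ind = 30, tracks_per = 3, sd_ind = 0.15,
                          sd_res = 0.2, seed = s + 100)
    d <- join_morpho(tr, beta = 0, seed = s + 100)
    length(stepwise_backward("mean_velocity", d)$retained)
  }, numeric(1))
  expect_lte(mean(n_kept) / 5, 0.15)
})

test_that("dredge ranks subsets with normalised Akaike weights", {
  tr <- simulate_tracks(n_ind = 40, tracks_per = 3, sd_ind = 0.15,
                        sd_res = 0.2, seed = 3)
  d <- join_morpho(tr, beta = 8, seed = 3)
  dr <- dredge_all_subsets("mean_velocity", d)
  expect_equal(nrow(dr$table), 2^5)
  expect_equal(sum(dr$table$weight), 1, tolerance = 1e-12)
  expect_gt(dr$variable_weights[["outer_edge_index"]], 0.9)
  # the full-subset AICc in the table equals a direct fit
  full_row <- dr$table[dr$table$terms ==
                         paste(pierisflight:::MORPHO_VARS, collapse = "+"), ]
  refit <- pierisflight:::morpho_lmm_ml("mean_velocity", d,
                                        pierisflight:::MORPHO_VARS)
  expect_equal(full_row$AICc,
               pierisflight:::aicc_of(refit, nrow(d)), tolerance = 1e-9)
  # no candidate terms: a single intercept model with weight 1
  dr0 <- dredge_all_subsets("mean_velocity", d, terms = character(0))
  expect_equal(nrow(dr0$table), 1)
  expect_equal(dr0$table$weight, 1)
  expect_error(dredge_all_subsets("mean_velocity", d,
                                  terms = sprintf("t%d", 1:13)), "cap")
})

test_that("temperature models are calibrated at the null and detect real effects", {
  base <- function(s, beta) {
    tr <- simulate_tracks(n_ind = 40, tracks_per = 4, sd_ind = 0.15,
                          sd_res = 0.2, seed = s)
    tr$day <- rep(1:10, length.out = nrow(tr))
    day_t <- 14 + 22 * rbeta(10, 1.5, 5.1)
    tr$temp_c <- day_t[tr$day] + rnorm(nrow(tr), 0, 0.5)
    tr$mean_velocity <- tr$mean_velocity * exp(beta * (tr$temp_c - 19))
    tr$flight_curvature <- exp(rnorm(nrow(tr), log(2.5), 0.3))
    tr
  }
  ps <- vapply(1:30, function(s) {
    tm <- temperature_models(base(s, 0), responses = "mean_velocity")
    tm$p[tm$spec == "full"]
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.20)   # near the nominal rate
  det <- vapply(1:10, function(s) {
    tm <- temperature_models(base(s, 0.05), responses = "mean_velocity")
    tm$p[tm$spec == "full"] < 0.05
  }, logical(1))
  expect_gt(mean(det), 0.9)
  d <- base(1, 0); d$temp_c[1:3] <- NA
  expect_message(temperature_models(d, responses = "mean_velocity"),
                 "dropping 3")
  d2 <- base(1, 0); d2$temp_c <- 19
  expect_error(temperature_models(d2, responses = "mean_velocity"),
               "constant")
})
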
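## Comparative statistical layer: morphology correlations and two-way
## ANOVA, PCA with iterative (EM) imputation of missing wingbeat-derived
## values, linear mixed models with Satterthwaite F-tests, marginal means
## with Tukey contrasts, Cohen's d from fitted slopes, stepwise backward
## elimination, and all-subsets AICc ranking with per-variable Akaike
## weight sums.

MORPHO_VARS <- c("forewing_area", "aspect_ratio", "wing_loading",
                 "outer_edge_index", "marginal_region_index")

#' Pairwise correlations among morphological variables
#'
#' Pearson correlation with a two-sided test for every pair of the five
#' standard morphological variables (forewing area, aspect ratio, wing
#' loading, outer-edge index, marginal-region index), or any supplied set.
#'
#' @param morpho Data frame containing the variables.
#' @param vars Variable names (default the standard five).
#' @return A list: `r` (correlation matrix), `p` (p-value matrix), `pairs`
#'   (tidy per-pair data frame), `n` (complete cases per pair).
#' @export
pairwise_correlations <- function(morpho, vars = MORPHO_VARS) {
  stopifnot(all(vars %in% names(morpho)))
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    x <- morpho[[vars[i]]]; y <- morpho[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L)
      stop("pairwise_correlations: < 3 complete cases for ",
           vars[i], " vs ", vars[j])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("pairwise_correlations: undefined correlation - constant column ",
           if (stats::sd(x[ok]) == 0) vars[i] else vars[j])
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    rows[[length(rows) + 1]] <- data.frame(
      var1 = vars[i], var2 = vars[j], r = unname(ct$estimate),
      p = ct$p.value, n = sum(ok))
  }
  list(r = r, p = p, pairs = do.call(rbind, rows), n = nmat)
}

#' Two-way ANOVA of morphology by species and seasonal form
#'
#' Per-variable `aov` with species, form and their interaction.
#'
#' @param morpho Data frame with the morphological variables plus `species`
#'   and `form` factor columns.
#' @param vars Variables to test.
#' @return A tidy data frame: variable, term, df, F, p.
#' @export
anova_morphology <- function(morpho, vars = MORPHO_VARS) {
  stopifnot(all(c(vars, "species", "form") %in% names(morpho)))
  tab <- table(morpho$species, morpho$form)
  if (any(dim(tab) < 2))
    stop("anova_morphology: need >= 2 levels of species and form")
  if (any(tab == 0))
    stop("anova_morphology: empty species x form cell with interaction ",
         "requested")
  if (any(tab == 1))
    stop("anova_morphology: single observation in a species x form cell")
  out <- list()
  for (v in vars) {
    fit <- stats::aov(stats::reformulate(c("species", "form", "species:form"),
                                         response = v), data = morpho)
    s <- summary(fit)[[1]]
    terms <- trimws(rownames(s))
    keep <- terms != "Residuals"
    out[[v]] <- data.frame(variable = v, term = terms[keep],
                           df = s$Df[keep], F = s$`F value`[keep],
                           p = s$`Pr(>F)`[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## iterative EM-PCA imputation: mean-initialised, rank-ncp SVD
## reconstruction of missing cells until convergence
impute_pca_em <- function(X, ncp = 2L, tol = 1e-8, max_iter = 1000L) {
  X <- as.matrix(X)
  miss <- is.na(X)
  if (any(colSums(!miss) == 0)) stop("impute_pca_em: all-missing column")
  if (!any(miss)) return(X)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[sdv == 0] <- 1
  W <- sweep(X, 2, sdv, "/")
  mu <- colMeans(W, na.rm = TRUE)
  W[miss] <- rep_row(mu, nrow(W))[miss]   # mean initialisation
  repeat {
    mu <- colMeans(W)                     # centre re-estimated each pass
    Z <- sweep(W, 2, mu)
    sv <- svd(Z, nu = ncp, nv = ncp)
    Zhat <- sv$u %*% (t(sv$v) * sv$d[seq_len(ncp)])
    new_vals <- sweep(Zhat, 2, mu, `+`)[miss]
    delta <- max(abs(new_vals - W[miss]))
    W[miss] <- new_vals
    max_iter <- max_iter - 1L
    if (delta < tol || max_iter <= 0L) break
  }
  sweep(W, 2, sdv, "*")
}

#' PCA with iterative imputation of missing values
#'
#' Missing cells (typically wingbeat frequency and advance ratio on tracks
#' where wingbeats could not be scored) are filled by deterministic,
#' mean-initialised iterative EM-PCA (rank `ncp`, convergence 1e-8); the
#' completed table is then standardised and decomposed by ordinary PCA.
#' With no missing values the result equals plain PCA.
#'
#' @param flight Data frame of flight parameters (numeric columns only are
#'   used).
#' @param vars Columns to include.
#' @param ncp Imputation rank.
#' @return A list: `scores`, `loadings`, `variance_fraction`, `imputed`
#'   (completed data frame), `n_imputed`.
#' @export
pca_with_imputation <- function(flight, vars = NULL, ncp = 2L) {
  if (is.null(vars))
    vars <- names(flight)[vapply(flight, is.numeric, logical(1))]
  X <- as.matrix(flight[, vars])
  frac_missing <- colMeans(is.na(X))
  if (any(frac_missing >= 0.2))
    stop("pca_with_imputation: column(s) over 20% missing: ",
         paste(vars[frac_missing >= 0.2], collapse = ", "))
  Xc <- impute_pca_em(X, ncp = ncp)
  pc <- stats::prcomp(Xc, center = TRUE, scale. = TRUE)
  list(scores = pc$x, loadings = pc$rotation,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
       imputed = as.data.frame(Xc), n_imputed = sum(is.na(X)))
}

## log-transform positive responses; sign-carrying responses (ascent
## angle) and any non-positive response are analysed untransformed
prep_response <- function(data, response) {
  y <- data[[response]]
  if (all(y > 0, na.rm = TRUE)) {
    data$.y <- log(y)
    attr(data, "log_response") <- TRUE
  } else {
    data$.y <- y
    attr(data, "log_response") <- FALSE
  }
  data
}

#' Linear mixed model for one flight characteristic
#'
#' REML fit of `log(response) ~ species + form + sex + log(covered
#' distance) + (1 | individual)` with Satterthwaite-approximated F-tests
#' for the fixed terms. Responses that are not strictly positive (ascent
#' angle) are analysed untransformed with a note. A singular random-effect
#' fit is flagged and refit without the random term.
#'
#' @param response Column name of the flight characteristic.
#' @param data Track-level data frame with columns `species`, `form`,
#'   `sex`, `covered_distance`, `individual_id` and the response.
#' @param fixed Character vector of fixed factor terms.
#' @return A list of class `flight_lmm`: `model`, `anova` (term, F, den df,
#'   p), `coefficients`, `singular`, `log_response`, `n_obs`, `n_groups`,
#'   `AIC`, `AICc`, `logLik`.
#' @export
fit_flight_lmm <- function(response, data,
                           fixed = c("species", "form", "sex")) {
  stopifnot(response %in% names(data))
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  data <- prep_response(data, response)
  data$.logdist <- log(data$covered_distance)
  fml <- stats::as.formula(paste(".y ~", paste(c(fixed, ".logdist"),
                                               collapse = " + "),
                                 "+ (1 | individual_id)"))
  if (max(table(data$individual_id)) < 2L) {
    ## one track per individual: the random intercept is unidentifiable
    singular <- TRUE
    fit <- NULL
  } else {
    fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
    singular <- lme4::isSingular(fit, tol = 1e-5)
  }
  if (singular) {
    warning("fit_flight_lmm(", response,
            "): singular random-effect variance; refitting without it")
    fit_fixed <- stats::lm(stats::as.formula(
      paste(".y ~", paste(c(fixed, ".logdist"), collapse = " + "))),
      data = data)
    an0 <- stats::anova(fit_fixed)
    an <- data.frame(term = rownames(an0)[rownames(an0) != "Residuals"],
                     F = an0$`F value`[rownames(an0) != "Residuals"],
                     den_df = stats::df.residual(fit_fixed),
                     p = an0$`Pr(>F)`[rownames(an0) != "Residuals"])
    co <- summary(fit_fixed)$coefficients
    model <- fit_fixed
  } else {
    an0 <- stats::anova(fit, type = 3)
    an <- data.frame(term = rownames(an0), F = an0$`F value`,
                     den_df = an0$DenDF, p = an0$`Pr(>F)`)
    co <- summary(fit)$coefficients
    model <- fit
  }
  ll <- as.numeric(stats::logLik(model))
  k <- attr(stats::logLik(model), "df")
  n <- nrow(data)
  structure(list(model = model, anova = an,
                 coefficients = as.data.frame(co),
                 singular = singular,
                 log_response = attr(data, "log_response"),
                 response = response,
                 n_obs = n, n_groups = length(unique(data$individual_id)),
                 AIC = stats::AIC(model),
                 AICc = stats::AIC(model) + 2 * k * (k + 1) / (n - k - 1),
                 logLik = ll),
            class = "flight_lmm")
}

#' @export
print.flight_lmm <- function(x, ...) {
  cat(sprintf("<flight_lmm> %s%s: %d obs / %d individuals%s\n",
              if (x$log_response) "log " else "", x$response,
              x$n_obs, x$n_groups,
              if (x$singular) " [singular random effect]" else ""))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Marginal means and Tukey contrasts for a model factor
#'
#' Model-based means at the reference grid (other factors averaged,
#' covariates at their means) with Tukey-adjusted pairwise comparisons.
#' When the model was fitted on the log scale, means are back-transformed
#' to the response scale (contrasts are tested on the model scale).
#'
#' @param fit A `flight_lmm` from [fit_flight_lmm()].
#' @param factor Factor name present in the model.
#' @return A list of class `marginal_means`: `means` (level, emmean, SE,
#'   response-scale mean when applicable), `contrasts` (Tukey-adjusted).
#' @export
marginal_means <- function(fit, factor) {
  mdl <- fit$model
  vars <- all.vars(stats::formula(mdl))
  if (!factor %in% vars) stop("marginal_means: factor '", factor,
                              "' not in the model")
  if (length(unique(stats::model.frame(mdl)[[factor]])) < 2)
    stop("marginal_means: factor '", factor, "' has a single level")
  em <- emmeans::emmeans(mdl, specs = factor)
  ms <- as.data.frame(em)
  names(ms)[1] <- "level"
  if (isTRUE(fit$log_response)) {
    ms$response_mean <- exp(ms$emmean)
    ms$response_SE <- exp(ms$emmean) * ms$SE   # delta method
  }
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  structure(list(means = ms, contrasts = ct, factor = factor),
            class = "marginal_means")
}

#' @export
print.marginal_means <- function(x, ...) {
  cat("<marginal_means> factor:", x$factor, "\n")
  print(x$means, digits = 4)
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Cohen's d from a fitted coefficient
#'
#' Standardised effect size of a model term: the estimated coefficient
#' divided by its standard error.
#'
#' @param coefficient Estimate.
#' @param se Standard error (> 0).
#' @return d.
#' @export
cohens_d_from_fit <- function(coefficient, se) {
  if (any(se <= 0)) stop("cohens_d_from_fit: SE must be > 0")
  coefficient / se
}

## LMM of one flight characteristic on log-transformed morphological
## predictors + log covered distance + sex, random intercept by individual
morpho_lmm <- function(response, data, terms) {
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  data <- prep_response(data, response)
  data$.logdist <- log(data$covered_distance)
  for (tm in terms) data[[paste0(".l_", tm)]] <- log(data[[tm]])
  rhs <- c(if (length(terms)) paste0(".l_", terms), ".logdist", "sex")
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                                 "+ (1 | individual_id)"))
  lmerTest::lmer(fml, data = data, REML = TRUE)
}

#' Stepwise backward selection of morphological predictors
#'
#' Starting from the full model (all morphological terms, plus log covered
#' distance and sex always retained), iteratively removes the
#' least-significant morphological term (largest Satterthwaite F-test p
#' above `alpha`) and refits, until every retained morphological term has
#' p <= alpha. Deterministic; the elimination order is logged.
#'
#' @param response Flight characteristic column.
#' @param data Track-level data joined with per-individual morphology.
#' @param terms Candidate morphological variables.
#' @param alpha Retention threshold.
#' @return A list of class `selection_result`: `retained`, `eliminated`
#'   (in order), `final_model`, `final_anova`.
#' @export
stepwise_backward <- function(response, data, terms = MORPHO_VARS,
                              alpha = 0.05) {
  current <- terms
  eliminated <- character(0)
  repeat {
    fit <- morpho_lmm(response, data, current)
    if (length(current) == 0) break
    an <- stats::anova(fit, type = 3)
    rows <- paste0(".l_", current)
    p <- an[rows, "Pr(>F)"]
    worst <- which.max(p)
    if (p[worst] <= alpha) break
    eliminated <- c(eliminated, current[worst])
    current <- current[-worst]
  }
  fit <- morpho_lmm(response, data, current)
  an <- if (length(current))
    stats::anova(fit, type = 3) else NULL
  structure(list(retained = current, eliminated = eliminated,
                 final_model = fit, final_anova = an, response = response),
            class = "selection_result")
}

## second-order AIC
aicc_of <- function(fit, n) {
  k <- attr(stats::logLik(fit), "df")
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets model ranking (dredge) by AICc
#'
#' Fits every subset of the candidate morphological terms (log covered
#' distance and sex always included) by maximum likelihood, ranks by AICc,
#' and reports Akaike weights plus per-variable weight sums (the summed
#' weight of every model containing the variable - a relative importance
#' measure).
#'
#' @inheritParams stepwise_backward
#' @param max_terms Cap on candidate terms (2^k models).
#' @return A list of class `dredge_result`: `table` (one row per model:
#'   terms, k, AICc, delta, weight), `variable_weights`.
#' @export
dredge_all_subsets <- function(response, data, terms = MORPHO_VARS,
                               max_terms = 12L) {
  if (length(terms) > max_terms)
    stop("dredge_all_subsets: ", length(terms),
         " candidate terms exceed the cap (", max_terms,
         "); reduce the term set")
  data2 <- data[is.finite(data[[response]]), , drop = FALSE]
  n <- nrow(data2)
  subsets <- lapply(0:(2^length(terms) - 1), function(mask) {
    terms[bitwAnd(mask, 2^(seq_along(terms) - 1)) > 0]
  })
  rows <- lapply(subsets, function(sub) {
    fit <- morpho_lmm_ml(response, data2, sub)
    data.frame(terms = paste(sub, collapse = "+"),
               k = attr(stats::logLik(fit), "df"),
               AICc = aicc_of(fit, n))
  })
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab <- tab[order(tab$AICc), ]
  vw <- vapply(terms, function(tm) {
    sum(tab$weight[vapply(strsplit(tab$terms, "+", fixed = TRUE),
                          function(s) tm %in% s, logical(1))])
  }, numeric(1))
  structure(list(table = tab, variable_weights = vw, response = response),
            class = "dredge_result")
}

## ML (not REML) variant for information-criterion comparison
morpho_lmm_ml <- function(response, data, terms) {
  data <- prep_response(data, response)
  data$.logdist <- log(data$covered_distance)
  for (tm in terms) data[[paste0(".l_", tm)]] <- log(data[[tm]])
  rhs <- c(if (length(terms)) paste0(".l_", terms), ".logdist", "sex")
  fml <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                                 "+ (1 | individual_id)"))
  lme4::lmer(fml, data = data, REML = FALSE)
}

#' Morphology-on-flight effect table
#'
#' Fits the full morphological LMM for one flight characteristic and
#' tabulates, per morphological variable, the slope, SE, Cohen's d and the
#' Satterthwaite F-test.
#'
#' @inheritParams stepwise_backward
#' @return Data frame: response, trait, slope, SE, d, F, den df, p.
#' @export
morphology_effects <- function(response, data, terms = MORPHO_VARS) {
  fit <- morpho_lmm(response, data, terms)
  co <- summary(fit)$coefficients
  an <- stats::anova(fit, type = 3)
  rows <- paste0(".l_", terms)
  data.frame(response = response, trait = terms,
             slope = co[rows, "Estimate"], SE = co[rows, "Std. Error"],
             d = cohens_d_from_fit(co[rows, "Estimate"],
                                   co[rows, "Std. Error"]),
             F = an[rows, "F value"], den_df = an[rows, "DenDF"],
             p = an[rows, "Pr(>F)"], row.names = NULL)
}

#' Ambient-temperature models
#'
#' The two temperature specifications: (1) an LMM of each flight
#' characteristic on ambient temperature with species and seasonal form as
#' fixed factors and individual as random factor; (2) a simplified LMM
#' with the mean ambient temperature of each recording day as the only
#' fixed effect.
#'
#' @param data Track-level data with a `temp_c` column (per-track ambient
#'   temperature) and `day`; rows with missing temperature are dropped
#'   with a message.
#' @param responses Flight characteristics to model.
#' @return A data frame with one row per response x specification:
#'   temperature F, den df, p.
#' @export
temperature_models <- function(data, responses = c("mean_velocity",
                                                   "flight_curvature")) {
  if (!"temp_c" %in% names(data))
    stop("temperature_models: no temp_c column")
  drop_n <- sum(!is.finite(data$temp_c))
  if (drop_n > 0) {
    message("temperature_models: dropping ", drop_n,
            " rows with missing temperature")
    data <- data[is.finite(data$temp_c), , drop = FALSE]
  }
  if (stats::sd(data$temp_c) == 0)
    stop("temperature_models: constant temperature")
  day_mean <- stats::aggregate(temp_c ~ day, data, mean)
  names(day_mean)[2] <- "day_temp"
  data <- merge(data, day_mean, by = "day", sort = FALSE)
  out <- list()
  for (resp in responses) {
    d2 <- prep_response(data[is.finite(data[[resp]]), , drop = FALSE], resp)
    f1 <- lmerTest::lmer(.y ~ temp_c + species + form + (1 | individual_id),
                         data = d2, REML = TRUE)
    a1 <- stats::anova(f1, type = 3)["temp_c", ]
    f2 <- lmerTest::lmer(.y ~ day_temp + (1 | individual_id),
                         data = d2, REML = TRUE)
    a2 <- stats::anova(f2, type = 3)["day_temp", ]
    out[[resp]] <- data.frame(
      response = resp, spec = c("full", "day_mean"),
      F = c(a1$`F value`, a2$`F value`),
      den_df = c(a1$DenDF, a2$DenDF),
      p = c(a1$`Pr(>F)`, a2$`Pr(>F)`))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
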
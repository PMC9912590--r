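#' @title Mixed-model inference stage
#' @description
#' Group matching, covariate imputation, linear mixed models with crossed
#' random intercepts for participant and scene, Satterthwaite F-tests,
#' Benjamini-Hochberg FDR adjustment, standardized coefficients, marginal
#' contrasts, maximum-likelihood model comparison, and simulation-based
#' power. Model fitting delegates to \pkg{lme4}/\pkg{lmerTest}; this module
#' owns the standardization, the coding, and the result schema.
#' @name stats_models
NULL

#' Nearest-neighbour group matching with a caliper
#'
#' 1:1 nearest-neighbour matching without replacement on z-standardized
#' matching variables (Euclidean distance). A pair is only formed when the
#' standardized difference on every matching variable is within the
#' caliper; cases with no admissible partner stay unmatched.
#'
#' @param cohort Participant table with `participant` and `group` columns
#'   (groups `"ASD"` and `"TD"`).
#' @param vars Matching variables (default perceptual IQ, age and the
#'   data-quality metrics present).
#' @param caliper Per-variable tolerance in SD units (default 0.4).
#' @return The matched subset of `cohort` with a `match_id` column; a
#'   warning (and zero rows) when no pair is feasible.
#' @export
match_groups <- function(cohort,
                         vars = intersect(c("perceptual_iq", "age",
                                            "accuracy_z", "precision_z",
                                            "available_data_pct"),
                                          names(cohort)),
                         caliper = 0.4) {
  stopifnot(all(c("participant", "group") %in% names(cohort)))
  cases <- which(cohort$group == "ASD")
  ctrls <- which(cohort$group == "TD")
  if (!length(cases) || !length(ctrls)) stop("both groups must be non-empty")
  z <- scale(as.matrix(cohort[, vars, drop = FALSE]))
  z[, apply(z, 2, function(c) all(!is.finite(c)))] <- 0  # constant vars
  z[!is.finite(z)] <- 0
  avail <- rep(TRUE, length(ctrls))
  pairs <- list()
  for (i in cases) {
    d2 <- colSums((t(z[ctrls, , drop = FALSE]) - z[i, ])^2)
    within <- apply(abs(t(z[ctrls, , drop = FALSE]) - z[i, ]) <= caliper, 2, all)
    cand <- which(avail & within)
    if (!length(cand)) next
    j <- cand[which.min(d2[cand])]
    avail[j] <- FALSE
    pairs[[length(pairs) + 1L]] <- c(i, ctrls[j])
  }
  if (!length(pairs)) {
    warning("no feasible pair within the caliper; empty match")
    out <- cohort[0, , drop = FALSE]
    out$match_id <- integer(0)
    return(out)
  }
  idx <- do.call(rbind, pairs)
  out <- cohort[as.vector(t(idx)), , drop = FALSE]
  out$match_id <- rep(seq_len(nrow(idx)), each = 2)
  rownames(out) <- NULL
  out
}

#' Impute missing covariates by group-wise predictive mean matching
#'
#' For each covariate with missing cells, a linear predictor is fitted
#' within each group from the complete auxiliary variables; each missing
#' cell receives the observed value of the donor whose prediction is
#' closest (1-nearest predictive mean matching). A `imputed_<var>` flag
#' column is added per imputed covariate.
#'
#' @param table Data frame with a `group` column.
#' @param covariates Columns to impute (default: those with any `NA`).
#' @param aux Auxiliary predictors (default age, perceptual IQ if present).
#' @return The table with no missing cells in `covariates`.
#' @export
impute_covariates <- function(table,
                              covariates = NULL,
                              aux = intersect(c("age", "perceptual_iq"),
                                              names(table))) {
  if (is.null(covariates)) {
    covariates <- names(table)[vapply(table, function(c)
      is.numeric(c) && anyNA(c), TRUE)]
  }
  for (v in covariates) {
    if (all(is.na(table[[v]]))) stop("covariate entirely missing: ", v)
    if (mean(is.na(table[[v]])) >= 0.5) {
      stop("covariate ", v, " is >= 50% missing")
    }
    flag <- is.na(table[[v]])
    for (g in unique(table$group)) {
      rows <- table$group == g
      miss <- rows & flag
      if (!any(miss)) next
      donors <- rows & !flag
      use_aux <- aux[vapply(aux, function(a)
        sum(!is.na(table[[a]][donors])) > 2, TRUE)]
      if (length(use_aux)) {
        f <- stats::as.formula(paste(v, "~", paste(use_aux, collapse = "+")))
        fit <- stats::lm(f, data = table[donors, , drop = FALSE])
        pred_d <- stats::predict(fit, table[donors, , drop = FALSE])
        pred_m <- stats::predict(fit, table[miss, , drop = FALSE])
        dvals <- table[[v]][donors]
        table[[v]][miss] <- vapply(pred_m, function(p) {
          dvals[which.min(abs(pred_d - p))]
        }, numeric(1))
      } else {
        table[[v]][miss] <- mean(table[[v]][donors])
      }
    }
    table[[paste0("imputed_", v)]] <- flag
  }
  table
}

#' Specify a linear mixed model
#'
#' @param outcome Outcome column (e.g. `"pupil_response"`,
#'   `"gaze_physical_salience"`, `"face_gaze"`).
#' @param fixed Fixed-effect terms (column names; `:` interactions allowed).
#' @param covariates Additional covariate columns.
#' @param time_poly Include the 3rd-degree polynomial of time-in-scene
#'   (`time1 + time2 + time3`); dropped automatically when PR1/PR2 enter.
#' @param human_only Restrict to human scenes (face-gaze models).
#' @param random Random-intercept grouping columns.
#' @return A list of class `lmm_spec`.
#' @export
lmm_spec <- function(outcome, fixed = c("group", "category",
                                        "group:category"),
                     covariates = character(0), time_poly = TRUE,
                     human_only = FALSE,
                     random = c("participant", "scene")) {
  uses_pr <- any(c("PR1", "PR2") %in% c(fixed, covariates))
  if (uses_pr) time_poly <- FALSE
  structure(list(outcome = outcome, fixed = fixed, covariates = covariates,
                 time_poly = time_poly, human_only = human_only,
                 random = random),
            class = "lmm_spec")
}

# deviation coding (+0.5 / -0.5) for the design factors; first level +0.5
dev_code <- function(f) {
  f <- droplevels(as.factor(f))
  if (nlevels(f) != 2) return(f)
  ct <- matrix(c(0.5, -0.5), 2, 1,
               dimnames = list(levels(f), levels(f)[1]))
  stats::contrasts(f) <- ct
  f
}

#' Fit a linear mixed model with standardized coefficients
#'
#' Continuous outcome and continuous predictors are z-standardized on the
#' analysis sample; two-level factors are deviation-coded (+0.5 / -0.5,
#' first level positive: ASD, human) so main effects are averages over the
#' other factor's levels and coefficients are standardized betas. Random
#' intercepts for participant and scene; REML estimation via
#' [lmerTest::lmer()].
#'
#' @param spec An [lmm_spec()].
#' @param records Fixation-record table.
#' @return A list of class `lmm_result`: `fit` (the `lmerModLmerTest`
#'   object), `beta` (standardized fixed effects with 95% Wald CI),
#'   `ranef_variance`, `converged`, `spec`, `n_obs`, `data`.
#' @export
fit_lmm <- function(spec, records) {
  stopifnot(inherits(spec, "lmm_spec"))
  df <- as.data.frame(records)
  if (spec$human_only) df <- df[df$category == "human", , drop = FALSE]
  vars <- unique(unlist(strsplit(c(spec$fixed, spec$covariates), ":",
                                 fixed = TRUE)))
  terms <- c(spec$fixed, spec$covariates)
  if (spec$time_poly) {
    terms <- c(terms, "time1", "time2", "time3")
    vars <- c(vars, "time1", "time2", "time3")
  }
  if (spec$time_poly && !all(c("time1", "time2", "time3") %in% names(df)) &&
        "time_in_scene_ms" %in% names(df)) {
    tt <- df$time_in_scene_ms / 5000
    df$time1 <- tt; df$time2 <- tt^2; df$time3 <- tt^3
  }
  need <- unique(c(spec$outcome, vars, spec$random))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  df <- df[stats::complete.cases(df[, need, drop = FALSE]), , drop = FALSE]
  if (length(unique(df[[spec$random[1]]])) < 2 ||
        (length(spec$random) > 1 && length(unique(df[[spec$random[2]]])) < 2)) {
    stop("records degenerate: need >= 2 participants and >= 2 scenes")
  }
  # standardize
  for (v in unique(c(spec$outcome, vars))) {
    if (is.numeric(df[[v]])) {
      s <- stats::sd(df[[v]])
      df[[v]] <- if (is.finite(s) && s > 0) (df[[v]] - mean(df[[v]])) / s
      else df[[v]] - mean(df[[v]])
    } else {
      df[[v]] <- dev_code(df[[v]])
    }
  }
  rnd <- paste(sprintf("(1 | %s)", spec$random), collapse = " + ")
  fml <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(c(terms, rnd), collapse = " + ")))
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  beta <- data.frame(term = names(fe), beta = unname(fe), se = unname(se),
                     ci_lo = unname(fe - 1.96 * se),
                     ci_hi = unname(fe + 1.96 * se))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- stats::setNames(vc$vcov, sub("^Residual$", "residual", vc$grp))
  structure(list(fit = fit, beta = beta, ranef_variance = rv,
                 converged = converged, spec = spec, n_obs = nrow(df),
                 data = df,
                 logLik = as.numeric(stats::logLik(fit))),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("lmm_result: %s ~ %s  (n = %d%s)\n", x$spec$outcome,
              paste(x$spec$fixed, collapse = " + "), x$n_obs,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$beta, digits = 3)
  invisible(x)
}

#' Satterthwaite ANOVA of a fitted model
#'
#' Type-III F tests with Satterthwaite denominator degrees of freedom.
#'
#' @param result An `lmm_result`.
#' @return Data frame: `term`, `F`, `df_num`, `df_den`, `p`. A singular fit
#'   gives `NA` degrees of freedom with a warning.
#' @export
anova_satterthwaite <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  a <- suppressMessages(stats::anova(result$fit, type = 3,
                                     ddf = "Satterthwaite"))
  out <- data.frame(term = rownames(a), F = a[["F value"]],
                    df_num = a[["NumDF"]], df_den = a[["DenDF"]],
                    p = a[["Pr(>F)"]], row.names = NULL)
  if (lme4::isSingular(result$fit)) {
    warning("singular fit: Satterthwaite degrees of freedom unreliable")
    out$df_den <- NA_real_
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment within one family of analyses.
#'
#' @param pvalues Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values (elementwise >= raw).
#' @export
fdr_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Marginal means or simple slopes for an interaction
#'
#' Marginal means at the levels of `factor` (averaged over covariates at
#' their means), or, when `var` is given, per-level simple slopes of that
#' continuous moderator; pairwise contrasts (delta-M / delta-beta) with 95%
#' CIs from the fixed-effect covariance.
#'
#' @param result An `lmm_result`.
#' @param factor Factor whose levels are compared (e.g. `"group"`).
#' @param by Optional conditioning factor (e.g. `"category"`).
#' @param var Optional continuous moderator for simple slopes.
#' @return List with `means` (emmeans/emtrends grid) and `contrasts`
#'   (data frame with estimate, CI, p).
#' @export
marginal_contrasts <- function(result, factor, by = NULL, var = NULL) {
  stopifnot(inherits(result, "lmm_result"))
  fml <- if (is.null(by)) stats::as.formula(paste("~", factor)) else
    stats::as.formula(paste("~", factor, "|", by))
  gr <- suppressMessages(if (is.null(var)) {
    emmeans::emmeans(result$fit, fml, lmer.df = "satterthwaite")
  } else {
    emmeans::emtrends(result$fit, fml, var = var,
                      lmer.df = "satterthwaite")
  })
  ctr <- as.data.frame(summary(emmeans::contrast(gr, method = "pairwise"),
                               infer = TRUE))
  means <- summary(gr, infer = TRUE)
  lo <- if ("lower.CL" %in% names(ctr)) ctr$lower.CL else ctr$asymp.LCL
  hi <- if ("upper.CL" %in% names(ctr)) ctr$upper.CL else ctr$asymp.UCL
  list(means = means,
       contrasts = data.frame(
         contrast = as.character(ctr$contrast),
         by = if (!is.null(by) && by %in% names(ctr))
           as.character(ctr[[by]]) else NA_character_,
         estimate = ctr$estimate, ci_lo = lo, ci_hi = hi,
         p = ctr$p.value))
}

#' Likelihood-ratio comparison of nested models
#'
#' Both models are refitted with maximum likelihood; the statistic is twice
#' the log-likelihood difference with df equal to the parameter difference.
#'
#' @param m1,m2 `lmm_result`s fitted on the same records; `m1` nested in
#'   `m2` (its fixed terms a subset).
#' @return List: `chisq`, `df`, `p`, and the ML log-likelihoods.
#' @export
compare_models <- function(m1, m2) {
  stopifnot(inherits(m1, "lmm_result"), inherits(m2, "lmm_result"))
  t1 <- colnames(stats::model.matrix(m1$fit))
  t2 <- colnames(stats::model.matrix(m2$fit))
  if (!all(t1 %in% t2)) stop("models are not nested (fixed effects differ)")
  f1 <- stats::update(m1$fit, REML = FALSE)
  f2 <- stats::update(m2$fit, REML = FALSE)
  ll1 <- as.numeric(stats::logLik(f1)); ll2 <- as.numeric(stats::logLik(f2))
  df <- attr(stats::logLik(f2), "df") - attr(stats::logLik(f1), "df")
  chisq <- max(2 * (ll2 - ll1), 0)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(chisq = chisq, df = df, p = p, logLik_1 = ll1, logLik_2 = ll2)
}

#' Simulation-based power for a fixed effect
#'
#' Simulates outcomes from the fitted template with the target fixed effect
#' forced to `beta` (other fixed effects and the estimated random-effect
#' and residual variances kept), refits each replicate, and counts
#' Satterthwaite-significant results. The confidence interval is the exact
#' binomial interval.
#'
#' @param result Template `lmm_result` (supplies the design and variance
#'   components).
#' @param term Fixed-effect coefficient name to force.
#' @param beta Standardized effect size to plant.
#' @param iterations Number of simulation replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return List of class `power_report`: `power`, `ci` (95%), `beta`,
#'   `iterations`, `n_significant`.
#' @export
power_simulation <- function(result, term, beta, iterations = 1000,
                             alpha = 0.05, seed = 1) {
  stopifnot(inherits(result, "lmm_result"))
  if (iterations < 1) stop("iterations must be >= 1")
  fit <- result$fit
  fe <- lme4::fixef(fit)
  if (!term %in% names(fe)) stop("unknown fixed-effect term: ", term)
  fe[term] <- beta
  set.seed(seed)
  newp <- list(beta = fe, theta = lme4::getME(fit, "theta"),
               sigma = stats::sigma(fit))
  ys <- stats::simulate(fit, nsim = iterations, newparams = newp)
  hits <- 0L
  for (i in seq_len(iterations)) {
    rf <- tryCatch(suppressMessages(suppressWarnings(
      lme4::refit(fit, ys[[i]]))), error = function(e) NULL)
    if (is.null(rf)) next
    rft <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::as_lmerModLmerTest(rf))), error = function(e) NULL)
    p <- if (!is.null(rft)) {
      co <- stats::coef(summary(rft))
      co[term, "Pr(>|t|)"]
    } else {
      co <- stats::coef(summary(rf))
      2 * stats::pnorm(-abs(co[term, "t value"]))
    }
    if (is.finite(p) && p < alpha) hits <- hits + 1L
  }
  ci <- as.numeric(stats::binom.test(hits, iterations)$conf.int)
  structure(list(power = hits / iterations, ci = ci, beta = beta,
                 term = term, iterations = iterations,
                 n_significant = hits),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("power %.3f [%.3f, %.3f] for beta = %g (%d iterations)\n",
              x$power, x$ci[1], x$ci[2], x$beta, x$iterations))
  invisible(x)
}

#' Aggregate on-face fixation indicators to face-gaze proportions
#'
#' The social-attention outcome: the per-fixation on-face indicator is
#' aggregated to a proportion per participant x scene x time bin (human
#' scenes only), carrying participant covariates forward, and modelled with
#' a linear mixed model.
#'
#' @param records Fixation-record table with an `on_face` column.
#' @param bin_ms Time-bin width (default 500 ms over the 5000 ms window).
#' @return Data frame with `face_gaze` (proportion), `time1`..`time3` at
#'   the bin centre, and the participant-level covariates.
#' @export
aggregate_face_gaze <- function(records, bin_ms = 500) {
  df <- as.data.frame(records)
  df <- df[df$category == "human" & !is.na(df$on_face), , drop = FALSE]
  if (!nrow(df)) stop("no human-scene fixations with AOI data")
  df$bin <- floor(df$time_in_scene_ms / bin_ms)
  agg_keys <- c("participant", "scene", "bin")
  prop <- stats::aggregate(on_face ~ participant + scene + bin, df, mean)
  names(prop)[names(prop) == "on_face"] <- "face_gaze"
  carry <- setdiff(names(df), c("face_gaze", "on_face", "on_eyes",
                                "on_mouth", "on_body", "time_in_scene_ms",
                                "time1", "time2", "time3", "onset_ms",
                                "duration_ms", "cx_px", "cy_px"))
  first <- df[!duplicated(df[agg_keys]), carry, drop = FALSE]
  out <- merge(prop, first, by = agg_keys, sort = TRUE)
  tt <- (out$bin + 0.5) * bin_ms / 5000
  out$time_in_scene_ms <- (out$bin + 0.5) * bin_ms
  out$time1 <- tt; out$time2 <- tt^2; out$time3 <- tt^3
  out
}
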
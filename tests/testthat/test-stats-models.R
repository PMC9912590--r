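test_that("nearest-neighbour matching respects the caliper and minimizes
           distance", {
  set.seed(20)
  n <- 16
  coh <- data.frame(
    participant = sprintf("p%02d", 1:n),
    group = rep(c("ASD", "TD"), each = n / 2),
    perceptual_iq = c(rnorm(n / 2, 100, 15), rnorm(n / 2, 100, 15)),
    age = c(runif(n / 2, 8, 28), runif(n / 2, 8, 28)))
  m <- match_groups(coh, vars = c("perceptual_iq", "age"))
  expect_true(all(table(m$match_id) == 2))
  # controls are used at most once
  expect_false(any(duplicated(m$participant)))

  # brute-force oracle: replay the greedy sequence with exhaustive search
  z <- scale(as.matrix(coh[, c("perceptual_iq", "age")]))
  used <- character(0)
  for (mid in sort(unique(m$match_id))) {
    pair <- m[m$match_id == mid, ]
    case <- which(coh$participant == pair$participant[pair$group == "ASD"])
    ctrl <- which(coh$participant == pair$participant[pair$group == "TD"])
    cand <- which(coh$group == "TD" & !coh$participant %in% used)
    d2 <- colSums((t(z[cand, , drop = FALSE]) - z[case, ])^2)
    ok <- apply(abs(t(z[cand, , drop = FALSE]) - z[case, ]) <= 0.4, 2, all)
    expect_equal(ctrl, cand[ok][which.min(d2[ok])])
    used <- c(used, coh$participant[ctrl])
  }

  # identical groups: everyone matched
  twin <- coh
  twin$perceptual_iq <- rep(twin$perceptual_iq[1:(n / 2)], 2)
  twin$age <- rep(twin$age[1:(n / 2)], 2)
  expect_equal(nrow(match_groups(twin, vars = c("perceptual_iq", "age"))), n)

  # a case one SD away from every control on age stays unmatched
  far <- coh
  far$age[far$group == "ASD"] <- 60
  expect_warning(m2 <- match_groups(far, vars = c("age")), "no feasible")
  expect_equal(nrow(m2), 0)
})

test_that("covariate imputation fills cells by group-wise predictive mean
           matching", {
  set.seed(21)
  tb <- data.frame(group = rep(c("ASD", "TD"), each = 20),
                   age = runif(40, 6, 30),
                   perceptual_iq = rnorm(40, 103, 15),
                   srs_score = c(rnorm(20, 95, 10), rnorm(20, 30, 10)))
  tb$srs_score[c(3, 25)] <- NA
  out <- impute_covariates(tb, covariates = "srs_score")
  expect_false(anyNA(out$srs_score))
  expect_true(all(out$imputed_srs_score == c(seq_len(40) %in% c(3, 25))))
  # donor values come from the same group (PMM: observed values only)
  expect_true(out$srs_score[3] %in% tb$srs_score[tb$group == "ASD"])
  expect_true(out$srs_score[25] %in% tb$srs_score[tb$group == "TD"])
  # no missing: identity
  expect_identical(impute_covariates(out, covariates = "srs_score")$srs_score,
                   out$srs_score)
  tb_bad <- tb; tb_bad$srs_score <- NA
  expect_error(impute_covariates(tb_bad, covariates = "srs_score"),
               "entirely missing")
})

test_that("planted interaction is recovered on the standardized scale", {
  rec <- simulate_fixation_records(40, 20, 5,
                                   effects = list(pupil_interaction = 0.3),
                                   seed = 42)
  fit <- fit_lmm(lmm_spec("pupil_response"), rec)
  b_int <- fit$beta$beta[grepl(":", fit$beta$term)]
  expect_lt(abs(b_int - 0.3), 0.1)
  expect_true(fit$converged)
  # both random intercepts estimated
  expect_setequal(names(fit$ranef_variance),
                  c("participant", "scene", "residual"))
  expect_true(all(fit$ranef_variance > 0))

  # adding a constant to the outcome leaves all betas unchanged
  rec2 <- rec; rec2$pupil_response <- rec2$pupil_response + 5
  fit2 <- fit_lmm(lmm_spec("pupil_response"), rec2)
  expect_equal(fit2$beta$beta, fit$beta$beta, tolerance = 1e-6)

  expect_error(fit_lmm(lmm_spec("pupil_response"),
                       rec[rec$participant == "p001", ]), "degenerate")
})

test_that("Satterthwaite F equals squared t in a balanced two-group design
           and df stay within bounds", {
  rec <- simulate_fixation_records(10, 6, 4,
                                   effects = list(pupil_group = 0.4),
                                   seed = 7)
  fit <- fit_lmm(lmm_spec("pupil_response", fixed = "group",
                          time_poly = FALSE), rec)
  a <- anova_satterthwaite(fit)
  tt <- stats::coef(summary(fit$fit))["groupASD", "t value"]
  expect_equal(a$F[a$term == "group"], tt^2, tolerance = 1e-6)
  # denominator df between (participants - rank) and (N - rank)
  expect_gt(a$df_den[a$term == "group"], 2)
  expect_lt(a$df_den[a$term == "group"], fit$n_obs)
  # p monotone decreasing in F at fixed df
  expect_true(all(diff(stats::pf(c(1, 5, 20), 1, 30,
                                 lower.tail = FALSE)) < 0))
})

test_that("FDR adjustment reproduces the hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 3)), rep(0.2, 3))
  p <- c(0.001, 0.04, 0.9)
  expect_true(all(fdr_adjust(p) >= p))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("marginal contrasts recover planted cell differences", {
  rec <- simulate_fixation_records(30, 12, 5,
                                   effects = list(pupil_interaction = 0.3),
                                   seed = 8)
  fit <- fit_lmm(lmm_spec("pupil_response"), rec)
  mc <- marginal_contrasts(fit, "group", by = "category")
  est <- mc$contrasts$estimate
  names(est) <- mc$contrasts$by
  # planted interaction splits evenly over the deviation-coded cells
  expect_lt(abs(est[["human"]] - est[["non-human"]] - 0.3), 0.12)
  expect_true(all(mc$contrasts$ci_lo < est & est < mc$contrasts$ci_hi))

  # two-cell mean difference equals the coefficient in a two-group model
  fit_g <- fit_lmm(lmm_spec("pupil_response", fixed = "group",
                            time_poly = FALSE), rec)
  mg <- marginal_contrasts(fit_g, "group")
  expect_equal(mg$contrasts$estimate,
               fit_g$beta$beta[fit_g$beta$term == "groupASD"],
               tolerance = 1e-6)
})

test_that("model comparison detects a planted moderator and is zero for
           identical specs", {
  rec <- simulate_fixation_records(20, 10, 5, seed = 15)
  # route part of the outcome through a moderator
  rec$face_prop <- 0.4 - 0.3 * scale(rec$pupil_response)[, 1] * 0.1 +
    stats::rnorm(nrow(rec), 0, 0.05)
  base <- lmm_spec("face_prop", fixed = c("group", "category"),
                   time_poly = FALSE)
  with_mod <- lmm_spec("face_prop",
                       fixed = c("group", "category", "pupil_response"),
                       time_poly = FALSE)
  m1 <- fit_lmm(base, rec)
  m2 <- fit_lmm(with_mod, rec)
  cmp <- compare_models(m1, m2)
  expect_gt(cmp$chisq, stats::qchisq(0.999, cmp$df))
  expect_equal(cmp$df, 1)

  same <- compare_models(m1, fit_lmm(base, rec))
  expect_equal(same$chisq, 0, tolerance = 1e-6)
  expect_error(compare_models(m2, m1), "not nested")
})

test_that("face-gaze aggregation yields per-cell proportions on human
           scenes", {
  rec <- simulate_fixation_records(6, 4, 10,
                                   effects = list(face_group = -0.2),
                                   seed = 33)
  agg <- aggregate_face_gaze(rec, bin_ms = 1000)
  expect_true(all(agg$face_gaze >= 0 & agg$face_gaze <= 1))
  expect_true(all(agg$category == "human"))
  # planted lower face-gaze probability in the ASD group
  expect_lt(mean(agg$face_gaze[agg$group == "ASD"]),
            mean(agg$face_gaze[agg$group == "TD"]))
  # proportions recompute from the raw indicators
  cell <- agg[1, ]
  raw <- rec[rec$participant == cell$participant &
               rec$scene == cell$scene &
               floor(rec$time_in_scene_ms / 1000) == cell$bin &
               !is.na(rec$on_face), ]
  expect_equal(cell$face_gaze, mean(raw$on_face))
})

test_that("power simulation responds to the planted effect size", {
  rec <- simulate_fixation_records(10, 6, 4, seed = 3)
  fit <- fit_lmm(lmm_spec("pupil_response", fixed = "group",
                          time_poly = FALSE), rec)
  pw0 <- power_simulation(fit, "groupASD", 0, iterations = 40, seed = 2)
  pw9 <- power_simulation(fit, "groupASD", 0.9, iterations = 40, seed = 2)
  expect_lt(pw0$power, 0.3)
  expect_gt(pw9$power, pw0$power)
  expect_true(all(pw0$ci >= 0 & pw0$ci <= 1))
  expect_error(power_simulation(fit, "groupASD", 0.1, iterations = 0),
               "iterations")
  expect_error(power_simulation(fit, "nope", 0.1, 10), "unknown")
})
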
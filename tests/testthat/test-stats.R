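# Statistical battery: ANOVA, Holm-Sidak, regressions, mixed model.

make_groups <- function(n = 10, k = 3, means = rep(0, k), sds = rep(1, k)) {
  data.frame(y = unlist(lapply(seq_len(k),
                               function(i) rnorm(n, means[i], sds[i]))),
             g = rep(letters[seq_len(k)], each = n))
}

test_that("one-way ANOVA matches the hand-coded sums-of-squares oracle", {
  ## small textbook-style fixture with unequal group sizes
  d <- data.frame(y = c(6.1, 5.8, 7.2, 8.4, 9.1, 8.8, 7.9, 4.2, 5.0, 4.6,
                        5.1, 6.0),
                  g = c("a", "a", "a", "b", "b", "b", "b", "c", "c", "c",
                        "c", "c"))
  out <- one_way_anova(d, "y", "g")
  orc <- anova_oracle(d$y, d$g)
  expect_equal(out$F, orc$F, tolerance = 1e-7)
  expect_equal(out$p, orc$p, tolerance = 1e-7)
  expect_equal(out$df_between, orc$df1)
  expect_equal(out$df_within, orc$df2)

  ## three identical groups: F ~ 0, p ~ 1
  d2 <- data.frame(y = rep(c(1.2, 3.4, 2.2, 4.1), 3),
                   g = rep(c("a", "b", "c"), each = 4))
  out2 <- one_way_anova(d2, "y", "g")
  expect_lt(out2$F, 1e-20)
  expect_gt(out2$p, 0.999)

  expect_error(one_way_anova(data.frame(y = rep(1, 6),
                                        g = rep(c("a", "b"), 3)), "y", "g"),
               "degenerate")
})

test_that("Holm-Sidak adjustment reproduces the closed-form step-down", {
  expect_equal(p_adjust_holm_sidak(0.04), 0.04)
  expect_equal(p_adjust_holm_sidak(c(0.01, 0.04, 0.30)),
               c(1 - 0.99^3, 1 - 0.96^2, 0.30), tolerance = 1e-12)
  ## order-independence and monotonicity enforcement
  expect_equal(p_adjust_holm_sidak(c(0.30, 0.01, 0.04)),
               c(0.30, 1 - 0.99^3, 1 - 0.96^2), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- p_adjust_holm_sidak(p)
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("post hoc table covers all pairs and flags significance", {
  set.seed(42)
  d <- make_groups(12, 3, means = c(0, 0, 2))
  ph <- holm_sidak_posthoc(d, "y", "g")
  expect_equal(nrow(ph), 3)
  expect_equal(unique(ph$df), 33)
  expect_true(all(ph$significant == (ph$p_adj < 0.05)))
  expect_true(ph$significant[ph$group1 == "a" & ph$group2 == "c"])
})

test_that("assumption diagnostics detect unequal variance and non-normality", {
  set.seed(7)
  d <- make_groups(30, 3)
  chk <- check_parametric_assumptions(d, "y", "g")
  expect_true(all(chk$normality$pass))
  expect_true(chk$homoscedasticity$pass)

  d2 <- make_groups(30, 3, sds = c(1, 1, 10))
  expect_false(check_parametric_assumptions(d2, "y", "g")$homoscedasticity$pass)

  d3 <- data.frame(y = exp(rnorm(150, sd = 2)), g = rep(c("a", "b", "c"), 50))
  norm3 <- check_parametric_assumptions(d3, "y", "g")$normality
  expect_true(all(!norm3$pass))
})

test_that("regression on regeneration uses individual means and exact fits", {
  ## exact line y = 2x + 1 through 5 individuals
  d <- data.frame(individual_id = paste0("i", 1:5),
                  regeneration_pct = c(35, 45, 55, 65, 80))
  d$speed_bl_s <- 2 * d$regeneration_pct + 1
  ## an exact line triggers the usual "perfect fit" note from summary.lm
  fit <- suppressWarnings(regress_on_regeneration(d, "speed_bl_s"))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  orc <- ols_oracle(d$regeneration_pct, d$speed_bl_s)
  expect_equal(fit$slope, unname(orc["slope"]), tolerance = 1e-10)

  ## sham rows (no regeneration value) are excluded automatically
  d2 <- rbind(d, data.frame(individual_id = "sham1",
                            regeneration_pct = NA, speed_bl_s = 99))
  expect_equal(suppressWarnings(
    regress_on_regeneration(d2, "speed_bl_s"))$n_individuals, 5)

  expect_error(regress_on_regeneration(
    data.frame(individual_id = c("a", "b", "c"),
               regeneration_pct = c(50, 50, 50), speed_bl_s = 1:3),
    "speed_bl_s"), "identical")
})

test_that("slope CI covers zero at the nominal rate under the null", {
  set.seed(11)
  cover <- 0
  for (r in 1:200) {
    d <- data.frame(individual_id = paste0("i", 1:11),
                    regeneration_pct = runif(11, 33.3, 84.2),
                    speed_bl_s = rnorm(11, 1.1, 0.3))
    fit <- regress_on_regeneration(d, "speed_bl_s")
    se <- abs(fit$slope) / sqrt(fit$F)
    ci <- fit$slope + c(-1, 1) * qt(0.975, fit$df2) * se
    cover <- cover + (ci[1] <= 0 && ci[2] >= 0)
  }
  expect_gte(cover / 200, 0.90)
})

test_that("mixed model recovers fixed effects and degenerates gracefully", {
  set.seed(21)
  sim <- function(sd_ind = 0.1, sd_eps = 0.1) {
    d <- expand.grid(individual_id = paste0("i", 1:11), trial = 1:6)
    regen <- setNames(runif(11, 33.3, 84.2), paste0("i", 1:11))
    u <- setNames(rnorm(11, 0, sd_ind), paste0("i", 1:11))
    d$regeneration_pct <- regen[d$individual_id]
    d$frequency_hz <- rnorm(nrow(d), 3.8, 0.5)
    d$speed_bl_s <- 0.2 + 0.30 * d$frequency_hz + u[d$individual_id] +
      rnorm(nrow(d), 0, sd_eps)
    d
  }
  fit <- mixed_model_speed(sim())
  expect_equal(fit$method, "REML")
  fe <- fit$fixed
  slope <- fe$estimate[fe$term == "frequency_hz"]
  se <- fe$se[fe$term == "frequency_hz"]
  expect_lt(abs(slope - 0.30), 3 * se)

  ## zero random-effect variance: estimates match OLS closely
  d0 <- sim(sd_ind = 0)
  fit0 <- mixed_model_speed(d0)
  ols <- coef(lm(speed_bl_s ~ frequency_hz * regeneration_pct, data = d0))
  expect_equal(fit0$fixed$estimate, unname(ols), tolerance = 0.01)

  ## single trial per individual: OLS fallback with an explicit warning
  d1 <- sim()[!duplicated(sim()$individual_id), ]
  expect_warning(f1 <- mixed_model_speed(d1), "single trial")
  expect_equal(f1$method, "ols_fallback")
})

test_that("interaction p-value is invariant to centering the covariate", {
  set.seed(31)
  d <- expand.grid(individual_id = paste0("i", 1:11), trial = 1:6)
  d$regeneration_pct <- runif(11, 33.3, 84.2)[as.integer(factor(d$individual_id))]
  d$frequency_hz <- rnorm(nrow(d), 3.8, 0.5)
  d$speed_bl_s <- 0.2 + 0.3 * d$frequency_hz +
    rnorm(11, 0, 0.1)[as.integer(factor(d$individual_id))] +
    rnorm(nrow(d), 0, 0.1)
  p1 <- mixed_model_speed(d)$fixed
  d2 <- d
  d2$regeneration_pct <- d2$regeneration_pct - mean(d2$regeneration_pct)
  p2 <- mixed_model_speed(d2)$fixed
  expect_equal(p1$p[p1$term == "interaction"],
               p2$p[p2$term == "interaction"], tolerance = 1e-6)
})

test_that("stats_report assembles the full battery from a trial table", {
  co <- generate_cohort(cohort_spec(seed = 8))
  co$speed_bl_s <- co$speed_bl_s  # responses are the drawn true parameters
  trials <- performance_indices(
    cbind(co, amp_pp_bl = co$amp_pp_tail_bl))
  rep <- stats_report(trials)
  expect_s3_class(rep, "stats_report")
  expect_true(all(c("wavelength_bl", "strouhal") %in% rep$anova$response))
  ## group means ordered as generated: sham longest wavelength
  ind <- aggregate(trials$wavelength_bl,
                   by = list(treatment = trials$treatment), FUN = mean)
  expect_gt(ind$x[ind$treatment == "sham"],
            ind$x[ind$treatment == "fifth_gill"])
  expect_gt(ind$x[ind$treatment == "mid_body"],
            ind$x[ind$treatment == "fifth_gill"])
  expect_s3_class(rep$mixed_model, "mixed_model_fit")
  expect_output(print(rep), "ANOVAs")
})
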
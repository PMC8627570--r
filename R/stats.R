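## Statistical battery for trial tables: parametric-assumption diagnostics,
## one-way ANOVA with Holm-Sidak post hoc comparisons, regressions on
## percent axon regeneration, and the random-intercept mixed model of speed
## on tail-beat frequency.

#' Diagnostics for parametric-test assumptions
#'
#' Shapiro-Wilk normality per group and Levene's test for homogeneity of
#' variance. Advisory only: results are reported with pass/fail flags at
#' `alpha` but no test is switched automatically.
#'
#' @param data data.frame of trials.
#' @param response,factor column names.
#' @param alpha significance level for the pass/fail flags.
#' @return list with `normality` (data.frame: group, n, W, p, pass,
#'   underpowered) and `homoscedasticity` (data.frame: df1, df2, F, p,
#'   pass).
#' @export
check_parametric_assumptions <- function(data, response, factor,
                                         alpha = 0.05) {
  y <- data[[response]]; g <- base::factor(data[[factor]])
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 observations each")
  norm <- do.call(rbind, lapply(levels(g), function(l) {
    yi <- y[g == l]
    if (length(yi) < 3 || length(unique(yi)) < 3)
      return(data.frame(group = l, n = length(yi), W = NA_real_,
                        p = NA_real_, pass = NA, underpowered = TRUE))
    sw <- shapiro.test(yi)
    data.frame(group = l, n = length(yi), W = unname(sw$statistic),
               p = sw$p.value, pass = sw$p.value >= alpha,
               underpowered = length(yi) < 3)
  }))
  lev <- car::leveneTest(y ~ g)
  homo <- data.frame(df1 = lev$Df[1], df2 = lev$Df[2],
                     F = lev$`F value`[1], p = lev$`Pr(>F)`[1],
                     pass = lev$`Pr(>F)`[1] >= alpha)
  list(normality = norm, homoscedasticity = homo)
}

#' One-way ANOVA
#'
#' Standard between/within sums-of-squares decomposition via [stats::aov()].
#'
#' @param data data.frame of trials.
#' @param response,factor column names.
#' @return one-row data.frame: response, df_between, df_within, F, p.
#' @export
one_way_anova <- function(data, response, factor) {
  y <- data[[response]]; g <- base::factor(data[[factor]])
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2 || length(y) <= nlevels(g))
    stop("need >= 2 groups and total n greater than the number of groups")
  if (all(tapply(y, g, function(z) var(z) == 0 || length(z) < 2)))
    stop("degenerate ANOVA: zero within-group variance everywhere")
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1]]
  data.frame(response = response,
             df_between = tab$Df[1], df_within = tab$Df[2],
             F = tab$`F value`[1], p = tab$`Pr(>F)`[1])
}

#' Holm-Sidak step-down adjustment of p-values
#'
#' Sorts the m raw p-values ascending and adjusts the i-th smallest as
#' 1 - (1 - p)^(m - i + 1), enforcing step-down monotonicity (an adjusted
#' p never decreases down the sorted list) and capping at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
p_adjust_holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  adj[order(o)]
}

#' Pairwise comparisons with Holm-Sidak adjustment
#'
#' All pairwise two-sided t comparisons between factor levels using the
#' pooled within-group variance (the ANOVA mean square error, df = N - k),
#' with Holm-Sidak step-down adjustment across the m = k(k-1)/2 pairs. A
#' single pair reduces to the single-step Sidak (= raw) p.
#'
#' @param data data.frame of trials.
#' @param response,factor column names.
#' @param alpha family-wise significance level for the `significant` flag.
#' @return data.frame: group1, group2, estimate (mean difference), t, df,
#'   p_raw, p_adj, significant.
#' @export
holm_sidak_posthoc <- function(data, response, factor, alpha = 0.05) {
  y <- data[[response]]; g <- base::factor(data[[factor]])
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups")
  ns <- tapply(y, g, length)
  ms <- tapply(y, g, mean)
  ssw <- sum(tapply(y, g, function(z) sum((z - mean(z))^2)))
  dfw <- length(y) - k
  mse <- ssw / dfw
  pairs <- utils::combn(levels(g), 2)
  res <- vapply(seq_len(ncol(pairs)), function(i) {
    pr <- pairs[, i]
    d <- unname(ms[pr[1]] - ms[pr[2]])
    se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    tval <- unname(d / se)
    c(d, tval, 2 * pt(-abs(tval), dfw))
  }, numeric(3))
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = res[1, ], t = res[2, ],
                    df = dfw, p_raw = res[3, ])
  out$p_adj <- p_adjust_holm_sidak(out$p_raw)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Regression of a response on percent axon regeneration
#'
#' Ordinary least squares of per-individual mean response on per-individual
#' percent regeneration. Sham animals carry no regeneration value and are
#' excluded automatically.
#'
#' @param data trial table with individual_id and regeneration_pct columns.
#' @param response column name.
#' @return one-row data.frame: response, slope, intercept, df1, df2, F, p,
#'   r_squared, n_individuals.
#' @export
regress_on_regeneration <- function(data, response) {
  d <- data[!is.na(data$regeneration_pct) & !is.na(data[[response]]), ]
  agg <- aggregate(d[, c(response, "regeneration_pct")],
                   by = list(individual_id = d$individual_id), FUN = mean)
  if (nrow(agg) < 3)
    stop("need >= 3 individuals with a regeneration value")
  if (var(agg$regeneration_pct) == 0)
    stop("undefined slope: all regeneration values identical")
  fit <- lm(agg[[response]] ~ agg$regeneration_pct)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  data.frame(response = response,
             slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             df1 = unname(fstat[2]), df2 = unname(fstat[3]),
             F = unname(fstat[1]),
             p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
             r_squared = sm$r.squared, n_individuals = nrow(agg))
}

#' Mixed model of swimming speed on tail-beat frequency and regeneration
#'
#' Fits speed ~ frequency + regeneration + frequency:regeneration with a
#' random intercept per individual by REML (via nlme), on trials of
#' transected individuals (sham animals have no regeneration value and are
#' excluded). Fixed-effect p-values are Wald t-tests from the single REML
#' fit. When every individual contributes a single trial the random
#' intercept is unidentifiable and the model falls back to OLS, recorded in
#' the result.
#'
#' @param data trial table with individual_id, regeneration_pct columns and
#'   the speed/frequency columns below.
#' @param speed,frequency column names of the response and the tail-beat
#'   frequency covariate.
#' @return list of class `mixed_model_fit`: `fixed` (data.frame: term,
#'   estimate, se, df, t, p), `random_intercept_sd`, `residual_sd`,
#'   `method` ("REML" or "ols_fallback"), `n_individuals`, `n_trials`,
#'   `warnings`.
#' @export
mixed_model_speed <- function(data, speed = "speed_bl_s",
                              frequency = "frequency_hz") {
  d <- data[!is.na(data$regeneration_pct), ]
  d <- d[complete.cases(d[, c(speed, frequency, "individual_id")]), ]
  if (length(unique(d$individual_id)) < 3)
    stop("need trials from >= 3 individuals")
  d$.y <- d[[speed]]; d$.f <- d[[frequency]]; d$.r <- d$regeneration_pct
  trials_per <- table(d$individual_id)
  warns <- character(0)
  if (all(trials_per == 1)) {
    fit <- lm(.y ~ .f * .r, data = d)
    sm <- coef(summary(fit))
    fixed <- data.frame(term = c("(Intercept)", frequency,
                                 "regeneration_pct", "interaction"),
                        estimate = sm[, 1], se = sm[, 2],
                        df = fit$df.residual, t = sm[, 3], p = sm[, 4])
    rownames(fixed) <- NULL
    warns <- paste("single trial per individual: random intercept",
                   "unidentifiable, ordinary least squares used")
    warning(warns)
    return(structure(list(fixed = fixed, random_intercept_sd = NA_real_,
                          residual_sd = summary(fit)$sigma,
                          method = "ols_fallback",
                          n_individuals = length(trials_per),
                          n_trials = nrow(d), warnings = warns),
                     class = "mixed_model_fit"))
  }
  fit <- nlme::lme(.y ~ .f * .r, random = ~ 1 | individual_id, data = d,
                   method = "REML")
  tt <- summary(fit)$tTable
  fixed <- data.frame(term = c("(Intercept)", frequency,
                               "regeneration_pct", "interaction"),
                      estimate = tt[, "Value"], se = tt[, "Std.Error"],
                      df = tt[, "DF"], t = tt[, "t-value"],
                      p = tt[, "p-value"])
  rownames(fixed) <- NULL
  vc <- nlme::VarCorr(fit)
  structure(list(fixed = fixed,
                 random_intercept_sd = as.numeric(vc["(Intercept)", "StdDev"]),
                 residual_sd = fit$sigma,
                 method = "REML",
                 n_individuals = length(trials_per), n_trials = nrow(d),
                 warnings = warns),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("mixed model (%s), %d trials from %d individuals\n",
              x$method, x$n_trials, x$n_individuals))
  print(x$fixed, digits = 4)
  cat(sprintf("random intercept SD: %.4g; residual SD: %.4g\n",
              x$random_intercept_sd, x$residual_sd))
  invisible(x)
}

#' Full statistical report for a trial table
#'
#' Reproduces the study's battery: per response, a one-way ANOVA across
#' treatments on individual means (trials of one animal are not independent)
#' with Holm-Sidak post hoc pairwise comparisons and assumption
#' diagnostics; regressions of each response on percent regeneration
#' (individual means, transected animals only); and the mixed model of
#' speed on tail-beat frequency x regeneration with a random intercept per
#' individual, fitted on trials.
#'
#' @param trials trial table with individual_id, treatment,
#'   regeneration_pct and the response columns.
#' @param responses response column names present in `trials`.
#' @param alpha significance level.
#' @return list of class `stats_report` with elements `anova`, `posthoc`,
#'   `assumptions`, `regressions`, `mixed_model`, `alpha`,
#'   `unit_of_analysis`.
#' @export
stats_report <- function(trials,
                         responses = c("speed_bl_s", "frequency_hz",
                                       "amp_pp_bl", "wavelength_bl",
                                       "amp_ratio", "strouhal",
                                       "stride_length_bl"),
                         alpha = 0.05) {
  responses <- intersect(responses, names(trials))
  ind <- aggregate(trials[, responses, drop = FALSE],
                   by = list(individual_id = trials$individual_id,
                             treatment = trials$treatment,
                             regeneration_pct = ifelse(
                               is.na(trials$regeneration_pct), -1,
                               trials$regeneration_pct)),
                   FUN = mean)
  ind$regeneration_pct[ind$regeneration_pct < 0] <- NA
  anova_tab <- do.call(rbind, lapply(responses, function(r)
    one_way_anova(ind, r, "treatment")))
  posthoc <- setNames(lapply(responses, function(r)
    holm_sidak_posthoc(ind, r, "treatment", alpha = alpha)), responses)
  assumptions <- setNames(lapply(responses, function(r)
    tryCatch(check_parametric_assumptions(ind, r, "treatment", alpha = alpha),
             error = function(e) conditionMessage(e))), responses)
  regressions <- do.call(rbind, lapply(responses, function(r)
    tryCatch(regress_on_regeneration(trials, r),
             error = function(e) NULL)))
  mm <- tryCatch(mixed_model_speed(trials),
                 error = function(e) conditionMessage(e))
  structure(list(anova = anova_tab, posthoc = posthoc,
                 assumptions = assumptions, regressions = regressions,
                 mixed_model = mm, alpha = alpha,
                 unit_of_analysis = c(anova = "individual_means",
                                      mixed_model = "trials")),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("One-way ANOVAs across treatments (individual means):\n")
  print(x$anova, digits = 4)
  cat("\nRegressions on percent regeneration (individual means):\n")
  if (is.null(x$regressions)) cat("  (not estimable)\n") else
    print(x$regressions, digits = 4)
  cat("\n")
  if (inherits(x$mixed_model, "mixed_model_fit")) print(x$mixed_model) else
    cat("mixed model:", x$mixed_model, "\n")
  invisible(x)
}
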
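# Chick-growth modelling (random-intercept LMM, AIC selection with the
# parsimony rule) and adult body condition (residual mass index, ANOVA on
# residuals between years).

#' Fit candidate chick-growth models
#'
#' Random-intercept linear mixed models (chick identity as random effect)
#' of mass over the linear growth window, fitted by maximum likelihood
#' (not REML, since fixed effects differ between candidates and AICs must
#' be comparable). The default candidate set is all combinations of age
#' and year, including their interaction.
#'
#' The parameter count `k` used for AIC includes the fixed effects plus
#' the random-intercept and residual variances.
#'
#' @param records data.frame `chick_id`, `age` (days), `mass` (g),
#'   `year`; rows outside `age_window` are dropped.
#' @param candidates list of right-hand-side formulas for the fixed
#'   effects.
#' @param age_window inclusive age limits of the linear growth period.
#' @return list of class `growth_fits`; each element has `formula`, `k`,
#'   `log_lik`, `aic`, `fixef` (coefficient table), `ranef_var`,
#'   `resid_var`, `converged`, `fit` (the lme4 object).
#' @export
fit_growth_models <- function(records,
                              candidates = list(~1, ~age, ~year,
                                                ~age + year, ~age * year),
                              age_window = c(4, 14)) {
  records <- records[records$age >= age_window[1] &
                     records$age <= age_window[2], , drop = FALSE]
  if (length(unique(records$chick_id)) < 2 || nrow(records) < 4)
    stop("need >= 2 observations for >= 2 chicks inside the age window")
  records$year <- factor(records$year)
  fits <- lapply(candidates, function(rhs) {
    fml <- as.formula(paste("mass ~",
                            paste(deparse(rhs[[2]]), collapse = ""),
                            "+ (1 | chick_id)"))
    fit <- tryCatch(
      lme4::lmer(fml, data = records, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                   lme4::.makeCC(action = "ignore", tol = 1e-4))),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate ", deparse(rhs), " failed to fit: ",
              conditionMessage(fit))
      return(list(formula = rhs, converged = FALSE))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    ll <- as.numeric(logLik(fit))
    k <- length(lme4::fixef(fit)) + 2 # + random-intercept var + resid var
    cc <- as.data.frame(coef(summary(fit)))
    list(formula = rhs, k = k, log_lik = ll, aic = 2 * k - 2 * ll,
         fixef = cc,
         ranef_var = vc$vcov[vc$grp == "chick_id"],
         resid_var = vc$vcov[vc$grp == "Residual"],
         converged = TRUE, fit = fit)
  })
  structure(fits, class = "growth_fits")
}

#' Select the most parsimonious model by AIC
#'
#' Among converged fits within 2 AIC units of the minimum, the model with
#' the fewest parameters is retained; ties on the parameter count are
#' broken by the lower AIC. The result is invariant to candidate order.
#'
#' @param fits a `growth_fits` list (or any list of elements with `aic`,
#'   `k`, `converged`).
#' @return the selected element, with a `selection` attribute holding the
#'   AIC table (`k`, `aic`, `delta_aic` per candidate).
#' @export
select_model <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(ok)) stop("no converged fits to select from")
  aic <- vapply(ok, `[[`, 0, "aic")
  k <- vapply(ok, `[[`, 0, "k")
  delta <- aic - min(aic)
  cand <- which(delta <= 2)
  best <- cand[order(k[cand], aic[cand])][1]
  tab <- data.frame(
    model = vapply(ok, function(f) deparse(f$formula), ""),
    k = k, aic = aic, delta_aic = delta)
  sel <- ok[[best]]
  attr(sel, "selection") <- tab[order(tab$aic), ]
  sel
}

#' Adult body-condition index and between-year comparison
#'
#' Mass is regressed on wing and head-bill length by OLS, pooled across
#' years; the residual is the condition index (positive = heavier than
#' predicted for its size). Years are compared by an F-test of the
#' residual mass on year (df = 1, n - 2 for two years, matching the
#' residual-index convention); a covariate-adjusted test (year added to
#' the mass regression) is also reported.
#'
#' @param morph data.frame `mass` (g), `wing` (mm), `headbill` (mm),
#'   `year`; `bird_id` optional.
#' @return list: `index` (data.frame with `residual_mass`), `fit` (the
#'   size regression), `anova_residual` (`F`, `df1`, `df2`, `p`),
#'   `ancova_adjusted` (same, from the joint model).
#' @export
body_condition <- function(morph) {
  need <- c("mass", "wing", "headbill", "year")
  stopifnot(all(need %in% names(morph)))
  if (anyNA(morph[need])) stop("missing morphometrics are not allowed")
  if (any(table(morph$year) < 3)) stop("need >= 3 birds per year")
  if (abs(cor(morph$wing, morph$headbill)) > 0.999)
    stop("wing and head-bill are collinear")
  morph$year <- factor(morph$year)
  fit <- lm(mass ~ wing + headbill, data = morph)
  idx <- data.frame(
    bird_id = if (!is.null(morph$bird_id)) morph$bird_id else
      seq_len(nrow(morph)),
    year = morph$year,
    residual_mass = residuals(fit))
  # residual-index comparison (one-way F on the residuals)
  a1 <- anova(lm(residual_mass ~ year, data = idx))
  # covariate-adjusted comparison
  a2 <- anova(lm(mass ~ wing + headbill + year, data = morph))
  row2 <- which(rownames(a2) == "year")
  list(
    index = idx,
    fit = fit,
    anova_residual = data.frame(F = a1$`F value`[1], df1 = a1$Df[1],
                                df2 = a1$Df[2], p = a1$`Pr(>F)`[1]),
    ancova_adjusted = data.frame(F = a2$`F value`[row2], df1 = a2$Df[row2],
                                 df2 = a2$Df[nrow(a2)],
                                 p = a2$`Pr(>F)`[row2])
  )
}
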
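#' Disease-duration-adjusted mixed model for longitudinal mRSS
#'
#' Fits, by restricted maximum likelihood, a linear mixed model of mRSS on
#' disease duration, treatment arm and visit index, with a patient-level
#' random intercept:
#'
#' \deqn{mRSS_{it} = \beta_0 + \beta_1\,duration_i + \beta_2\,drug_i +
#'   \beta_3\,visit_t (+ \beta_4\,visit_t \times drug_i) + b_i +
#'   \varepsilon_{it}}
#'
#' `drug` is coded 1 for abatacept, 0 for placebo, so the drug coefficient is
#' the abatacept-vs-placebo difference. Confidence intervals and p-values use
#' a t reference with residual degrees of freedom
#' `nObs - pFixed - (nPatients - 1)` (the classic within-subject convention;
#' recorded in the fit). A boundary (zero) random-intercept variance is
#' reported as such, in which case the fixed effects coincide with ordinary
#' least squares.
#'
#' @param visits data.frame `patient_id`, `visit` (index 1..8 or any numeric
#'   time), `mrss`.
#' @param patients data.frame `patient_id`, `arm`, `disease_duration`.
#' @param interaction include the visit x drug interaction term.
#' @param level confidence level (default 0.95).
#' @return a [MixedModelFit-class].
#' @export
fitMrssMixedModel <- function(visits, patients, interaction = FALSE,
                              level = 0.95) {
  .stopIfNot(all(c("patient_id", "visit", "mrss") %in% names(visits)),
             "visits needs patient_id, visit, mrss")
  .stopIfNot(all(c("patient_id", "arm", "disease_duration") %in%
                 names(patients)),
             "patients needs patient_id, arm, disease_duration")
  df <- merge(visits, patients[, c("patient_id", "arm", "disease_duration")],
              by = "patient_id")
  df <- df[!is.na(df$mrss), , drop = FALSE]
  df$drug <- as.integer(df$arm == "abatacept")
  .stopIfNot(length(unique(df$patient_id[df$drug == 1])) >= 2 &&
             length(unique(df$patient_id[df$drug == 0])) >= 2,
             "need at least 2 patients per arm")
  nVisits <- tapply(df$visit, df$patient_id, function(v) length(unique(v)))
  .stopIfNot(all(nVisits >= 2), "need at least 2 visits per patient")

  form <- if (interaction)
    mrss ~ disease_duration + drug + visit + visit:drug + (1 | patient_id)
  else mrss ~ disease_duration + drug + visit + (1 | patient_id)
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed model did not converge: ",
                             conditionMessage(e), call. = FALSE))

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  nObs <- nrow(df)
  nPat <- length(unique(df$patient_id))
  dfResid <- nObs - length(beta) - (nPat - 1)
  .stopIfNot(dfResid >= 1, "not enough observations for residual-df inference")
  tval <- beta / se
  crit <- stats::qt(1 - (1 - level) / 2, dfResid)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), df = dfResid,
                      lower = unname(beta - crit * se),
                      upper = unname(beta + crit * se),
                      p = unname(.tPvalue(tval, dfResid)),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varInt <- vc$vcov[vc$grp == "patient_id"][1L]
  varRes <- vc$vcov[vc$grp == "Residual"][1L]
  new("MixedModelFit", coefficients = coefs,
      varIntercept = varInt, varResidual = varRes,
      dfMethod = sprintf("residual (nObs - pFixed - (nPatients - 1) = %d)",
                         as.integer(dfResid)),
      nObs = as.integer(nObs), nPatients = as.integer(nPat))
}
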
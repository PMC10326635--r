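# Prognostic evaluation of candidate genes: third-quartile expression
# dichotomization, clinical covariate categorization, Kaplan-Meier with
# log-rank, Gleason-stratified Cox regression (Breslow ties) and a
# Grambsch-Therneau proportional-hazards check. Model fitting is done by
# the survival package; this module owns the dichotomization, the category
# boundaries and the result shaping.

#' Dichotomize expression at the third quartile
#'
#' `high` iff the value strictly exceeds Q3 (linear-interpolation, type-7
#' quantile); ties with Q3 and everything below are `low`, so `high` is
#' the extreme quartile.
#'
#' @param x numeric expression values (>= 4).
#' @return factor with levels `low`, `high` (reference = low).
#' @export
dichotomize_q3 <- function(x) {
  if (length(x) < 4L) stop_("need at least 4 values to dichotomize at Q3")
  q3 <- stats::quantile(x, 0.75, type = 7, names = FALSE)
  if (all(x == x[1L]))
    warning("all expression values identical; every sample is 'low'",
            call. = FALSE)
  factor(ifelse(x > q3, "high", "low"), levels = c("low", "high"))
}

#' Categorize clinical covariates
#'
#' Age: `<=62` (reference) vs `>62`. PSA: `<=10` (reference), `10-19.9`
#' for values in \[10, 20), `>=20`. pT: low `2-4` (reference) vs high
#' `5-6` (split point configurable; pT is treated as an opaque ordinal
#' code). Gleason: `<7` , `=7`, `>7` (reference `<7`).
#'
#' @param records data.frame with numeric columns `age`, `psa`, `gleason`,
#'   `pt`.
#' @param age_cut age boundary (boundary value goes to the low class).
#' @param pt_high_min smallest pT code in the high class.
#' @return data.frame of factors `age_cat`, `psa_cat`, `pt_cat`, `gs_cat`.
#' @export
categorize_covariates <- function(records, age_cut = 62, pt_high_min = 5) {
  need <- c("age", "psa", "gleason", "pt")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_("records missing covariate(s): ", paste(miss, collapse = ", "))
  if (any(is.na(records[need])))
    stop_("missing covariate values are not supported")
  if (any(records$psa < 0) || any(records$gleason < 2) ||
      any(records$gleason > 10))
    stop_("covariate out of range (psa < 0 or gleason outside 2..10)")
  age_cat <- factor(ifelse(records$age <= age_cut,
                           paste0("<=", age_cut), paste0(">", age_cut)),
                    levels = paste0(c("<=", ">"), age_cut))
  psa_cat <- factor(ifelse(records$psa <= 10, "<=10",
                           ifelse(records$psa < 20, "10-19.9", ">=20")),
                    levels = c("<=10", "10-19.9", ">=20"))
  pt_cat <- factor(ifelse(records$pt < pt_high_min, "low", "high"),
                   levels = c("low", "high"))
  gs_cat <- factor(ifelse(records$gleason < 7, "<7",
                          ifelse(records$gleason == 7, "=7", ">7")),
                   levels = c("<7", "=7", ">7"))
  data.frame(age_cat = age_cat, psa_cat = psa_cat, pt_cat = pt_cat,
             gs_cat = gs_cat)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates per group with censoring information, plus the
#' two-group (or k-group) log-rank chi-square and p-value.
#'
#' @param time follow-up times (> 0).
#' @param event 1 = event, 0 = censored.
#' @param group group labels (>= 2 groups, each non-empty).
#' @return list with `curves` (group, time, n_risk, n_event, n_censor,
#'   surv), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop_("log-rank needs at least two non-empty groups")
  group <- droplevels(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  grp <- sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, n_censor = sm$n.censor,
                       surv = sm$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), df = df, p = p)
}

#' Gleason-stratified Cox regression
#'
#' Fits a proportional-hazards model for the expression group adjusted for
#' PSA, age and pT categories, with stratum-specific baseline hazards per
#' Gleason category (Gleason is not a model covariate). Breslow tie
#' handling; Wald confidence intervals and p-values. Covariates constant
#' across all subjects are dropped with a warning; reference levels are
#' reported with HR = 1.
#'
#' @param records data.frame with `time`, `event` and the raw covariates
#'   `age`, `psa`, `gleason`, `pt`.
#' @param expr_group factor from [dichotomize_q3()] (levels low/high).
#' @param stratify_gs stratify on the Gleason category (default TRUE); if
#'   FALSE, the model is unstratified.
#' @return list with `table` (variable, level, hr, ci_low, ci_high, p,
#'   reference), `fit` (the coxph object), and `dropped` (names of
#'   constant covariates removed).
#' @export
cox_stratified <- function(records, expr_group, stratify_gs = TRUE) {
  if (sum(records$event) < 1L) stop_("no events in data")
  cats <- categorize_covariates(records)
  dat <- data.frame(time = records$time, event = records$event,
                    expr = expr_group, cats)
  covs <- c(expr = "expr", psa = "psa_cat", age = "age_cat", pt = "pt_cat")
  use <- covs[vapply(covs, function(v) nlevels(droplevels(dat[[v]])) > 1L,
                     TRUE)]
  dropped <- setdiff(covs, use)
  if (length(dropped))
    warning("covariate(s) constant across subjects, dropped: ",
            paste(names(covs)[covs %in% dropped], collapse = ", "),
            call. = FALSE)
  if (!length(use)) stop_("no non-constant covariates to fit")
  rhs <- paste(use, collapse = " + ")
  if (stratify_gs && nlevels(droplevels(dat$gs_cat)) > 1L)
    rhs <- paste(rhs, "+ strata(gs_cat)")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (!is.null(fit$coefficients) && any(!is.finite(fit$coefficients)))
    warning("possible complete separation: non-finite coefficient",
            call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  rows <- list()
  for (v in use) {
    levs <- levels(droplevels(dat[[v]]))
    vn <- paste0(v, levs)
    label <- switch(v, expr = "expression", psa_cat = "psa",
                    age_cat = "age", pt_cat = "pt", v)
    rows[[v]] <- data.frame(
      variable = label, level = levs,
      hr = c(1, exp(co[vn[-1L], "coef"])),
      ci_low = c(NA, ci[vn[-1L], "lower .95"]),
      ci_high = c(NA, ci[vn[-1L], "upper .95"]),
      p = c(NA, co[vn[-1L], "Pr(>|z|)"]),
      reference = c(TRUE, rep(FALSE, length(levs) - 1L)),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fit = fit, dropped = names(covs)[covs %in% dropped])
}

#' Proportional-hazards check (scaled Schoenfeld residuals)
#'
#' Grambsch-Therneau test per covariate; covariates with p < `alpha` are
#' flagged as PH-violating (candidates for stratification, as done for
#' the Gleason score). With fewer than 5 events the test is unreliable and
#' NA is returned with a warning.
#'
#' @param fit a coxph fit (e.g. `cox_stratified(...)$fit`).
#' @param alpha flagging threshold, default 0.05.
#' @return data.frame covariate, chisq, p, violates.
#' @export
ph_check <- function(fit, alpha = 0.05) {
  nev <- fit$nevent
  if (!is.null(nev) && nev < 5L) {
    warning("fewer than 5 events; PH test not computed", call. = FALSE)
    return(data.frame(covariate = NA_character_, chisq = NA_real_,
                      p = NA_real_, violates = NA))
  }
  z <- survival::cox.zph(fit, transform = "km", global = FALSE)
  tab <- z$table
  data.frame(covariate = rownames(tab), chisq = tab[, "chisq"],
             p = tab[, "p"], violates = tab[, "p"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
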
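# Endpoint derivation and comparative survival machinery.
#
# Endpoint definitions: OS = time to death of any cause; PFS = time to
# progression, relapse, or death from any cause; disease-specific
# mortality = time to lymphoma-related death with death from other and
# unknown causes as competing risk. Relapsed-category patients are
# excluded from all survival sets. Administrative censoring at 60
# months (configurable). Kaplan-Meier / log-rank / Cox (Efron ties,
# Schoenfeld PH check) are delegated to the survival package; Gray's
# test and Fine-Gray regression to cmprsk; the Aalen-Johansen
# cumulative incidence estimator is own code (cross-checked against
# cmprsk in the test suite).

#' Derive analysis endpoints from patient records
#'
#' Excludes relapsed-category patients, applies administrative censoring
#' (events after the horizon become censorings at the horizon), and
#' builds the three endpoints. The competing-risk status covers deaths
#' from other and unknown causes alike.
#'
#' @param patients phenotype table (needs `disease_category`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`, `death_cause`,
#'   plus any covariates to carry through)
#' @param thresholds an `lbcl_thresholds` object
#' @return `data.frame`: patient_id, os_time/os_event,
#'   pfs_time/pfs_event, dsm_time/dsm_status (0 censored, 1 lymphoma
#'   death, 2 competing death), and all covariate columns
#' @export
derive_endpoints <- function(patients, thresholds = default_thresholds()) {
  if (any(patients$os_months < 0 | patients$pfs_months < 0))
    stop("negative follow-up time")
  if (!"disease_category" %in% names(patients))
    patients$disease_category <- categorize_disease(patients)
  keep <- patients$disease_category != "relapsed"
  p <- patients[keep, , drop = FALSE]
  horizon <- thresholds$admin_censor_months

  admin <- function(time, event) {
    over <- time > horizon
    list(time = pmin(time, horizon), event = ifelse(over, 0L, as.integer(event)))
  }
  os <- admin(p$os_months, p$os_event)
  pfs <- admin(p$pfs_months, p$pfs_event)
  dsm_status <- ifelse(os$event == 1L,
                       ifelse(p$death_cause == "lymphoma", 1L, 2L), 0L)
  out <- data.frame(patient_id = p$patient_id,
                    os_time = os$time, os_event = os$event,
                    pfs_time = pfs$time, pfs_event = pfs$event,
                    dsm_time = os$time, dsm_status = dsm_status,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(p), c(names(out), "os_months", "pfs_months",
                               "os_event", "pfs_event"))
  cbind(out, p[, extra, drop = FALSE])
}

endpoint_cols <- function(endpoint) {
  switch(endpoint,
         os = c("os_time", "os_event"),
         pfs = c("pfs_time", "pfs_event"),
         stop("endpoint must be 'os' or 'pfs' (use competing_risks() for dsm)"))
}

#' Kaplan-Meier estimate and log-rank test
#'
#' Product-limit curves (95% CI via the log(-log) transform), the
#' survival rate at a landmark time (default 60 months), and the
#' log-rank test across groups.
#'
#' @param endpoints output of [derive_endpoints()]
#' @param endpoint `"os"` or `"pfs"`
#' @param group name of a grouping column, or `NULL` for a single curve
#'   (no test)
#' @param landmark landmark time in months for the reported rate
#' @return list: `fit` (a `survfit`), `table` (group, n, events, rate at
#'   the landmark with CI), `logrank_p` (`NA` without a group)
#' @export
km_and_logrank <- function(endpoints, endpoint = c("os", "pfs"),
                           group = NULL, landmark = 60) {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_cols(endpoint)
  d <- endpoints
  d$.time <- d[[cols[1]]]; d$.event <- d[[cols[2]]]
  if (sum(d$.event) == 0) stop("no events for endpoint ", endpoint)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = d,
                             conf.type = "log-log")
    logrank_p <- NA_real_
    grp_levels <- "all"
  } else {
    g <- d[[group]]
    if (length(unique(g)) < 2)
      stop("log-rank test needs at least two groups in '", group, "'")
    d$.group <- factor(g)
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = d,
                             conf.type = "log-log")
    sd_ <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = d)
    logrank_p <- stats::pchisq(sd_$chisq, length(sd_$n) - 1, lower.tail = FALSE)
    grp_levels <- levels(d$.group)
  }
  s <- summary(fit, times = landmark, extend = TRUE)
  tab <- data.frame(
    group = grp_levels,
    n = if (is.null(group)) fit$n else as.vector(table(d$.group)),
    events = sum(d$.event),
    rate = s$surv, lower = s$lower, upper = s$upper,
    stringsAsFactors = FALSE
  )
  if (!is.null(group)) {
    ev <- tapply(d$.event, d$.group, sum)
    tab$events <- as.vector(ev)
  }
  list(fit = fit, table = tab, logrank_p = logrank_p)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; Wald confidence
#' intervals; proportional-hazards diagnostic via the scaled
#' Schoenfeld-residual trend test (flagged when its p-value is below
#' 0.05). In univariable mode each covariate is fit in its own model.
#' Non-convergence or monotone likelihood is reported as an error, never
#' silently returned.
#'
#' @param endpoints output of [derive_endpoints()]
#' @param endpoint `"os"` or `"pfs"`
#' @param covariates character vector of covariate column names
#' @param multivariable fit one joint model (`TRUE`) or one model per
#'   covariate (`FALSE`)
#' @return `data.frame`: covariate, hr, lower, upper, p, ph_p, ph_flag
#' @export
cox_fit <- function(endpoints, endpoint = c("os", "pfs"), covariates,
                    multivariable = FALSE) {
  endpoint <- match.arg(endpoint)
  cols <- endpoint_cols(endpoint)
  d <- endpoints
  d$.time <- d[[cols[1]]]; d$.event <- d[[cols[2]]]
  if (sum(d$.event) < length(covariates))
    stop("fewer events than covariates")
  for (cv in covariates) {
    if (length(unique(d[[cv]])) < 2)
      stop("covariate '", cv, "' has no contrast (single level)")
  }
  fit_one <- function(cvs) {
    f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(cvs, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(f, data = d, ties = "efron"),
      warning = function(w) {
        if (grepl("did not converge|infinite|Loglik converged", conditionMessage(w)))
          stop("Cox fit failed for ", paste(cvs, collapse = "+"), ": ",
               conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    ph_p <- if (is.null(zph)) rep(NA_real_, length(cvs)) else
      zph$table[seq_along(cvs), "p"]
    data.frame(covariate = cvs,
               hr = sm$conf.int[seq_along(cvs), "exp(coef)"],
               lower = sm$conf.int[seq_along(cvs), "lower .95"],
               upper = sm$conf.int[seq_along(cvs), "upper .95"],
               p = sm$coefficients[seq_along(cvs), "Pr(>|z|)"],
               ph_p = unname(ph_p),
               stringsAsFactors = FALSE)
  }
  out <- if (multivariable) fit_one(covariates) else
    do.call(rbind, lapply(covariates, fit_one))
  out$ph_flag <- !is.na(out$ph_p) & out$ph_p < 0.05
  rownames(out) <- NULL
  out
}

#' Aalen-Johansen cumulative incidence (own implementation)
#'
#' Nonparametric cumulative incidence per cause under competing risks:
#' at each event time, the increment of cause k is the all-cause
#' Kaplan-Meier survival just before the time multiplied by the
#' cause-specific hazard d_k/n. By construction the cause-specific
#' incidences and the all-cause survival sum to one at every time.
#'
#' @param time follow-up times
#' @param status 0 = censored, 1..K = event causes
#' @param causes cause codes to report columns for (default: those
#'   observed; pass explicitly to align tables across groups)
#' @return `data.frame`: time, surv (all-cause KM), one `cif<k>` column
#'   per cause
#' @export
cuminc_aj <- function(time, status, causes = NULL) {
  stopifnot(length(time) == length(status), all(status >= 0))
  if (is.null(causes)) causes <- sort(unique(status[status > 0]))
  if (!length(causes)) causes <- 1L
  times <- sort(unique(time[status > 0]))
  n <- length(time)
  surv_prev <- 1
  surv <- numeric(length(times))
  cif <- matrix(0, length(times), length(causes),
                dimnames = list(NULL, paste0("cif", causes)))
  cif_run <- stats::setNames(numeric(length(causes)), paste0("cif", causes))
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(time >= t)
    d_all <- sum(time == t & status > 0)
    for (j in seq_along(causes)) {
      d_k <- sum(time == t & status == causes[j])
      cif_run[j] <- cif_run[j] + surv_prev * d_k / at_risk
    }
    surv_prev <- surv_prev * (1 - d_all / at_risk)
    surv[i] <- surv_prev
    cif[i, ] <- cif_run
  }
  data.frame(time = times, surv = surv, cif, check.names = FALSE)
}

#' Competing-risks analysis of disease-specific mortality
#'
#' Cumulative incidence curves per cause (own Aalen-Johansen
#' estimator), Gray's test between groups, and the two regression
#' flavors side by side: Fine-Gray subdistribution hazards and
#' cause-specific Cox (competing deaths censored). With no
#' lymphoma-death events, incidence is identically zero and the tests
#' are skipped with a notice.
#'
#' @param endpoints output of [derive_endpoints()]
#' @param group optional grouping column name (numeric/logical/factor
#'   two-level covariate for the regressions)
#' @return list: `cif` (curves; per group when grouped), `grays_p`,
#'   `fine_gray` (hr/lower/upper/p), `cause_specific` (same columns),
#'   `note`
#' @export
competing_risks <- function(endpoints, group = NULL) {
  time <- endpoints$dsm_time
  status <- endpoints$dsm_status
  note <- NULL
  if (sum(status == 1) == 0) {
    return(list(cif = cuminc_aj(time, status), grays_p = NA_real_,
                fine_gray = NULL, cause_specific = NULL,
                note = "no primary-cause events; incidence identically 0, tests skipped"))
  }
  if (is.null(group)) {
    return(list(cif = cuminc_aj(time, status), grays_p = NA_real_,
                fine_gray = NULL, cause_specific = NULL, note = note))
  }
  g <- endpoints[[group]]
  if (length(unique(g)) < 2) stop("group '", group, "' has a single level")
  all_causes <- sort(unique(status[status > 0]))
  cif_by <- lapply(split(seq_along(time), g),
                   function(i) cuminc_aj(time[i], status[i], causes = all_causes))
  ci <- cmprsk::cuminc(ftime = time, fstatus = status, group = g, cencode = 0)
  grays_p <- ci$Tests["1", "pv"]
  x <- stats::model.matrix(~g)[, -1, drop = FALSE]
  fg <- cmprsk::crr(ftime = time, fstatus = status, cov1 = x,
                    failcode = 1, cencode = 0)
  fg_sm <- summary(fg)
  fine_gray <- data.frame(covariate = group,
                          hr = fg_sm$conf.int[1, "exp(coef)"],
                          lower = fg_sm$conf.int[1, "2.5%"],
                          upper = fg_sm$conf.int[1, "97.5%"],
                          p = fg_sm$coef[1, "p-value"],
                          stringsAsFactors = FALSE)
  dcs <- data.frame(.time = time, .event = as.integer(status == 1), g = g)
  cs_fit <- survival::coxph(survival::Surv(.time, .event) ~ g, data = dcs,
                            ties = "efron")
  cs_sm <- summary(cs_fit)
  cause_specific <- data.frame(covariate = group,
                               hr = cs_sm$conf.int[1, "exp(coef)"],
                               lower = cs_sm$conf.int[1, "lower .95"],
                               upper = cs_sm$conf.int[1, "upper .95"],
                               p = cs_sm$coefficients[1, "Pr(>|z|)"],
                               stringsAsFactors = FALSE)
  list(cif = cif_by, grays_p = unname(grays_p), fine_gray = fine_gray,
       cause_specific = cause_specific, note = note)
}
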
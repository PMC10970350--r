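# Synthetic clinical cohort: covariates, IHC percentages, rearrangement
# status, staging, LymphGen-style subtype probabilities, and observed
# follow-up generated from competing cause-specific exponential hazards.

#' Simulate a clinical cohort with known event-time truth
#'
#' Covariates (front-line rituximab-based chemotherapy, MYD88 mutation
#' status) shift the cause-specific log-hazards of lymphoma death and of
#' progression by the configured log hazard ratios; other-cause death is
#' covariate-independent. Latent times per cause are exponential; the
#' earliest of lymphoma death, other death, random censoring, and the
#' follow-up horizon is observed. Progression-free survival observes the
#' earliest of progression and death. True (uncensored) cause and time
#' are retained as truth columns.
#'
#' @param cfg a [sim_config()] object
#' @return a `data.frame` with one row per patient: identifiers,
#'   covariates, IHC marker percentages (`cd10_pct`, `bcl6_pct`,
#'   `mum1_pct`, `myc_pct`, `bcl2_pct`), rearrangement booleans
#'   (`myc_rearr`, `bcl2_rearr`, `bcl6_rearr`), staging and history
#'   fields, LymphGen subtype probability columns (`p_MCD` ... `p_A53`),
#'   observed follow-up (`os_months`, `os_event`, `pfs_months`,
#'   `pfs_event`, `death_cause`) and truth columns (`true_cause`,
#'   `true_death_months`)
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_samples = 10, seed = 3))
#' table(coh$death_cause)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, "cohort"))
  n <- cfg$n_samples
  patient_id <- sprintf("S%03d", seq_len(n))

  rituximab <- stats::runif(n) < 0.5
  myd88_mutation <- stats::runif(n) < 0.2
  covars <- cbind(rituximab = as.numeric(rituximab),
                  myd88_mutation = as.numeric(myd88_mutation))

  # staging / history: mix of localized, disseminated, unstaged, relapsed
  prior_lymphoma <- stats::runif(n) < 0.2
  prior_sll_untransformed <- prior_lymphoma & stats::runif(n) < 0.15
  ann_arbor <- sample(c("IE", "IIE", "III", "IV", "unstaged"), n, replace = TRUE,
                      prob = c(0.40, 0.20, 0.07, 0.18, 0.15))
  histology <- sample(c("DLBCL-NOS", "HGBCL"), n, replace = TRUE, prob = c(0.93, 0.07))

  # IHC percentages: bimodal mixtures around negative/positive staining
  draw_pct <- function(p_pos, hi = 70, lo = 5) {
    pos <- stats::runif(n) < p_pos
    pmin(100, pmax(0, ifelse(pos, stats::rnorm(n, hi, 15), stats::rnorm(n, lo, 5))))
  }
  cd10_pct <- draw_pct(0.4)
  bcl6_pct <- draw_pct(0.6)
  mum1_pct <- draw_pct(0.5)
  myc_pct <- draw_pct(0.45, hi = 55)
  bcl2_pct <- draw_pct(0.55, hi = 75)

  myc_rearr <- stats::runif(n) < 0.07
  bcl2_rearr <- stats::runif(n) < 0.15
  bcl6_rearr <- stats::runif(n) < 0.20

  # LymphGen-style subtype probabilities: one dominant class per patient
  classes <- c("MCD", "EZB", "ST2", "BN2", "N1", "A53")
  probs <- matrix(stats::runif(n * 6, 0, 0.15), n, 6,
                  dimnames = list(NULL, paste0("p_", classes)))
  dominant <- sample(classes, n, replace = TRUE,
                     prob = c(0.30, 0.20, 0.10, 0.10, 0.05, 0.25))
  shape <- sample(c("core", "extended", "other"), n, replace = TRUE,
                  prob = c(0.4, 0.35, 0.25))
  for (i in seq_len(n)) {
    p <- switch(shape[i],
                core = stats::runif(1, 0.91, 0.99),
                extended = stats::runif(1, 0.55, 0.89),
                other = stats::runif(1, 0, 0.45))
    probs[i, paste0("p_", dominant[i])] <- p
  }

  lp_lymph <- covars %*% ifelse(is.na(cfg$loghr_lymphoma[colnames(covars)]), 0,
                                cfg$loghr_lymphoma[colnames(covars)])
  lp_prog <- covars %*% ifelse(is.na(cfg$loghr_progression[colnames(covars)]), 0,
                               cfg$loghr_progression[colnames(covars)])
  rexp_rate <- function(rate) {
    t <- rep(Inf, n)
    pos <- rate > 0
    t[pos] <- stats::rexp(sum(pos), rate[pos])
    t
  }
  t_lymph <- rexp_rate(cfg$hazard_lymphoma * exp(drop(lp_lymph)))
  t_other <- rexp_rate(rep(cfg$hazard_other, n))
  t_prog <- rexp_rate(cfg$hazard_progression * exp(drop(lp_prog)))
  t_cens <- rexp_rate(rep(cfg$censor_rate, n))

  t_death <- pmin(t_lymph, t_other)
  true_cause <- ifelse(is.infinite(t_death), "none",
                       ifelse(t_lymph <= t_other, "lymphoma", "other"))
  horizon <- cfg$followup_horizon_months
  os_months <- pmin(t_death, t_cens, horizon)
  os_event <- as.integer(t_death <= pmin(t_cens, horizon))
  death_cause <- ifelse(os_event == 1,
                        ifelse(true_cause == "lymphoma", "lymphoma",
                               sample(c("other", "unknown"), n, replace = TRUE)),
                        "alive")
  pfs_raw <- pmin(t_prog, t_death)
  pfs_months <- pmin(pfs_raw, t_cens, horizon)
  pfs_event <- as.integer(pfs_raw <= pmin(t_cens, horizon))

  data.frame(
    patient_id = patient_id,
    rituximab = rituximab,
    myd88_mutation = myd88_mutation,
    histology = histology,
    ann_arbor = ann_arbor,
    prior_lymphoma = prior_lymphoma,
    prior_sll_untransformed = prior_sll_untransformed,
    cd10_pct = cd10_pct, bcl6_pct = bcl6_pct, mum1_pct = mum1_pct,
    myc_pct = myc_pct, bcl2_pct = bcl2_pct,
    myc_rearr = myc_rearr, bcl2_rearr = bcl2_rearr, bcl6_rearr = bcl6_rearr,
    probs,
    os_months = os_months, os_event = os_event,
    pfs_months = pfs_months, pfs_event = pfs_event,
    death_cause = death_cause,
    true_cause = true_cause,
    true_death_months = t_death,
    stringsAsFactors = FALSE
  )
}
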
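#' Configuration for the toy EHR cohort simulator
#'
#' The simulator emulates the structural challenges of inpatient EHR data:
#' static numeric and categorical features, sparsely observed temporal
#' features (30-95% missingness), skewed and discrete-grid numeric laws,
#' nonuniform categorical distributions, highly variable sequence lengths,
#' non-decreasing measurement times from cumulative positive gaps, and a
#' low-prevalence binary outcome driven by a latent severity variable that
#' also shifts selected vitals (a planted, recoverable signal).
#'
#' @param n_patients number of records.
#' @param t_max maximum sequence length.
#' @param len_mu,len_size negative-binomial parameters for sequence length
#'   (`1 + NB`, capped at `t_max`).
#' @param gap_rate exponential rate of inter-measurement gaps (per hour).
#' @param prevalence target outcome prevalence in (0, 1).
#' @param outcome_signal if `FALSE`, the outcome is independent of all
#'   features (for no-signal calibration tests).
#' @param mar_strength missingness-at-random strength: logit shift of the
#'   per-entry missingness probability by the latent severity (0 = MCAR).
#' @param static_cat_miss missingness rate applied to static categoricals.
#' @param miss_override if non-`NULL`, a single missingness rate replacing
#'   every per-feature rate (0 gives fully observed cohorts).
#' @param seed master seed.
#' @return a `toy_config` list, including the implied `ehr_schema`.
#' @export
toy_config <- function(n_patients = 2000L, t_max = 30L, len_mu = 8,
                       len_size = 2, gap_rate = 1 / 6, prevalence = 0.10,
                       outcome_signal = TRUE, mar_strength = 0,
                       static_cat_miss = 0.10, miss_override = NULL,
                       seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n_patients >= 1, t_max >= 1)
  temporal_numeric <- list(
    # name = list(law, params, missing rate)
    heart_rate    = list(law = "normal",   mean = 82, sd = 17, miss = 0.35, sev = 6),
    resp_rate     = list(law = "normal",   mean = 19, sd = 5,  miss = 0.40, sev = 1.5),
    spo2          = list(law = "revgamma", top = 100, shape = 2, scale = 1.2,
                         miss = 0.50, sev = -0.8),
    nbp_systolic  = list(law = "normal",   mean = 120, sd = 22, miss = 0.60, sev = -4),
    nbp_diastolic = list(law = "normal",   mean = 57, sd = 15, miss = 0.60, sev = -2),
    resp_pressure = list(law = "grid", values = c(35, 40, 45, 50),
                         prob = c(0.4, 0.3, 0.2, 0.1), miss = 0.55, sev = 0),
    glucose       = list(law = "lognormal", meanlog = log(130), sdlog = 0.35,
                         miss = 0.70, sev = 0.05),
    hemoglobin    = list(law = "normal",   mean = 10.5, sd = 2.0, miss = 0.75,
                         sev = 0, gender_shift = 0.9),
    creatinine    = list(law = "lognormal", meanlog = log(1.1), sdlog = 0.5,
                         miss = 0.80, sev = 0.1),
    alarm_low     = list(law = "spike_unif", spike = 90, p_spike = 0.7,
                         lo = 80, hi = 90, miss = 0.40, sev = 0)
  )
  temporal_categorical <- list(
    rhythm    = list(levels = c("sinus", "afib", "other"),
                     prob = c(0.7, 0.2, 0.1), miss = 0.50),
    vent_mode = list(levels = c("none", "cpap", "ac", "simv"),
                     prob = c(0.6, 0.2, 0.15, 0.05), miss = 0.65)
  )
  static_categorical <- list(
    marital_status = list(levels = c("married", "single", "divorced", "widowed"),
                          prob = c(0.45, 0.3, 0.15, 0.1)),
    religion  = list(levels = c("none", "catholic", "other"),
                     prob = c(0.5, 0.3, 0.2)),
    insurance = list(levels = c("medicare", "private", "medicaid"),
                     prob = c(0.55, 0.3, 0.15))
  )
  schema <- ehr_schema(
    static_numeric = c("age", "gender", "mortality"),
    static_categorical = lapply(static_categorical, `[[`, "levels"),
    temporal_numeric = names(temporal_numeric),
    temporal_categorical = lapply(temporal_categorical, `[[`, "levels"),
    time_name = "time",
    max_seq_len = t_max
  )
  structure(list(
    n_patients = as.integer(n_patients), t_max = as.integer(t_max),
    len_mu = len_mu, len_size = len_size, gap_rate = gap_rate,
    prevalence = prevalence, outcome_signal = outcome_signal,
    mar_strength = mar_strength, static_cat_miss = static_cat_miss,
    miss_override = miss_override,
    temporal_numeric = temporal_numeric,
    temporal_categorical = temporal_categorical,
    static_categorical = static_categorical,
    schema = schema, seed = as.integer(seed)
  ), class = "toy_config")
}

#' MIMIC-like preset configuration
#'
#' A ready-made [toy_config()] echoing the shape of a critical-care EHR
#' cohort at reduced width: 3 static numeric features (age, gender, a binary
#' mortality outcome with 10% prevalence), 3 static categorical features,
#' 10 temporal numeric features with 35-80% missingness (including a
#' discrete-grid and two skewed laws), 2 temporal categorical features, and
#' sequence lengths between 1 and 30.
#'
#' @param seed master seed.
#' @param n_patients cohort size (default 2000).
#' @return a `toy_config`.
#' @export
default_mimic_like <- function(seed = 1L, n_patients = 2000L) {
  toy_config(n_patients = n_patients, t_max = 30L, seed = seed)
}

draw_law <- function(law, n, sev, gender) {
  x <- switch(law$law,
    normal = stats::rnorm(n, law$mean, law$sd),
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    revgamma = law$top - stats::rgamma(n, shape = law$shape, scale = law$scale),
    grid = sample(law$values, n, replace = TRUE, prob = law$prob),
    spike_unif = ifelse(stats::runif(n) < law$p_spike, law$spike,
                        stats::runif(n, law$lo, law$hi)),
    stop("unknown law: ", law$law))
  if (!is.null(law$sev) && law$sev != 0) x <- x + law$sev * sev
  if (!is.null(law$gender_shift)) x <- x + law$gender_shift * gender
  x
}

#' Generate a toy cohort with known ground truth
#'
#' Fully reproducible per seed. The binary outcome (`mortality`) follows a
#' logistic model on age and the latent severity (which shifts heart rate
#' and other vitals), with the intercept calibrated so the expected
#' prevalence matches the configured target.
#'
#' @param config a [toy_config()].
#' @return list with `data` (`ehr_cohort`), `masks` (`ehr_masks`) and
#'   `ground_truth` (the laws, severity values and outcome coefficients).
#' @export
generate_cohort <- function(config = default_mimic_like()) {
  stopifnot(inherits(config, "toy_config"))
  sch <- config$schema
  n <- config$n_patients
  tmax <- config$t_max
  seed <- config$seed

  sev <- with_substream(seed, "severity", stats::rnorm(n))
  age <- with_substream(seed, "age",
                        clamp(stats::rnorm(n, 65, 15) + 2.5 * sev, 18, 95))
  gender <- with_substream(seed, "gender", stats::rbinom(n, 1, 0.51))

  # outcome: logit = b0 + b_sev * sev + b_age * (age - 65); b0 calibrated
  b_sev <- if (config$outcome_signal) 1.1 else 0
  b_age <- if (config$outcome_signal) 0.035 else 0
  lp <- b_sev * sev + b_age * (age - 65)
  f <- function(b0) mean(sigmoid(b0 + lp)) - config$prevalence
  b0 <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
  mortality <- with_substream(seed, "outcome",
                              stats::rbinom(n, 1, sigmoid(b0 + lp)))

  lens <- with_substream(seed, "lengths",
    pmin(1L + stats::rnbinom(n, mu = config$len_mu, size = config$len_size),
         tmax))
  tim <- matrix(NA_real_, n, tmax)
  with_substream(seed, "times", {
    for (i in seq_len(n))
      tim[i, seq_len(lens[i])] <- cumsum(stats::rexp(lens[i], config$gap_rate))
  })

  miss_draw <- function(rate, n_draw, sev_rep, name) {
    rate <- config$miss_override %||% rate
    p <- sigmoid(stats::qlogis(clamp(rate, 1e-6, 1 - 1e-6)) +
                   config$mar_strength * sev_rep)
    with_substream(seed, paste0("miss-", name), stats::runif(n_draw) < p)
  }

  tn <- array(NA_real_, c(n, tmax, length(sch$temporal_numeric)),
              dimnames = list(NULL, NULL, sch$temporal_numeric))
  sp <- matrix(0, n, tmax)
  for (i in seq_len(n)) sp[i, seq_len(lens[i])] <- 1
  present <- which(sp == 1)  # column-major cell index into n x tmax
  sev_cell <- sev[(present - 1L) %% n + 1L]
  gen_cell <- gender[(present - 1L) %% n + 1L]
  for (f_ in names(config$temporal_numeric)) {
    law <- config$temporal_numeric[[f_]]
    vals <- with_substream(seed, paste0("law-", f_),
                           draw_law(law, length(present), sev_cell, gen_cell))
    drop <- miss_draw(law$miss, length(present), sev_cell, f_)
    vals[drop] <- NA_real_
    m <- matrix(NA_real_, n, tmax)
    m[present] <- vals
    tn[, , f_] <- m
  }
  tc <- array(NA_character_, c(n, tmax, length(sch$temporal_categorical)),
              dimnames = list(NULL, NULL, names(sch$temporal_categorical)))
  for (f_ in names(config$temporal_categorical)) {
    law <- config$temporal_categorical[[f_]]
    vals <- with_substream(seed, paste0("law-", f_),
      sample(law$levels, length(present), replace = TRUE, prob = law$prob))
    drop <- miss_draw(law$miss, length(present), sev_cell, f_)
    vals[drop] <- NA_character_
    m <- matrix(NA_character_, n, tmax)
    m[present] <- vals
    tc[, , f_] <- m
  }

  scm <- matrix(NA_character_, n, length(sch$static_categorical),
                dimnames = list(NULL, names(sch$static_categorical)))
  for (f_ in names(config$static_categorical)) {
    law <- config$static_categorical[[f_]]
    vals <- with_substream(seed, paste0("law-", f_),
      sample(law$levels, n, replace = TRUE, prob = law$prob))
    drop <- miss_draw(config$static_cat_miss, n, sev, f_)
    vals[drop] <- NA_character_
    scm[, f_] <- vals
  }

  sn <- cbind(age = age, gender = as.numeric(gender),
              mortality = as.numeric(mortality))
  data <- ehr_cohort(sch, sprintf("p%05d", seq_len(n)), sn, scm, lens, tim,
                     tn, tc)
  validate_cohort(data)
  list(data = data, masks = derive_masks(data),
       ground_truth = list(
         severity = sev, outcome_coef = c(b0 = b0, b_sev = b_sev, b_age = b_age),
         temporal_numeric = config$temporal_numeric,
         temporal_categorical = config$temporal_categorical,
         static_categorical = config$static_categorical,
         config = config))
}
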
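#' @title Synthetic cohort generation
#' @description Seeded generator of waiting-list and donor tables with the
#'   marginal structure a deceased-donor kidney program sees: mostly adult
#'   recipients, a sensitised PRA tail, a minority of urgent cases, ABO
#'   frequencies near population values, and a predicted survival that
#'   decreases with age and dialysis exposure. It stands in for registry
#'   extracts so every stage of the pipeline is testable offline.
#' @name synthetic_cohort
NULL

#' Cohort generator configuration
#'
#' Defaults state the emulated world once: ABO frequencies O/A/B/AB =
#' .37/.34/.22/.07, a 0.6 point mass of unsensitised (PRA 0) patients with a
#' uniform sensitised tail, ages Normal(45, 15) truncated to \[1, 80\],
#' urgency prevalence 10%, diabetes 30%, prior transplant 8%, dialysis years
#' gamma-distributed with 15% pre-emptive (zero-dialysis) listings, and HLA
#' antigen pools of 20/30/15 labels at loci A/B/DR.
#'
#' @param n_patients,n_donors cohort sizes.
#' @param seed integer master seed; it fans out to independent per-field
#'   substreams, so adding a field does not perturb earlier draws.
#' @param urgency_prevalence,diabetes_prevalence,prior_tx_prevalence binary
#'   prevalences in \[0, 1\].
#' @param blood_type_freq named frequency vector over A, B, AB, O summing
#'   to 1.
#' @param pra_zero_mass probability of PRA exactly 0.
#' @param age_mean,age_sd,age_range truncated-normal age model.
#' @param dialysis_zero_mass,dialysis_shape,dialysis_mean dialysis-years
#'   model: point mass at 0 plus a gamma tail.
#' @param hla_pool_sizes named integer vector of antigen pool sizes for
#'   loci A, B, DR.
#' @return validated list of class `fiska_cohort_config`.
#' @export
cohort_config <- function(n_patients = 100, n_donors = 10, seed = 1,
                          urgency_prevalence = 0.1,
                          diabetes_prevalence = 0.3,
                          prior_tx_prevalence = 0.08,
                          blood_type_freq = c(A = 0.34, B = 0.22, AB = 0.07, O = 0.37),
                          pra_zero_mass = 0.6,
                          age_mean = 45, age_sd = 15, age_range = c(1, 80),
                          dialysis_zero_mass = 0.15,
                          dialysis_shape = 1.5, dialysis_mean = 3,
                          hla_pool_sizes = c(A = 20, B = 30, DR = 15)) {
  cfg <- list(n_patients = n_patients, n_donors = n_donors, seed = as.integer(seed),
              urgency_prevalence = urgency_prevalence,
              diabetes_prevalence = diabetes_prevalence,
              prior_tx_prevalence = prior_tx_prevalence,
              blood_type_freq = blood_type_freq,
              pra_zero_mass = pra_zero_mass,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              dialysis_zero_mass = dialysis_zero_mass,
              dialysis_shape = dialysis_shape, dialysis_mean = dialysis_mean,
              hla_pool_sizes = hla_pool_sizes)
  probs <- c(urgency_prevalence, diabetes_prevalence, prior_tx_prevalence,
             pra_zero_mass, dialysis_zero_mass, blood_type_freq)
  if (any(probs < 0 | probs > 1)) stop_config("probabilities must lie in [0, 1]")
  if (abs(sum(blood_type_freq) - 1) > 1e-9) {
    stop_config("blood-type frequencies must sum to 1")
  }
  if (!all(c("A", "B", "AB", "O") %in% names(blood_type_freq))) {
    stop_config("blood_type_freq must name A, B, AB, O")
  }
  if (n_patients < 1 || n_donors < 1) stop_config("cohort sizes must be >= 1")
  structure(cfg, class = "fiska_cohort_config")
}

# master seed -> independent substream seeds (kept below 2^31)
substream_seeds <- function(seed, n = 24) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

draw_hla <- function(n, pools) {
  out <- data.frame(row.names = seq_len(n))
  for (locus in c("A", "B", "DR")) {
    labels <- paste0(locus, seq_len(pools[[locus]]))
    out[[paste0("hla_", tolower(locus), "1")]] <- sample(labels, n, replace = TRUE)
    out[[paste0("hla_", tolower(locus), "2")]] <- sample(labels, n, replace = TRUE)
  }
  out
}

#' Generate a synthetic waiting list
#'
#' Deterministic for a fixed config (each field draws from its own seeded
#' substream). Predicted survival decreases with recipient age and dialysis
#' years, so score-monotonicity and rule-recovery tests have signal.
#'
#' @param config a `fiska_cohort_config`.
#' @return validated waiting-list data.frame of `n_patients` rows.
#' @export
generate_patients <- function(config) {
  if (!inherits(config, "fiska_cohort_config")) stop_config("invalid cohort config")
  n <- config$n_patients
  seeds <- substream_seeds(config$seed)
  draw <- function(k, expr) { set.seed(seeds[k]); expr }

  age <- draw(1, rtruncnorm(n, config$age_mean, config$age_sd,
                            config$age_range[1], config$age_range[2]))
  blood <- draw(2, sample(names(config$blood_type_freq), n, replace = TRUE,
                          prob = config$blood_type_freq))
  pra <- draw(3, ifelse(stats::runif(n) < config$pra_zero_mass, 0,
                        stats::runif(n, 0, 100)))
  urgent <- draw(4, as.integer(stats::runif(n) < config$urgency_prevalence))
  waiting <- draw(5, stats::rexp(n, rate = 1 / 2.5))
  hla <- draw(6, draw_hla(n, config$hla_pool_sizes))
  diabetes <- draw(7, as.integer(stats::runif(n) < config$diabetes_prevalence))
  prior_tx <- draw(8, as.integer(stats::runif(n) < config$prior_tx_prevalence))
  dialysis <- draw(9, ifelse(stats::runif(n) < config$dialysis_zero_mass, 0,
                             stats::rgamma(n, shape = config$dialysis_shape,
                                           scale = config$dialysis_mean /
                                             config$dialysis_shape)))
  # survival falls with age and dialysis exposure, noisy, clamped to [0, 20]
  survival <- draw(10, pmin(pmax(
    20 - 0.16 * age - 0.6 * dialysis + stats::rnorm(n, 0, 2.5), 0), 20))

  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    recipient_age = round(age, 1),
    blood_type = blood,
    pra = round(pra, 1),
    medical_urgency = urgent,
    waiting_time_years = round(waiting, 3),
    stringsAsFactors = FALSE
  )
  patients <- cbind(patients, hla)
  patients$predicted_survival <- round(survival, 2)
  patients$diabetes <- diabetes
  patients$prior_solid_organ_transplant <- prior_tx
  patients$dialysis_years <- round(dialysis, 2)
  validate_waitlist(patients)
  patients
}

#' Generate synthetic donor records
#'
#' @param config a `fiska_cohort_config`.
#' @return data.frame of `n_donors` validated donor rows with a fixed
#'   allocation date.
#' @export
generate_donors <- function(config) {
  if (!inherits(config, "fiska_cohort_config")) stop_config("invalid cohort config")
  n <- config$n_donors
  seeds <- substream_seeds(config$seed)
  draw <- function(k, expr) { set.seed(seeds[k]); expr }
  age <- draw(11, rtruncnorm(n, config$age_mean, config$age_sd, 5, 75))
  blood <- draw(12, sample(names(config$blood_type_freq), n, replace = TRUE,
                           prob = config$blood_type_freq))
  hla <- draw(13, draw_hla(n, config$hla_pool_sizes))
  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(n)),
    donor_age = round(age, 1),
    blood_type = blood,
    stringsAsFactors = FALSE
  )
  donors <- cbind(donors, hla)
  donors$allocation_date <- "2017-12-01"
  for (i in seq_len(n)) validate_donor(donors[i, , drop = FALSE])
  donors
}

#' Generate a score-labelled synthetic training table
#'
#' Generates a cohort, pairs every patient with a seeded random
#' ABO-compatible donor (patients with no compatible donor are dropped with
#' a message), and delegates to [build_training_table()].
#'
#' @param config a `fiska_cohort_config`.
#' @param weights a `fiska_weights` table; default packaged table.
#' @param thresholds optional explicit class cut points (default quintiles).
#' @return a `fiska_training_table`.
#' @export
generate_labeled_dataset <- function(config, weights = load_weight_table(),
                                     thresholds = NULL) {
  patients <- generate_patients(config)
  donors <- generate_donors(config)
  seeds <- substream_seeds(config$seed)
  set.seed(seeds[14])
  assignment <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    ok <- abo_relation(donors$blood_type, patients$blood_type[i]) != "incompatible"
    if (!any(ok)) {
      assignment[i] <- NA_character_
      next
    }
    cand <- donors$donor_id[ok]
    assignment[i] <- cand[sample.int(length(cand), 1)]
  }
  if (anyNA(assignment)) {
    message(sprintf("dropping %d patient(s) with no ABO-compatible donor",
                    sum(is.na(assignment))))
    patients <- patients[!is.na(assignment), , drop = FALSE]
    assignment <- assignment[!is.na(assignment)]
  }
  build_training_table(patients, donors, assignment, weights, thresholds)
}

#' Write a synthetic cohort to CSV files
#'
#' @param config a `fiska_cohort_config`.
#' @param dir output directory (created if needed).
#' @return paths of the written waitlist and donor CSVs, invisibly.
#' @export
write_cohort_csv <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wl <- file.path(dir, "waitlist.csv")
  dn <- file.path(dir, "donors.csv")
  utils::write.csv(generate_patients(config), wl, row.names = FALSE)
  utils::write.csv(generate_donors(config), dn, row.names = FALSE)
  invisible(c(waitlist = wl, donors = dn))
}
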
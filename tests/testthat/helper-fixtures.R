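# Builders for small in-code fixtures shared across test files.

make_patient <- function(id = "P1", age = 40, blood = "A", pra = 0,
                         urgent = 0, waiting = 1,
                         hla = c("A1", "A2", "B1", "B2", "DR1", "DR2"),
                         survival = 8, diabetes = 0, prior_tx = 0,
                         dialysis = 1) {
  data.frame(
    patient_id = id, recipient_age = age, blood_type = blood, pra = pra,
    medical_urgency = urgent, waiting_time_years = waiting,
    hla_a1 = hla[1], hla_a2 = hla[2], hla_b1 = hla[3], hla_b2 = hla[4],
    hla_dr1 = hla[5], hla_dr2 = hla[6],
    predicted_survival = survival, diabetes = diabetes,
    prior_solid_organ_transplant = prior_tx, dialysis_years = dialysis,
    stringsAsFactors = FALSE
  )
}

make_donor <- function(id = "D1", age = 40, blood = "A",
                       hla = c("A1", "A2", "B1", "B2", "DR1", "DR2")) {
  data.frame(
    donor_id = id, donor_age = age, blood_type = blood,
    hla_a1 = hla[1], hla_a2 = hla[2], hla_b1 = hla[3], hla_b2 = hla[4],
    hla_dr1 = hla[5], hla_dr2 = hla[6],
    allocation_date = "2017-12-01", stringsAsFactors = FALSE
  )
}

# random waitlist sharing the donor's antigen pool so mismatch counts vary
random_waitlist <- function(n, seed = 1) {
  set.seed(seed)
  pool <- function(locus, k) paste0(locus, sample.int(k, 2 * n, replace = TRUE))
  a <- pool("A", 5); b <- pool("B", 5); dr <- pool("DR", 5)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    recipient_age = round(runif(n, 1, 80), 1),
    blood_type = sample(c("A", "B", "AB", "O"), n, replace = TRUE),
    pra = round(ifelse(runif(n) < 0.5, 0, runif(n, 0, 100)), 1),
    medical_urgency = rbinom(n, 1, 0.15),
    waiting_time_years = round(rexp(n, 1 / 2), 3),
    hla_a1 = a[1:n], hla_a2 = a[(n + 1):(2 * n)],
    hla_b1 = b[1:n], hla_b2 = b[(n + 1):(2 * n)],
    hla_dr1 = dr[1:n], hla_dr2 = dr[(n + 1):(2 * n)],
    predicted_survival = round(runif(n, 0, 20), 2),
    diabetes = rbinom(n, 1, 0.3),
    prior_solid_organ_transplant = rbinom(n, 1, 0.1),
    dialysis_years = round(rexp(n, 1 / 3), 2),
    stringsAsFactors = FALSE
  )
}

# one-rule system over a single crisp input, for engine unit tests
tiny_rulebase <- function(consequent = "very_high") {
  urg <- linguistic_variable("medical_urgency", c(0, 1), list(
    fuzzy_set("not_urgent", 0, 0, 0, 0.5),
    fuzzy_set("urgent", 0.5, 1, 1, 1)))
  out <- load_variables()$output
  rule_base(list(fuzzy_rule(c(medical_urgency = "urgent"), consequent)),
            list(medical_urgency = urg), out)
}

# independent grid oracle for the centroid of one fuzzy set
set_centroid_oracle <- function(set, lo = 0, hi = 100, n = 200001) {
  g <- seq(lo, hi, length.out = n)
  mu <- trapezoid_membership(g, set)
  sum(mu * g) / sum(mu)
}
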
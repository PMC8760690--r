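#' @title Ranking policies and allocation outcome metrics
#' @description The three ranking policies compared in this package (fuzzy
#'   inference, point scoring, ABO/urgency filtering), the two
#'   ranking-agreement metrics (overlapping rate over the top six,
#'   two-first-choices over the top two), the raw EPTS post-transplant
#'   survival score, and per-method outcome summaries.
#' @name allocation_metrics
NULL

ranked_list <- function(entries, method) {
  stopifnot(is.data.frame(entries))
  entries$rank <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  structure(entries[, c("rank", "patient_id", "score"), drop = FALSE],
            method = method,
            recipients = utils::head(entries$patient_id, 2),
            reserves = entries$patient_id[seq_len(nrow(entries)) > 2 & seq_len(nrow(entries)) <= 6],
            class = c("fiska_ranked_list", "data.frame"))
}

#' @export
print.fiska_ranked_list <- function(x, ...) {
  cat(sprintf("Ranked list (%s): %d candidate(s)\n", attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

compatible_subset <- function(patients, donor) {
  inputs <- allocation_inputs(patients, donor)
  excluded <- inputs$patient_id[inputs$abo_label == "incompatible"]
  if (length(excluded) > 0) {
    message(sprintf("excluding %d ABO-incompatible patient(s)", length(excluded)))
  }
  list(inputs = inputs[inputs$abo_label != "incompatible", , drop = FALSE],
       excluded = excluded)
}

order_by_score <- function(inputs, score) {
  # descending score; ties to the longer-waiting patient, then patient_id
  inputs[order(-score, -inputs$waiting_time, inputs$patient_id), , drop = FALSE]
}

#' Rank a waiting list with the fuzzy inference system
#'
#' Excludes ABO-incompatible patients, evaluates the Mamdani system on each
#' remaining patient's donor-relative inputs, and sorts by descending crisp
#' score (ties: longer waiting time, then patient id).
#'
#' @param patients validated waiting list.
#' @param donor validated donor record.
#' @param rulebase a `fiska_rulebase`.
#' @param resolution output sample step for defuzzification.
#' @param fallback if `TRUE`, patients covered by no rule receive the
#'   centroid of the `medium` output set instead of raising an error.
#' @return a `fiska_ranked_list` over all compatible patients.
#' @export
rank_fiska <- function(patients, donor, rulebase, resolution = 0.1,
                       fallback = FALSE) {
  cs <- compatible_subset(patients, donor)
  inputs <- cs$inputs
  if (nrow(inputs) == 0) {
    warning("no ABO-compatible patients for this donor")
    return(ranked_list(data.frame(patient_id = character(0), score = numeric(0)),
                       "fiska"))
  }
  scores <- infer_batch(inputs, rulebase, resolution)
  if (anyNA(scores)) {
    if (!fallback) {
      stop_domain("no rule fired for patient(s): %s",
                  paste(inputs$patient_id[is.na(scores)], collapse = ", "))
    }
    med <- rulebase$output$sets[[3]]
    grid <- output_grid(rulebase$output, resolution)
    scores[is.na(scores)] <- defuzzify_cog(trapezoid_membership(grid, med), grid)
  }
  ord <- order_by_score(inputs, scores)
  ord$score <- scores[match(ord$patient_id, inputs$patient_id)]
  out <- ranked_list(ord[, c("patient_id", "score")], "fiska")
  attr(out, "excluded") <- cs$excluded
  out
}

#' Rank a waiting list with the point scoring system
#'
#' As [rank_fiska()] but ordered by [total_score()].
#'
#' @inheritParams rank_fiska
#' @param weights a `fiska_weights` table.
#' @return a `fiska_ranked_list`.
#' @export
rank_scoring <- function(patients, donor, weights) {
  cs <- compatible_subset(patients, donor)
  inputs <- cs$inputs
  if (nrow(inputs) == 0) {
    warning("no ABO-compatible patients for this donor")
    return(ranked_list(data.frame(patient_id = character(0), score = numeric(0)),
                       "scoring"))
  }
  scores <- score_from_inputs(inputs, weights)
  ord <- order_by_score(inputs, scores)
  ord$score <- scores[match(ord$patient_id, inputs$patient_id)]
  out <- ranked_list(ord[, c("patient_id", "score")], "scoring")
  attr(out, "excluded") <- cs$excluded
  out
}

#' Rank a waiting list with the filtering policy
#'
#' The conventional filtering baseline: keep ABO-compatible patients, put
#' urgent patients ahead of non-urgent ones, sort each tier by waiting time
#' descending (ties by patient id), and truncate to the top six (two
#' recipients plus four reserves).
#'
#' @inheritParams rank_fiska
#' @param urgent_only if `TRUE`, non-urgent patients are dropped rather
#'   than ranked after the urgent tier.
#' @return a `fiska_ranked_list` of at most six entries.
#' @export
rank_filtering <- function(patients, donor, urgent_only = FALSE) {
  cs <- compatible_subset(patients, donor)
  inputs <- cs$inputs
  if (urgent_only) inputs <- inputs[inputs$medical_urgency == 1, , drop = FALSE]
  ord <- inputs[order(-inputs$medical_urgency, -inputs$waiting_time,
                      inputs$patient_id), , drop = FALSE]
  ord <- utils::head(ord, 6)
  ord$score <- rep(NA_real_, nrow(ord))
  out <- ranked_list(ord[, c("patient_id", "score")], "filtering")
  attr(out, "excluded") <- cs$excluded
  out
}

top_ids <- function(x, k) {
  if (inherits(x, "fiska_ranked_list")) x <- x$patient_id
  utils::head(as.character(x), k)
}

# truncate (not round) to one decimal, guarding binary representation
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

#' Overlapping rate between two top-k selections
#'
#' `100 * |set(a) intersect set(b)| / k`, truncated (not rounded) to one
#' decimal so that 4 shared candidates out of 6 report as 66.6.
#'
#' @param list_a,list_b ranked lists or id vectors; their first `k` entries
#'   are compared as unordered sets.
#' @param k selection size (default 6, the two recipients plus four
#'   reserves of the filtering policy).
#' @return percent in \[0, 100\].
#' @examples
#' overlapping_rate(c(8, 7, 15, 5, 24, 2), c(8, 7, 15, 14, 1, 24))  # 66.6
#' @export
overlapping_rate <- function(list_a, list_b, k = 6) {
  a <- top_ids(list_a, k)
  b <- top_ids(list_b, k)
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop_input("duplicate ids within a ranked list")
  }
  trunc1(100 * length(intersect(a, b)) / k)
}

#' Two-first-choices agreement between two rankings
#'
#' Donors give two kidneys, so the two top-ranked candidates matter most:
#' 100 if both models pick the same (unordered) top two, 50 if they share
#' one, 0 if none.
#'
#' @param list_a,list_b ranked lists or id vectors with at least 2 entries.
#' @return 0, 50 or 100.
#' @export
two_first_choices <- function(list_a, list_b) {
  a <- top_ids(list_a, 2)
  b <- top_ids(list_b, 2)
  if (length(a) < 2 || length(b) < 2) stop_input("each list needs at least 2 entries")
  100 * length(intersect(a, b)) / 2
}

#' Raw EPTS (Estimated Post Transplant Survival) score
#'
#' The UNOS raw EPTS linear predictor from candidate age, diabetes status,
#' prior solid-organ transplant and years on dialysis (natural logarithm;
#' `dialysis_years == 0` enters as a binary indicator). Lower raw EPTS
#' predicts longer post-transplant survival. The raw score is reported
#' without the UNOS percentile mapping, which is not packaged.
#'
#' @param age years.
#' @param diabetes,prior_transplant binary 0/1 indicators.
#' @param dialysis_years years on dialysis (>= 0).
#' @return raw EPTS score (unitless), vectorised.
#' @examples
#' epts_raw(25, 0, 0, 0)  # 0.130
#' @export
epts_raw <- function(age, diabetes, prior_transplant, dialysis_years) {
  if (any(dialysis_years < 0)) stop_input("dialysis_years must be non-negative")
  if (!all(diabetes %in% c(0, 1)) || !all(prior_transplant %in% c(0, 1))) {
    stop_input("diabetes and prior_transplant must be 0/1")
  }
  over25 <- pmax(age - 25, 0)
  logdial <- log(dialysis_years + 1)
  nodial <- as.numeric(dialysis_years == 0)
  0.047 * over25 -
    0.015 * diabetes * over25 +
    0.398 * prior_transplant -
    0.237 * diabetes * prior_transplant +
    0.315 * logdial -
    0.099 * diabetes * logdial +
    0.130 * nodial -
    0.348 * diabetes * nodial +
    1.262 * diabetes
}

#' Summarise allocation outcomes per method
#'
#' For each ranking method's chosen recipients, reports the mean raw EPTS
#' score, the mean waiting time at allocation, the mean donor-recipient age
#' difference, and the count/fraction of ABO-identical allocations.
#'
#' @param allocations data.frame with columns `method`, `donor_id`,
#'   `patient_id` — the chosen recipients per method per donor.
#' @param patients validated waiting list covering all chosen recipients.
#' @param donors data.frame of validated donors covering all `donor_id`s.
#' @return data.frame of class `fiska_outcome_report`, one row per method.
#' @export
compare_outcomes <- function(allocations, patients, donors) {
  need <- c("method", "donor_id", "patient_id")
  if (!all(need %in% names(allocations))) {
    stop_input("allocations needs columns: %s", paste(need, collapse = ", "))
  }
  if (!all(allocations$patient_id %in% patients$patient_id)) {
    stop_input("allocations reference unknown patient id(s)")
  }
  rows <- lapply(split(allocations, allocations$method), function(al) {
    p <- patients[match(al$patient_id, patients$patient_id), , drop = FALSE]
    d <- donors[match(al$donor_id, donors$donor_id), , drop = FALSE]
    epts <- epts_raw(p$recipient_age, p$diabetes, p$prior_solid_organ_transplant,
                     p$dialysis_years)
    waits <- vapply(seq_len(nrow(p)), function(i) {
      patient_waiting_years(p[i, , drop = FALSE], d[i, , drop = FALSE])
    }, 0)
    rel <- abo_relation(d$blood_type, p$blood_type)
    data.frame(
      method = al$method[1],
      n_allocations = nrow(al),
      mean_epts_raw = mean(epts),
      mean_waiting_years = mean(waits),
      mean_age_difference = mean(age_difference(d$donor_age, p$recipient_age)),
      identical_abo_count = sum(rel == "identical"),
      identical_abo_fraction = mean(rel == "identical"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fiska_outcome_report", "data.frame")
  out
}
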
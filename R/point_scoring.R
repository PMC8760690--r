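#' @title Point scoring system
#' @description The conventional baseline: each allocation factor earns a
#'   weighted number of points and the kidney goes to the highest total.
#'   The weights come from an IF-AHP elicitation organised as criterion
#'   (equity/utility) x sub-criterion x attribute bin; the packaged default
#'   table ships in `inst/extdata/table2_weights.json`.
#' @name point_scoring
NULL

PRIORITY_LEVELS <- c("very_low", "low", "medium", "high", "very_high")

#' Load and validate an allocation weight table
#'
#' Validates three invariants: the two criterion weights sum to 1 (+- 0.01);
#' every sub-criterion or bin relative-weight group sums to 1 (+- 0.02,
#' printed weights are rounded to 2 decimals); and each global weight equals
#' the product of its criterion, sub-criterion and bin relative weights
#' within +- 2e-4 (the published 4-mismatch cell is off by 9e-5, hence the
#' tolerance).
#'
#' @param path JSON weight config; `NULL` loads the packaged default.
#' @return a `fiska_weights` object: the parsed table plus a flat `global`
#'   list used by [total_score()].
#' @export
load_weight_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_weights.json", package = "fiska")
  }
  if (!file.exists(path)) stop_config("weight config not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crit <- cfg$criteria
  if (is.null(crit$equity) || is.null(crit$utility)) {
    stop_config("weight config must define equity and utility criteria")
  }

  failures <- character(0)
  check_sum <- function(vals, what, tol) {
    if (abs(sum(vals) - 1) > tol) {
      failures <<- c(failures, sprintf("%s weights sum to %.4f, not 1", what, sum(vals)))
    }
  }
  check_sum(vapply(crit, function(cr) cr$weight, 0), "criterion", 0.01)

  global <- list()
  for (cname in names(crit)) {
    cr <- crit[[cname]]
    check_sum(vapply(cr$sub, function(s) s$weight, 0),
              paste(cname, "sub-criterion"), 0.02)
    for (sname in names(cr$sub)) {
      sub <- cr$sub[[sname]]
      if (!is.null(sub$bins)) {
        check_sum(vapply(sub$bins, function(b) b$weight, 0),
                  paste(sname, "bin"), 0.02)
        g <- vapply(sub$bins, function(b) b$global, 0)
        expect <- cr$weight * sub$weight * vapply(sub$bins, function(b) b$weight, 0)
        bad <- abs(g - expect) > 2e-4
        if (any(bad)) {
          failures <- c(failures, sprintf(
            "%s/%s global weight inconsistent with product", sname,
            names(sub$bins)[bad]))
        }
        global[[sname]] <- g
      } else {
        if (is.null(sub$global)) {
          failures <- c(failures, sprintf("%s: missing global weight", sname))
          next
        }
        if (abs(sub$global - cr$weight * sub$weight) > 2e-4) {
          failures <- c(failures, sprintf("%s global weight inconsistent with product", sname))
        }
        global[[sname]] <- sub$global
      }
    }
  }
  needed <- c("medical_urgency", "pra_gt80", "recipient_age",
              "waiting_time_per_year", "hla_mismatch", "blood_type_matching",
              "age_difference", "predicted_survival")
  miss <- setdiff(needed, names(global))
  if (length(miss) > 0) failures <- c(failures, paste("missing group(s):", paste(miss, collapse = ", ")))
  if (length(failures) > 0) {
    stop_config("invalid weight table:\n  - %s", paste(failures, collapse = "\n  - "))
  }
  structure(list(criteria = crit, global = global, source = path),
            class = "fiska_weights")
}

#' @export
print.fiska_weights <- function(x, ...) {
  cat("Allocation weight table (", length(unlist(x$global)), " global weights)\n", sep = "")
  for (g in names(x$global)) {
    v <- x$global[[g]]
    cat(sprintf("  %-22s %s\n", g, paste(format(v, digits = 4), collapse = " ")))
  }
  invisible(x)
}

# Bin lookups. Boundaries follow the published bin labels:
# recipient age <11 / 11-15 / 15-18 (pediatric only, <18); age difference
# <5 / 5-15 / >15; predicted survival <1 / 1-5 / >5; HLA mismatches 0..5
# with a count of 6 collapsed onto the 5-mismatch bin.
age_bin_weight <- function(age, g) {
  w <- numeric(length(age))
  w[age < 11] <- g[["lt11"]]
  w[age >= 11 & age < 15] <- g[["b11_15"]]
  w[age >= 15 & age < 18] <- g[["b15_18"]]
  w  # adults (>= 18) earn 0 from this factor
}

hla_bin_weight <- function(mm, g) {
  idx <- pmin(pmax(as.integer(round(mm)), 0L), 5L) + 1L
  unname(vapply(g, identity, 0))[idx]
}

agediff_bin_weight <- function(d, g) {
  ifelse(d < 5, g[["lt5"]], ifelse(d <= 15, g[["b5_15"]], g[["gt15"]]))
}

survival_bin_weight <- function(s, g) {
  ifelse(s < 1, g[["lt1"]], ifelse(s <= 5, g[["b1_5"]], g[["gt5"]]))
}

# Score vector from a precomputed allocation_inputs() frame (no ABO check).
score_from_inputs <- function(inputs, weights) {
  g <- weights$global
  pts <- inputs$medical_urgency * g$medical_urgency +
    (inputs$pra > 80) * g$pra_gt80 +
    age_bin_weight(inputs$recipient_age, g$recipient_age) +
    inputs$waiting_time * g$waiting_time_per_year +
    hla_bin_weight(inputs$hla_mismatch, g$hla_mismatch) +
    ifelse(inputs$abo == 1, g$blood_type_matching[["identical"]],
           g$blood_type_matching[["compatible"]]) +
    agediff_bin_weight(inputs$age_difference, g$age_difference) +
    survival_bin_weight(inputs$predicted_survival, g$predicted_survival)
  100 * pts
}

#' Total allocation score for patients against a donor
#'
#' Sums the applicable global weights (on a 0-100 point scale): urgency if
#' urgent; PRA weight if PRA > 80; pediatric age-bin weight if the recipient
#' is under 18; waiting-time weight per year, pro rata and uncapped; and
#' exactly one weight from each of the HLA-mismatch, ABO, age-difference and
#' predicted-survival bin groups. ABO-incompatible pairs are a domain error:
#' they must be filtered out before scoring.
#'
#' @param patients validated waiting list (or a one-row data.frame).
#' @param donor validated donor record.
#' @param weights a `fiska_weights` table from [load_weight_table()].
#' @return numeric score vector (points, 0-100 scale).
#' @examples
#' \dontrun{
#' w <- load_weight_table()
#' total_score(patients, donor, w)
#' }
#' @export
total_score <- function(patients, donor, weights) {
  inputs <- allocation_inputs(patients, donor)
  if (any(inputs$abo_label == "incompatible")) {
    stop_domain("ABO-incompatible patient(s) must be pre-filtered: %s",
                paste(inputs$patient_id[inputs$abo_label == "incompatible"],
                      collapse = ", "))
  }
  score_from_inputs(inputs, weights)
}

#' Quantize scores into the five priority classes
#'
#' Maps scores onto the ordered classes very_low < low < medium < high <
#' very_high. With explicit `thresholds` (4 strictly ascending cut points)
#' the class intervals are closed on the left and open on the right, so a
#' score equal to a cut point takes the higher class. Without thresholds the
#' 20/40/60/80% quantiles of `scores` are used (the published expert cut
#' points are unavailable). If all scores coincide in quantile mode, every
#' score lands in the same (highest) class.
#'
#' @param scores numeric scores.
#' @param thresholds optional 4 ascending cut points; `NULL` for quantile mode.
#' @return ordered factor of priority classes, plus a `thresholds` attribute.
#' @export
quantize_priority <- function(scores, thresholds = NULL) {
  if (is.null(thresholds)) {
    if (length(scores) < 5) stop_config("quantile mode needs at least 5 scores")
    thresholds <- unname(stats::quantile(scores, c(0.2, 0.4, 0.6, 0.8), type = 7))
  } else {
    if (length(thresholds) != 4 || is.unsorted(thresholds, strictly = TRUE)) {
      stop_config("thresholds must be 4 strictly ascending cut points")
    }
  }
  idx <- findInterval(scores, thresholds) + 1L  # [t_i, t_{i+1}) bins
  structure(factor(PRIORITY_LEVELS[idx], levels = PRIORITY_LEVELS, ordered = TRUE),
            thresholds = thresholds)
}
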
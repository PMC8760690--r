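#' @title Clinical compatibility primitives
#' @description Blood-group relations, HLA mismatch counting, waiting time
#'   and donor-recipient age difference: the crisp quantities every
#'   allocation policy in this package consumes.
#' @name core_model
NULL

ABO_TYPES <- c("A", "B", "AB", "O")

# standard ABO donation rules: donor type -> recipient types it can donate to
ABO_CAN_DONATE <- list(
  O  = c("O", "A", "B", "AB"),
  A  = c("A", "AB"),
  B  = c("B", "AB"),
  AB = "AB"
)

HLA_COLS <- c("hla_a1", "hla_a2", "hla_b1", "hla_b2", "hla_dr1", "hla_dr2")

#' ABO blood-group relation between a donor and a recipient
#'
#' Classifies each donor/recipient pair as `identical` (equal types),
#' `compatible` (donation permitted under standard ABO rules: O donates to
#' all, A to A/AB, B to B/AB, AB to AB) or `incompatible`. Identical
#' transplants are prioritised over merely compatible ones by the scoring
#' weights, so the distinction is kept.
#'
#' @param donor_bt,recipient_bt character vectors of blood types in
#'   `A`, `B`, `AB`, `O` (recycled to a common length).
#' @return character vector with values `"identical"`, `"compatible"`,
#'   `"incompatible"`.
#' @examples
#' abo_relation("O", "A")   # compatible
#' abo_relation("AB", "O")  # incompatible
#' @export
abo_relation <- function(donor_bt, recipient_bt) {
  donor_bt <- as.character(donor_bt)
  recipient_bt <- as.character(recipient_bt)
  bad <- setdiff(unique(c(donor_bt, recipient_bt)), ABO_TYPES)
  if (length(bad) > 0) {
    stop_input("unknown blood-type label(s): %s", paste(bad, collapse = ", "))
  }
  n <- max(length(donor_bt), length(recipient_bt))
  donor_bt <- rep_len(donor_bt, n)
  recipient_bt <- rep_len(recipient_bt, n)
  out <- rep("incompatible", n)
  ok <- mapply(function(d, r) r %in% ABO_CAN_DONATE[[d]], donor_bt, recipient_bt)
  out[ok] <- "compatible"
  out[donor_bt == recipient_bt] <- "identical"
  out
}

#' Construct an HLA typing
#'
#' A typing carries exactly two antigen labels at each of the loci A, B and
#' DR; a homozygous locus repeats its antigen.
#'
#' @param a,b,dr length-2 character vectors of antigen labels.
#' @return a named list of loci with class `fiska_hla`.
#' @export
hla_typing <- function(a, b, dr) {
  typing <- list(A = as.character(a), B = as.character(b), DR = as.character(dr))
  for (locus in names(typing)) {
    if (length(typing[[locus]]) != 2 || anyNA(typing[[locus]])) {
      stop_input("HLA locus %s must carry exactly 2 antigen labels", locus)
    }
  }
  structure(typing, class = "fiska_hla")
}

#' Count HLA mismatches between a donor and a recipient
#'
#' For each of the loci A, B and DR, every *distinct* donor antigen absent
#' from the recipient's pair at that locus counts one mismatch (the standard
#' antigen-level transplant convention); the total ranges 0-6.
#'
#' @param donor_hla,recipient_hla typings from [hla_typing()].
#' @return integer in 0..6.
#' @export
count_hla_mismatches <- function(donor_hla, recipient_hla) {
  for (typing in list(donor_hla, recipient_hla)) {
    if (!all(c("A", "B", "DR") %in% names(typing))) {
      stop_input("HLA typing is missing a locus (need A, B, DR)")
    }
  }
  total <- 0L
  for (locus in c("A", "B", "DR")) {
    d <- unique(as.character(donor_hla[[locus]]))
    r <- as.character(recipient_hla[[locus]])
    total <- total + sum(!(d %in% r))
  }
  as.integer(total)
}

# Vectorised mismatch count for one donor row against a waitlist data.frame;
# used by the scoring/training/ranking hot paths.
hla_mismatches_vec <- function(donor, patients) {
  miss <- setdiff(HLA_COLS, c(names(donor), names(patients)))
  if (length(miss) > 0) {
    stop_input("missing HLA columns: %s", paste(miss, collapse = ", "))
  }
  total <- integer(nrow(patients))
  for (locus in c("a", "b", "dr")) {
    d1 <- as.character(donor[[paste0("hla_", locus, "1")]])
    d2 <- as.character(donor[[paste0("hla_", locus, "2")]])
    r1 <- as.character(patients[[paste0("hla_", locus, "1")]])
    r2 <- as.character(patients[[paste0("hla_", locus, "2")]])
    mm <- as.integer(d1 != r1 & d1 != r2)
    if (d2 != d1) mm <- mm + as.integer(d2 != r1 & d2 != r2)
    total <- total + mm
  }
  total
}

#' Waiting time in years between listing and allocation
#'
#' Day count divided by 365.25 (ISO-8601 dates, fractional years pro rata).
#'
#' @param listing_date,allocation_date dates or ISO-8601 strings.
#' @return numeric years, vectorised.
#' @export
waiting_time_years <- function(listing_date, allocation_date) {
  listing_date <- as.Date(listing_date)
  allocation_date <- as.Date(allocation_date)
  days <- as.numeric(allocation_date - listing_date)
  if (any(is.na(days))) stop_input("unparseable date in waiting-time computation")
  if (any(days < 0)) stop_input("listing_date is after allocation_date")
  days / 365.25
}

#' Absolute donor-recipient age difference in years
#' @param donor_age,recipient_age numeric ages (years, non-negative).
#' @export
age_difference <- function(donor_age, recipient_age) {
  if (any(donor_age < 0) || any(recipient_age < 0)) {
    stop_input("ages must be non-negative")
  }
  abs(donor_age - recipient_age)
}

WAITLIST_REQUIRED <- c("patient_id", "recipient_age", "blood_type", "pra",
                       "medical_urgency", HLA_COLS, "predicted_survival",
                       "diabetes", "prior_solid_organ_transplant",
                       "dialysis_years")

#' Validate a waiting-list table
#'
#' Checks the waiting-list schema and the record invariants: PRA in
#' \[0,100\], age in \[0,120\], binary flags in \{0,1\}, two antigens per
#' locus, and either a `waiting_time_years` column or a `listing_date`
#' column from which waiting time can be computed.
#'
#' @param patients a data.frame in the waiting-list schema.
#' @return the validated data.frame (invisibly classed `fiska_waitlist`).
#' @export
validate_waitlist <- function(patients) {
  miss <- setdiff(WAITLIST_REQUIRED, names(patients))
  if (length(miss) > 0) {
    stop_input("waiting list is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!("waiting_time_years" %in% names(patients)) &&
      !("listing_date" %in% names(patients))) {
    stop_input("waiting list needs either waiting_time_years or listing_date")
  }
  if (anyDuplicated(patients$patient_id)) stop_input("duplicate patient_id values")
  chk <- function(ok, what) if (!all(ok)) stop_input("invariant violated: %s", what)
  chk(patients$pra >= 0 & patients$pra <= 100, "pra in [0,100]")
  chk(patients$recipient_age >= 0 & patients$recipient_age <= 120,
      "recipient_age in [0,120]")
  for (f in c("medical_urgency", "diabetes", "prior_solid_organ_transplant")) {
    chk(patients[[f]] %in% c(0, 1), paste(f, "in {0,1}"))
  }
  chk(patients$blood_type %in% ABO_TYPES, "blood_type in {A,B,AB,O}")
  chk(patients$predicted_survival >= 0, "predicted_survival >= 0")
  chk(patients$dialysis_years >= 0, "dialysis_years >= 0")
  if ("waiting_time_years" %in% names(patients)) {
    chk(patients$waiting_time_years >= 0, "waiting_time_years >= 0")
  }
  for (col in HLA_COLS) chk(!is.na(patients[[col]]), paste(col, "present"))
  class(patients) <- unique(c("fiska_waitlist", class(patients)))
  invisible(patients)
}

DONOR_REQUIRED <- c("donor_id", "donor_age", "blood_type", HLA_COLS)

#' Validate a donor record
#' @param donor a one-row data.frame (or list) in the donor schema.
#' @return the validated donor, invisibly.
#' @export
validate_donor <- function(donor) {
  miss <- setdiff(DONOR_REQUIRED, names(donor))
  if (length(miss) > 0) {
    stop_input("donor record is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (!donor$blood_type[1] %in% ABO_TYPES) {
    stop_input("unknown donor blood type: %s", donor$blood_type[1])
  }
  if (donor$donor_age[1] < 0) stop_input("donor_age must be non-negative")
  if ("allocation_date" %in% names(donor) && is.na(as.Date(donor$allocation_date[1]))) {
    stop_input("allocation_date is not a valid date")
  }
  invisible(donor)
}

#' Read a waiting-list CSV
#' @param path CSV file in the waiting-list schema.
#' @return validated waiting-list data.frame.
#' @export
read_waitlist <- function(path) {
  if (!file.exists(path)) stop_config("waiting-list file not found: %s", path)
  validate_waitlist(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a donor CSV (first row is used)
#' @param path CSV file in the donor schema.
#' @return validated one-row donor data.frame.
#' @export
read_donor <- function(path) {
  if (!file.exists(path)) stop_config("donor file not found: %s", path)
  donor <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(donor) < 1) stop_input("donor file is empty")
  validate_donor(donor[1, , drop = FALSE])
}

# Waiting time for every patient relative to one donor: prefer the explicit
# waiting_time_years column, fall back to date arithmetic.
patient_waiting_years <- function(patients, donor) {
  if ("waiting_time_years" %in% names(patients) &&
      !all(is.na(patients$waiting_time_years))) {
    return(as.numeric(patients$waiting_time_years))
  }
  if (!("allocation_date" %in% names(donor))) {
    stop_input("donor has no allocation_date and waiting_time_years is absent")
  }
  waiting_time_years(patients$listing_date, donor$allocation_date[1])
}

#' Donor-relative crisp allocation inputs for a waiting list
#'
#' Computes, for every patient against one donor, the eight crisp values all
#' ranking policies share: medical urgency, PRA, recipient age, waiting time,
#' HLA mismatch count, ABO relation indicator (1 identical / 0 compatible),
#' donor-recipient age difference and predicted survival. ABO-incompatible
#' patients are *kept* here with `abo = NA`; callers filter them.
#'
#' @param patients validated waiting list.
#' @param donor validated donor record.
#' @return data.frame with columns `patient_id`, the eight inputs, and
#'   `abo_label`.
#' @export
allocation_inputs <- function(patients, donor) {
  rel <- abo_relation(donor$blood_type[1], patients$blood_type)
  data.frame(
    patient_id = patients$patient_id,
    medical_urgency = as.numeric(patients$medical_urgency),
    pra = as.numeric(patients$pra),
    recipient_age = as.numeric(patients$recipient_age),
    waiting_time = patient_waiting_years(patients, donor),
    hla_mismatch = as.numeric(hla_mismatches_vec(donor, patients)),
    abo = ifelse(rel == "identical", 1, ifelse(rel == "compatible", 0, NA)),
    age_difference = age_difference(donor$donor_age[1], patients$recipient_age),
    predicted_survival = as.numeric(patients$predicted_survival),
    abo_label = rel,
    stringsAsFactors = FALSE
  )
}
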
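w <- load_weight_table()

# top-six lists published for the 30-patient comparison study
published_lists <- list(
  filtering = c(8, 15, 1, 12, 4, 2),
  scoring = c(8, 15, 12, 5, 1, 7),
  fiska = c(8, 7, 15, 5, 24, 2),
  expert = c(8, 7, 15, 14, 1, 24)
)

test_that("the published top-six comparison row is reproduced exactly", {
  with(published_lists, {
    expect_identical(overlapping_rate(fiska, expert), 66.6)
    expect_identical(two_first_choices(fiska, expert), 100)
    expect_identical(overlapping_rate(scoring, expert), 66.6)
    expect_identical(two_first_choices(scoring, expert), 50)
    expect_identical(overlapping_rate(filtering, expert), 50)
    expect_identical(two_first_choices(filtering, expert), 50)
  })
})

test_that("agreement metrics are symmetric, bounded, and truncate", {
  expect_identical(overlapping_rate(1:6, 1:6), 100)
  expect_identical(overlapping_rate(1:6, 7:12), 0)
  expect_identical(two_first_choices(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_error(overlapping_rate(c(1, 1, 2, 3, 4, 5), 1:6),
               class = "fiska_input_error")
  set.seed(12)
  for (i in 1:20) {
    a <- sample(100, 6); b <- sample(100, 6)
    expect_identical(overlapping_rate(a, b), overlapping_rate(b, a))
    expect_identical(two_first_choices(a, b), two_first_choices(b, a))
    expect_true(overlapping_rate(a, b) >= 0 && overlapping_rate(a, b) <= 100)
  }
  # 1/6 and 5/6 shares exercise the truncate-to-one-decimal rule
  expect_identical(overlapping_rate(1:6, c(1, 7, 8, 9, 10, 11)), 16.6)
  expect_identical(overlapping_rate(1:6, c(1:5, 11)), 83.3)
})

test_that("raw EPTS evaluates its linear predictor exactly", {
  expect_equal(epts_raw(25, 0, 0, 0), 0.130, tolerance = 1e-9)
  # frozen hand evaluation: 0.047*15 - 0.015*15 + 0.398 - 0.237 +
  #   (0.315 - 0.099)*ln(3) + 1.262
  expect_equal(epts_raw(40, 1, 1, 2), 2.1403002543523117, tolerance = 1e-6)
  expect_equal(epts_raw(20, 0, 0, 0), 0.130, tolerance = 1e-9)  # MAX clamp
  expect_error(epts_raw(40, 0, 0, -1), class = "fiska_input_error")
  expect_error(epts_raw(40, 2, 0, 1), class = "fiska_input_error")
  # non-decreasing in age above 25 for non-diabetics
  ages <- seq(25, 80, by = 0.5)
  expect_true(all(diff(epts_raw(ages, 0, 0, 1)) >= 0))
})

test_that("scoring ranks dominate and order the worked examples", {
  donor <- make_donor(blood = "A", age = 10)
  donor2_hla <- c("A9", "A10", "B9", "B10", "DR9", "DR2")
  wl <- rbind(
    make_patient("good", age = 8, blood = "A", pra = 90, urgent = 1,
                 waiting = 1, survival = 8),
    make_patient("poor", age = 40, blood = "AB", pra = 50, waiting = 0,
                 survival = 0.5, hla = donor2_hla))
  rl <- rank_scoring(wl, donor, w)
  expect_identical(rl$patient_id, c("good", "poor"))
  expect_equal(rl$score, c(73.32, 4.34), tolerance = 1e-8)
  expect_identical(attr(rl, "recipients"), c("good", "poor"))

  empty <- suppressWarnings(rank_scoring(make_patient(blood = "O"),
                                         make_donor(blood = "A"), w))
  expect_identical(nrow(empty), 0L)
})

test_that("filtering ranks urgency tiers by waiting time and truncates", {
  wl <- do.call(rbind, lapply(1:8, function(i) {
    make_patient(sprintf("P%d", i), blood = "A", urgent = as.integer(i <= 3),
                 waiting = i)
  }))
  rl <- rank_filtering(wl, make_donor(blood = "A"))
  expect_identical(nrow(rl), 6L)
  expect_identical(rl$patient_id[1:3], c("P3", "P2", "P1"))  # urgent, by waiting
  expect_identical(rl$patient_id[4:6], c("P8", "P7", "P6"))

  none <- suppressMessages(rank_filtering(make_patient(blood = "O"),
                                          make_donor(blood = "A")))
  expect_identical(nrow(none), 0L)
})

test_that("fiska ranking breaks ties by waiting time and ignores row order", {
  rb <- tiny_rulebase("very_high")
  wl <- rbind(make_patient("P1", urgent = 1, waiting = 1, blood = "A"),
              make_patient("P2", urgent = 1, waiting = 3, blood = "A"),
              make_patient("P3", urgent = 1, waiting = 2, blood = "A"))
  rl <- rank_fiska(wl, make_donor(blood = "A"), rb)
  expect_identical(rl$patient_id, c("P2", "P3", "P1"))

  rl_perm <- rank_fiska(wl[c(3, 1, 2), ], make_donor(blood = "A"), rb)
  expect_identical(rl_perm$patient_id, rl$patient_id)

  single <- rank_fiska(wl[1, ], make_donor(blood = "A"), rb)
  expect_identical(single$rank, 1L)

  # uncovered inputs raise unless the fallback rule is enabled
  calm <- make_patient("P9", urgent = 0, blood = "A")
  expect_error(rank_fiska(calm, make_donor(blood = "A"), rb),
               class = "fiska_domain_error")
  fb <- rank_fiska(calm, make_donor(blood = "A"), rb, fallback = TRUE)
  expect_equal(fb$score, 50, tolerance = 1e-2)  # centroid of 'medium'
})

test_that("all ranking policies exclude exactly the same patients", {
  wl <- validate_waitlist(random_waitlist(40, seed = 21))
  donor <- make_donor(blood = "A")
  rb <- tiny_rulebase("high")
  suppressMessages({
    ex_f <- attr(rank_fiska(wl, donor, rb, fallback = TRUE), "excluded")
    ex_s <- attr(rank_scoring(wl, donor, w), "excluded")
    ex_t <- attr(rank_filtering(wl, donor), "excluded")
  })
  expect_identical(ex_f, ex_s)
  expect_identical(ex_s, ex_t)
  incompat <- wl$patient_id[abo_relation(donor$blood_type, wl$blood_type) ==
                              "incompatible"]
  expect_identical(sort(ex_f), sort(incompat))
})

test_that("outcome report summarises recipients per method", {
  wl <- rbind(make_patient("P1", age = 30, blood = "A", waiting = 2,
                           diabetes = 1, dialysis = 3),
              make_patient("P2", age = 55, blood = "O", waiting = 1))
  donor <- make_donor(blood = "A", age = 40)
  alloc <- data.frame(method = c("fiska", "fiska", "scoring", "scoring"),
                      donor_id = "D1",
                      patient_id = c("P1", "P2", "P1", "P2"))
  outr <- compare_outcomes(alloc, wl, donor)
  expect_identical(nrow(outr), 2L)
  # both methods chose the same recipients -> identical summaries
  expect_equal(outr$mean_epts_raw[1], outr$mean_epts_raw[2])
  expect_equal(outr$mean_waiting_years, rep(1.5, 2))
  expect_equal(outr$mean_age_difference, rep(12.5, 2))
  expect_equal(outr$identical_abo_fraction, rep(0.5, 2))
  expect_equal(outr$mean_epts_raw[1],
               mean(epts_raw(c(30, 55), c(1, 0), c(0, 0), c(3, 1))))

  single <- compare_outcomes(alloc[1, ], wl, donor)
  expect_equal(single$mean_epts_raw, epts_raw(30, 1, 0, 3))
  expect_error(compare_outcomes(data.frame(method = "m", donor_id = "D1",
                                           patient_id = "nope"), wl, donor),
               class = "fiska_input_error")
})
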
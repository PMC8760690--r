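vars <- load_variables()

test_that("trapezoid membership follows the piecewise definition", {
  s <- fuzzy_set("demo", 0, 20, 40, 60)
  expect_equal(trapezoid_membership(c(10, 30, 70), s), c(0.5, 1, 0))
  expect_equal(trapezoid_membership(c(-5, 0, 20, 40, 50, 60), s),
               c(0, 0, 1, 1, 0.5, 0))
  # triangular special case b = c
  tri <- fuzzy_set("tri", 0, 50, 50, 100)
  expect_equal(trapezoid_membership(c(25, 50, 75), tri), c(0.5, 1, 0.5))
  # degenerate edges behave as crisp boundaries (plateau value at the point)
  crisp <- fuzzy_set("crisp", 0, 0, 0, 0.5)
  expect_equal(trapezoid_membership(c(0, 0.25, 0.5), crisp), c(1, 0.5, 0))
  expect_error(fuzzy_set("bad", 3, 2, 4, 5), class = "fiska_config_error")
})

test_that("membership is continuous and bounded on a dense grid", {
  for (v in vars$inputs) {
    g <- seq(v$universe[1], v$universe[2], length.out = 2000)
    for (s in v$sets) {
      mu <- trapezoid_membership(g, s)
      expect_true(all(mu >= 0 & mu <= 1))
      if (s$a < s$b || s$c < s$d) {  # crisp singletons aside, no jumps
        expect_lt(max(abs(diff(mu))), 0.05)
      }
    }
  }
})

test_that("fuzzify returns per-set degrees, clamps, and hits crossovers", {
  hla <- vars$inputs$hla_mismatch
  expect_equal(unname(fuzzify(2, hla)["mm2"]), 1)
  # symmetric crossover between adjacent +-1 triangles
  expect_equal(unname(fuzzify(1.5, hla)[c("mm1", "mm2")]), c(0.5, 0.5))
  # values outside the universe clamp to the edge
  expect_equal(fuzzify(-3, hla), fuzzify(0, hla))
  expect_equal(fuzzify(8, hla), fuzzify(5, hla))
  expect_equal(sum(fuzzify(0.3, vars$inputs$medical_urgency) > 0), 1)
})

test_that("firing strength is the min over antecedent degrees", {
  fz <- list(a = c(s1 = 0.3, s2 = 0.7), b = c(x = 0.7), c = c(y = 1.0))
  r <- fuzzy_rule(c(a = "s1", b = "x", c = "y"), "medium")
  expect_equal(firing_strength(r, fz), 0.3)
  r0 <- fuzzy_rule(c(a = "s2", b = "x"), "medium")
  fz0 <- list(a = c(s1 = 0.3, s2 = 0), b = c(x = 0.7))
  expect_equal(firing_strength(r0, fz0), 0)
  expect_equal(firing_strength(fuzzy_rule(list(), "medium"), fz), 1)
  expect_error(firing_strength(fuzzy_rule(c(a = "nope"), "medium"), fz),
               class = "fiska_config_error")
})

test_that("aggregation is the max of clipped consequents", {
  rb <- rule_base(
    list(fuzzy_rule(c(medical_urgency = "urgent"), "medium"),
         fuzzy_rule(c(medical_urgency = "not_urgent"), "medium")),
    vars$inputs["medical_urgency"], vars$output)
  agg <- aggregate_rules(rb, c(0.3, 0.6), resolution = 0.5)
  med <- vars$output$sets[[3]]
  expect_equal(agg$mu, pmin(0.6, trapezoid_membership(agg$grid, med)))

  agg1 <- aggregate_rules(rb, c(1, 0), resolution = 0.5)
  expect_equal(agg1$mu, trapezoid_membership(agg1$grid, med))

  agg0 <- aggregate_rules(rb, c(0, 0), resolution = 0.5)
  expect_true(all(agg0$mu == 0))
  expect_error(defuzzify_cog(agg0$mu, agg0$grid), class = "fiska_domain_error")
})

test_that("COG reproduces analytic centroids of simple shapes", {
  g <- seq(0, 100, by = 0.1)
  rect <- as.numeric(g >= 10 & g <= 30)
  expect_equal(defuzzify_cog(rect, g), 20, tolerance = 1e-2)

  tri <- pmax(0, 1 - abs(g - 50) / 50)
  expect_equal(defuzzify_cog(tri, g), 50, tolerance = 1e-2)

  two <- as.numeric((g >= 10 & g <= 30) | (g >= 70 & g <= 90))
  expect_equal(defuzzify_cog(two, g), 50, tolerance = 1e-2)
})

test_that("COG of a clipped symmetric set is its axis at any height", {
  s <- fuzzy_set("sym", 20, 35, 45, 60)  # axis of symmetry at 40
  g <- seq(0, 100, by = 0.05)
  for (h in c(0.1, 0.35, 0.8, 1)) {
    expect_equal(defuzzify_cog(pmin(h, trapezoid_membership(g, s)), g), 40,
                 tolerance = 1e-2)
  }
})

test_that("discrete COG converges under grid refinement", {
  s <- fuzzy_set("skew", 0, 10, 20, 80)
  for (step in c(0.1, 0.05)) {
    g1 <- seq(0, 100, by = step)
    g2 <- seq(0, 100, by = step / 2)
    c1 <- defuzzify_cog(trapezoid_membership(g1, s), g1)
    c2 <- defuzzify_cog(trapezoid_membership(g2, s), g2)
    expect_lt(abs(c1 - c2), 1e-2)
  }
})

test_that("infer composes the pipeline deterministically", {
  rb <- tiny_rulebase("very_high")
  out_set <- vars$output$sets[[5]]
  expected <- set_centroid_oracle(out_set)  # centroid of very_high itself
  expect_equal(infer(c(medical_urgency = 1), rb), expected, tolerance = 1e-2)
  expect_equal(infer(c(medical_urgency = 1), rb),
               infer(c(medical_urgency = 1), rb))
  # doubling the resolution barely moves the output
  expect_lt(abs(infer(c(medical_urgency = 1), rb, resolution = 0.1) -
                  infer(c(medical_urgency = 1), rb, resolution = 0.05)), 0.1)
  expect_error(infer(c(medical_urgency = 0), rb), class = "fiska_domain_error")
})

test_that("rule_grid_size multiplies per-variable set counts", {
  expect_identical(rule_grid_size(vars$inputs), 13824)
  v1 <- linguistic_variable("x", c(0, 1), list(fuzzy_set("only", 0, 0, 1, 1)))
  expect_identical(rule_grid_size(list(v1)), 1)
  v2 <- linguistic_variable("y", c(0, 1), list(fuzzy_set("lo", 0, 0, 0, 1),
                                               fuzzy_set("hi", 0, 1, 1, 1)))
  expect_identical(rule_grid_size(list(v2, v2)), 4)
})

test_that("rule-base JSON serialisation round-trips loss-free", {
  rb <- rule_base(
    list(fuzzy_rule(c(pra = "high", medical_urgency = "urgent"), "very_high", n = 12),
         fuzzy_rule(c(waiting_time = "long"), "medium", n = 30),
         fuzzy_rule(list(), "low")),
    vars$inputs, vars$output)
  path <- tempfile(fileext = ".json")
  write_rulebase(rb, path)
  back <- read_rulebase(path)
  expect_equal(back, rb)
  # and a second round-trip is byte-identical
  path2 <- tempfile(fileext = ".json")
  write_rulebase(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("variable definitions round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  write_variables(vars, path)
  expect_equal(load_variables(path), vars)
})

test_that("score_to_class assigns the maximal-membership class", {
  out <- vars$output
  expect_identical(as.character(score_to_class(c(10, 30, 50, 70, 90), out)),
                   c("very_low", "low", "medium", "high", "very_high"))
  expect_true(is.na(score_to_class(NA_real_, out)))
})
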
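test_that("rule firing obeys the strict threshold and the weight cap", {
  expect_identical(fire_rule(1.0, weight = 0.5), 0.5)
  expect_identical(fire_rule(0.19, weight = 0.5, threshold = 0.2), NA_real_)
  expect_identical(fire_rule(0.2, weight = 0.5, threshold = 0.2), NA_real_)
  expect_identical(fire_rule(0.6, weight = 0.5), 0.3)
  # min combiner also caps at the weight
  expect_identical(fire_rule(0.6, weight = 0.5, combiner = "min"), 0.5)
  expect_identical(fire_rule(0.3, weight = 0.5, combiner = "min"), 0.3)
  expect_error(fire_rule(1.2), "\\[0, 1\\]")
})

test_that("missing trait values emit low-potential conclusions for every linked index", {
  rb <- rulebook(list(explicit_trait("t1", "F"),
                      explicit_trait("t2", c("F", "B"))),
                 rbind(identity_rules("t1", "F"),
                       identity_rules("t2", c("F", "B"))))
  pen1 <- missing_penalty("t1", rb)
  expect_equal(pen1$index, "F")
  expect_equal(pen1$conclusion, "low")
  expect_equal(pen1$membership, 0.5)  # weight 0.5 x penalty degree 1
  pen2 <- missing_penalty("t2", rb)
  expect_setequal(pen2$index, c("F", "B"))
  expect_true(all(pen2$conclusion == "low"))
  expect_error(missing_penalty("nope", rb), "not declared")
})

test_that("MYCIN accumulation matches its closed form and hand-checked values", {
  expect_identical(accumulate_membership(numeric(0)), 0)
  expect_identical(accumulate_membership(0.37), 0.37)
  expect_equal(accumulate_membership(c(0.5, 0.5)), 0.75)
  expect_equal(accumulate_membership(c(0.5, 0.5, 0.5)), 0.875)
  expect_error(accumulate_membership(c(0.5, 1.3)), "\\[0, 1\\]")
})

test_that("accumulation equals the sequential recurrence and is permutation-invariant", {
  set.seed(11)
  for (rep in 1:200) {
    ms <- runif(sample(1:8, 1))
    expect_equal(accumulate_membership(ms), accumulate_oracle(ms),
                 tolerance = 1e-12)
    expect_equal(accumulate_membership(ms),
                 accumulate_membership(sample(ms)), tolerance = 1e-12)
    # monotone: appending a conclusion never decreases the result
    expect_gte(accumulate_membership(c(ms, runif(1))) + 1e-15,
               accumulate_membership(ms))
    # strictly below 1 when every input is below 1
    expect_lt(accumulate_membership(pmin(ms, 0.999)), 1)
  }
})

test_that("k equal-weight conclusions are bounded by 1 - 0.5^k", {
  for (k in 1:6)
    expect_lte(accumulate_membership(rep(0.5, k)), 1 - 0.5^k + 1e-15)
})

test_that("inference fires, accumulates, and is invariant to trait column order", {
  rb <- make_tiny_rulebook(2, "F")
  rb <- fit_families(rb, data.frame())  # explicit breakpoints only
  # 90 sits on the very_high plateau of the standard geometry
  rec <- data.frame(species_id = "s1", taxon = "finfish", t1 = 90, t2 = 10)
  acc <- infer_species(rec, rb)
  expect_equal(unname(acc$F$degrees["very_high"]), 0.5)
  expect_equal(unname(acc$F$degrees["low"]), 0.5)
  expect_equal(sum(acc$C$degrees), 0)  # no C rules
  rec_rev <- rec[, c("t2", "t1", "taxon", "species_id")]
  expect_identical(infer_species(rec_rev, rb), acc)
})

test_that("a species with all traits missing accumulates the closed-form low penalty", {
  for (n in 2:4) {
    rb <- make_tiny_rulebook(n, "F")
    rec <- as.data.frame(c(list(species_id = "s", taxon = "algae"),
                           setNames(rep(NA_real_, n), paste0("t", 1:n))))
    acc <- infer_species(rec, fit_families(rb, data.frame()))
    expect_equal(unname(acc$F$degrees["low"]), 1 - 0.5^n)
    expect_equal(unname(acc$F$n_rules["low"]), n)
  }
})

test_that("records with undeclared trait columns are rejected", {
  rb <- make_tiny_rulebook(2, "F")
  rb <- fit_families(rb, data.frame())
  rec <- data.frame(species_id = "s", taxon = "x", t1 = 1, t2 = 2, bogus = 3)
  expect_error(infer_species(rec, rb), "bogus")
})
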
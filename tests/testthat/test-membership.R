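test_that("trapezoid and triangular evaluation hit plateau, apex, shoulders, support", {
  trap <- membership_function("low", "trapezoid", c(0, 0, 10, 20))
  expect_identical(evaluate_membership(trap, 5), 1)
  expect_identical(evaluate_membership(trap, 15), 0.5)
  expect_identical(evaluate_membership(trap, 25), 0)
  expect_identical(evaluate_membership(trap, 0), 1)  # zero-width left shoulder

  tri <- membership_function("medium", "triangular", c(10, 20, 30))
  expect_identical(evaluate_membership(tri, 10), 0)
  expect_identical(evaluate_membership(tri, 20), 1)
  expect_identical(evaluate_membership(tri, 25), 0.5)
  expect_identical(evaluate_membership(tri, 35), 0)
})

test_that("membership function construction enforces shape and ordering rules", {
  expect_error(membership_function("medium", "trapezoid", c(0, 1, 2, 3)),
               "reserved")
  expect_error(membership_function("low", "triangular", c(0, 1, 2)),
               "reserved")
  expect_error(membership_function("low", "trapezoid", c(3, 2, 1, 0)),
               "increasing")
  expect_error(membership_function("high", "triangular", c(0, 1)),
               "3 breakpoints")
  expect_error(evaluate_membership(
    membership_function("low", "trapezoid", c(0, 1, 2, 3)), NaN),
    "finite")
})

test_that("evaluation matches a piecewise-linear interpolation oracle and stays in [0,1]", {
  set.seed(101)
  for (rep in 1:50) {
    bp4 <- sort(runif(4, 0, 100))
    bp3 <- sort(runif(3, 0, 100))
    if (anyDuplicated(bp4) || anyDuplicated(bp3)) next
    trap <- membership_function("very_high", "trapezoid", bp4)
    tri <- membership_function("high", "triangular", bp3)
    grid <- seq(-10, 110, length.out = 400)
    dt <- evaluate_membership(trap, grid)
    dr <- evaluate_membership(tri, grid)
    expect_true(all(dt >= 0 & dt <= 1) && all(dr >= 0 & dr <= 1))
    expect_equal(dt, piecewise_oracle(bp4, "trapezoid", grid),
                 tolerance = 1e-12)
    expect_equal(dr, piecewise_oracle(bp3, "triangular", grid),
                 tolerance = 1e-12)
  }
})

test_that("quantile recipe anchors plateaus to the quartiles and passes invariants", {
  fam <- build_family_from_quantiles(1:100, fuzziness = 0.5, trait_id = "q")
  expect_equal(fam$functions$low$breakpoints[3], 25.75)      # type-7 Q25
  expect_equal(fam$functions$very_high$breakpoints[2], 75.25) # type-7 Q75
  expect_equal(fam$functions$medium$breakpoints[2], 50.5)     # median apex
  expect_silent(validate_family(fam))

  expect_error(build_family_from_quantiles(rep(3, 10)), "degenerate")
  expect_error(build_family_from_quantiles(c(1, 2, 3)), "at least 4")
})

test_that("quantile families satisfy overlap and coverage on random samples", {
  set.seed(202)
  for (rep in 1:25) {
    vals <- switch(1 + rep %% 3,
                   rnorm(60, 10, 3),
                   rlnorm(60, 2, 1),
                   runif(60, -5, 5))
    fam <- build_family_from_quantiles(vals, fuzziness = 0.5)
    grid <- seq(fam$domain[1], fam$domain[2], length.out = 300)
    degs <- sapply(fam$functions, function(fn) evaluate_membership(fn, grid))
    expect_true(all(apply(degs, 1, max) > 0))  # coverage
    for (k in 1:3)                              # adjacent overlap
      expect_gt(max(pmin(degs[, k], degs[, k + 1])), 0)
  }
})

test_that("fuzzify retains only degrees above the floor and flags missing values", {
  fam <- make_test_family()
  # 10 sits on the low plateau only
  cm <- fuzzify(10, fam)
  expect_equal(cm$degrees, c(low = 1))
  # 30 belongs to low (1/3) and medium (1/2): multi-set assignment
  cm <- fuzzify(30, fam)
  expect_setequal(names(cm$degrees), c("low", "medium"))
  expect_equal(unname(cm$degrees["medium"]), 0.5)
  # a degree of exactly 0.2 is dropped (strictly "exceeds")
  trap <- membership_function("low", "trapezoid", c(0, 0, 10, 20))
  fam2 <- make_test_family()
  expect_equal(evaluate_membership(fam2$functions$low, 32), 0.2)
  expect_false("low" %in% names(fuzzify(32, fam2)$degrees))
  # missing value returns the distinguished marker
  expect_s3_class(fuzzify(NA, fam), "missing_trait")
})

test_that("raising the retention floor never adds categories", {
  fam <- make_test_family()
  set.seed(303)
  xs <- runif(100, 0, 100)
  for (x in xs) {
    lo <- names(fuzzify(x, fam, floor = 0.1)$degrees)
    hi <- names(fuzzify(x, fam, floor = 0.35)$degrees)
    expect_true(all(hi %in% lo))
  }
})

test_that("out-of-domain values are clamped with a warning", {
  fam <- make_test_family()
  expect_warning(cm <- fuzzify(150, fam), "clamped")
  expect_equal(cm$degrees, c(very_high = 1))
  expect_silent(cm2 <- fuzzify(150, fam, warn_clamp = FALSE))
  expect_equal(cm2$degrees, cm$degrees)
})
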
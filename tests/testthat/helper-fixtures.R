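# Shared fixtures: an explicit breakpoint geometry on [0, 100] whose
# overlap/coverage invariants hold by construction, small rulebooks
# assembled from it, and independent oracles used against the
# implementation.

std_breakpoints <- function() {
  list(low = c(0, 0, 20, 35),
       medium = c(20, 40, 60),
       high = c(45, 65, 85),
       very_high = c(70, 85, 100, 100))
}

make_test_family <- function(trait_id = "t") {
  bp <- std_breakpoints()
  fuzzy_set_family(
    trait_id,
    list(low = membership_function("low", "trapezoid", bp$low),
         medium = membership_function("medium", "triangular", bp$medium),
         high = membership_function("high", "triangular", bp$high),
         very_high = membership_function("very_high", "trapezoid",
                                         bp$very_high)),
    domain = c(0, 100))
}

explicit_trait <- function(id, linked) {
  trait_definition(id, linked_indices = linked,
                   breakpoints = std_breakpoints())
}

# rules: identity mapping premise -> conclusion for every linked index
identity_rules <- function(id, linked, weight = 0.5) {
  do.call(rbind, lapply(linked, function(idx)
    data.frame(trait_id = id,
               premise = c("low", "medium", "high", "very_high"),
               index = idx,
               conclusion = c("low", "medium", "high", "very_high"),
               weight = weight, stringsAsFactors = FALSE)))
}

# n traits, all linked to F (identity rules), explicit breakpoints
make_tiny_rulebook <- function(n_traits = 2, linked = "F") {
  ids <- paste0("t", seq_len(n_traits))
  rulebook(lapply(ids, explicit_trait, linked = linked),
           do.call(rbind, lapply(ids, identity_rules, linked = linked)))
}

# sequential MYCIN recurrence, the oracle for the closed form
accumulate_oracle <- function(ms) {
  acc <- 0
  for (m in ms) acc <- acc + m * (1 - acc)
  acc
}

# O(n^2) tie-corrected Kendall tau-b by explicit pair enumeration
tau_b_oracle <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# piecewise-linear interpolation oracle for strict breakpoint geometries
piecewise_oracle <- function(breakpoints, shape, x) {
  if (shape == "trapezoid") {
    knots <- breakpoints; vals <- c(0, 1, 1, 0)
  } else {
    knots <- breakpoints; vals <- c(0, 1, 0)
  }
  stats::approx(knots, vals, xout = x, yleft = 0, yright = 0)$y
}
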
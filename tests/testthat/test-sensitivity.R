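small_table <- function(seed = 5, n = c(finfish = 6, crustaceans = 4,
                                        molluscs = 4, algae = 4))
  generate_table(synthetic_config(n_species = n), seed = seed)

test_that("removing the empty trait set gives deviation exactly zero", {
  tab <- small_table()
  rb <- fit_families(default_rulebook(), tab)
  baseline <- fcbscore:::score_table_safe(tab, rb)
  maxima <- setNames(vapply(c("F", "C", "B"),
                            function(i) max(baseline[[i]]), numeric(1)),
                     c("F", "C", "B"))
  d <- fcbscore:::jackknife_one_subset(tab, rb, baseline, maxima,
                                       character(0))
  expect_true(all(d$deviation == 0))
  expect_true(all(d$percent_variation == 0))
})

test_that("traits with no rules for an index leave that index untouched", {
  tab <- small_table()
  jk <- jackknife_single(tab, default_rulebook())
  # max_size informs F only, so its removal cannot move B or C
  for (idx in c("C", "B")) {
    d <- subset(jk$deviations, removed_traits == "max_size" & index == idx)
    expect_true(all(d$deviation == 0))
  }
  # percent variation is deviation over the per-index baseline maximum
  expect_equal(jk$deviations$percent_variation,
               jk$deviations$deviation /
                 jk$max_index[jk$deviations$index] * 100,
               ignore_attr = TRUE)
})

test_that("duplicate-trait removal matches the closed-form accumulation change", {
  # t1 and t2 identical values and rules to F:very_high; t3 supplies a
  # fixed low conclusion so the score moves when very_high mass changes
  traits <- list(explicit_trait("t1", "F"), explicit_trait("t2", "F"),
                 explicit_trait("t3", "F"))
  vh <- function(id) data.frame(trait_id = id, premise = "very_high",
                                index = "F", conclusion = "very_high",
                                weight = 0.5, stringsAsFactors = FALSE)
  lo <- data.frame(trait_id = "t3", premise = "low", index = "F",
                   conclusion = "low", weight = 0.5, stringsAsFactors = FALSE)
  rb <- rulebook(traits, rbind(vh("t1"), vh("t2"), lo))
  tab <- data.frame(species_id = "s", taxon = "finfish",
                    t1 = 90, t2 = 90, t3 = 10)
  jk <- jackknife_single(tab, rb)
  m <- 0.5  # fired conclusion membership at full premise
  base_vh <- 1 - (1 - m)^2
  f_base <- (0.5 * 1 + base_vh * 100) / (0.5 + base_vh)
  f_removed <- (0.5 * 1 + m * 100) / (0.5 + m)
  d <- subset(jk$deviations, removed_traits == "t2" & index == "F")
  expect_equal(d$baseline, f_base)
  expect_equal(d$deviation, f_removed - f_base)
})

test_that("removal of a trait concluding only to very_high cannot raise scores", {
  traits <- list(explicit_trait("up", "F"), explicit_trait("t2", "F"))
  rules <- rbind(
    data.frame(trait_id = "up", premise = c("high", "very_high"),
               index = "F", conclusion = "very_high", weight = 0.5),
    identity_rules("t2", "F"))
  rb <- rulebook(traits, rules)
  set.seed(77)
  tab <- data.frame(species_id = sprintf("s%02d", 1:20), taxon = "finfish",
                    up = runif(20, 0, 100), t2 = runif(20, 0, 100))
  jk <- jackknife_single(tab, rb)
  d <- subset(jk$deviations, removed_traits == "up" & index == "F")
  expect_true(all(d$deviation <= 1e-12))
})

test_that("randomized multi-trait removal is reproducible and range-checked", {
  tab <- small_table()
  rb <- default_rulebook()
  jm1 <- jackknife_multi(tab, rb, n_remove = 3, reps = 5, seed = 99)
  jm2 <- jackknife_multi(tab, rb, n_remove = 3, reps = 5, seed = 99)
  expect_identical(jm1$deviations, jm2$deviations)
  expect_error(jackknife_multi(tab, rb, n_remove = 12), "n_remove")
  expect_error(jackknife_multi(tab, rb, n_remove = 0), "n_remove")
})

test_that("single-trait sampling marginals equal the exhaustive analysis", {
  tab <- small_table()
  rb <- default_rulebook()
  jk <- jackknife_single(tab, rb)
  jm <- jackknife_multi(tab, rb, n_remove = 1, reps = 15, seed = 3)
  for (r in unique(jm$deviations$replicate_id)) {
    sub <- subset(jm$deviations, replicate_id == r)
    tr <- sub$removed_traits[1]
    ex <- subset(jk$deviations, removed_traits == tr)
    expect_equal(sub$deviation, ex$deviation)
  }
})

test_that("leaving a single trait reproduces direct one-trait scoring", {
  traits <- list(explicit_trait("t1", c("F", "C", "B")),
                 explicit_trait("t2", c("F", "C", "B")),
                 explicit_trait("t3", c("F", "C", "B")))
  rules <- do.call(rbind, lapply(paste0("t", 1:3), identity_rules,
                                 linked = c("F", "C", "B")))
  rb <- rulebook(traits, rules)
  set.seed(13)
  tab <- data.frame(species_id = sprintf("s%02d", 1:8), taxon = "finfish",
                    t1 = runif(8, 5, 95), t2 = runif(8, 5, 95),
                    t3 = runif(8, 5, 95))
  jm <- jackknife_multi(tab, rb, n_remove = 2, reps = 6, seed = 8)
  for (r in unique(jm$deviations$replicate_id)) {
    sub <- subset(jm$deviations, replicate_id == r)
    removed <- strsplit(sub$removed_traits[1], "+", fixed = TRUE)[[1]]
    kept <- setdiff(paste0("t", 1:3), removed)
    rb1 <- rulebook(list(explicit_trait(kept, c("F", "C", "B"))),
                    identity_rules(kept, c("F", "C", "B")))
    direct <- score_table(tab[c("species_id", "taxon", kept)], rb1)
    got <- reshape(sub[c("species_id", "index", "score_removed")],
                   idvar = "species_id", timevar = "index",
                   direction = "wide")
    expect_equal(got$score_removed.F, direct$f_score)
    expect_equal(got$score_removed.C, direct$c_score)
    expect_equal(got$score_removed.B, direct$b_score)
  }
})
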
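# Score every species on every index, tolerating undefined scores
# (an index left with no conclusions after trait removal yields NA and
# a flag instead of an error).
score_table_safe <- function(table, rb) {
  n <- nrow(table)
  out <- data.frame(species_id = table$species_id,
                    F = NA_real_, C = NA_real_, B = NA_real_,
                    undefined = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    acc <- infer_species(table[i, , drop = FALSE], rb, warn_clamp = FALSE)
    bad <- character()
    for (idx in FCB_INDICES) {
      s <- tryCatch(defuzzify(acc[[idx]]$degrees, rb$defuzz_indices),
                    error = function(e) NA_real_)
      if (is.na(s)) bad <- c(bad, idx)
      out[[idx]][i] <- s
    }
    out$undefined[i] <- paste(bad, collapse = ",")
  }
  out
}

scores_long <- function(scored, indices = FCB_INDICES) {
  do.call(rbind, lapply(indices, function(idx)
    data.frame(species_id = scored$species_id, index = idx,
               score = scored[[idx]], stringsAsFactors = FALSE)))
}

# indices any declared trait links to; only these can carry conclusions
# or penalties, so only these are meaningful in a sensitivity analysis
informed_indices <- function(rb) {
  FCB_INDICES[FCB_INDICES %in%
                unlist(lapply(rb$traits, `[[`, "linked_indices"))]
}

check_baseline_defined <- function(baseline, informed) {
  bad <- vapply(strsplit(baseline$undefined, ","), function(u)
    any(u %in% informed), logical(1))
  if (any(bad))
    stop("baseline scores undefined for some species; check the rulebook",
         call. = FALSE)
}

#' Maximum baseline index score
#'
#' The denominator of the jackknife percent-variation summaries: the
#' maximum baseline score over species for one index.  It is fixed by
#' the baseline run, so the same denominator applies to every removal.
#'
#' @param scores data frame from [score_table()] (columns `f_score`,
#'   `c_score`, `b_score`).
#' @param index `"F"`, `"C"`, or `"B"`.
#' @return the maximum score (a scalar).
#' @export
max_index <- function(scores, index = c("F", "C", "B")) {
  index <- match.arg(index)
  col <- c(F = "f_score", C = "c_score", B = "b_score")[[index]]
  if (!is.data.frame(scores) || nrow(scores) == 0 || !col %in% names(scores))
    stop("scores must be a non-empty score table", call. = FALSE)
  max(scores[[col]], na.rm = TRUE)
}

jackknife_one_subset <- function(table, rb_full, baseline, maxima, removed) {
  rb_red <- remove_trait(rb_full, removed)
  scored <- score_table_safe(table[setdiff(names(table), removed)], rb_red)
  informed <- names(maxima)
  base_long <- scores_long(baseline, informed)
  rem_long <- scores_long(scored, informed)
  dev <- rem_long$score - base_long$score
  data.frame(removed_traits = paste(removed, collapse = "+"),
             species_id = base_long$species_id,
             index = base_long$index,
             baseline = base_long$score,
             score_removed = rem_long$score,
             deviation = dev,
             percent_variation = dev / maxima[base_long$index] * 100,
             undefined = rep(scored$undefined, times = length(informed)),
             stringsAsFactors = FALSE)
}

#' Exhaustive single-trait jackknife sensitivity analysis
#'
#' Removes each declared trait in turn — together with its rules and its
#' missing-data penalty — re-scores every species, and reports the
#' deviation from the baseline score (all traits included) per species
#' and index.  Percent variation is the deviation in index points
#' divided by the maximum baseline score of that index, times 100.
#' Traits whose removal produces relatively large deviations have
#' greater influence on the system.
#'
#' @param table species-by-trait data frame.
#' @param rb a [rulebook()].
#' @param denominator `"baseline"` (default; the maximum baseline score
#'   per index across species) or `"theoretical"` (100).
#' @return list with `deviations` (per trait x species x index),
#'   `summary` (median/min/max percent variation per trait x index),
#'   `max_index` (the per-index denominators), and `baseline` (the
#'   baseline score table).
#' @export
jackknife_single <- function(table, rb,
                             denominator = c("baseline", "theoretical")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(table), inherits(rb, "rulebook"))
  if (nrow(table) < 1) stop("need at least one species", call. = FALSE)
  if (length(rb$traits) < 2)
    stop("need at least two traits to jackknife", call. = FALSE)
  rb <- fit_families(rb, table)
  informed <- informed_indices(rb)
  baseline <- score_table_safe(table, rb)
  check_baseline_defined(baseline, informed)
  maxima <- if (denominator == "baseline")
    vapply(stats::setNames(informed, informed),
           function(i) max(baseline[[i]]), numeric(1))
  else stats::setNames(rep(100, length(informed)), informed)
  dev <- do.call(rbind, lapply(names(rb$traits), function(tr)
    jackknife_one_subset(table, rb, baseline, maxima, tr)))
  rownames(dev) <- NULL
  smry <- stats::aggregate(percent_variation ~ removed_traits + index,
                           data = dev,
                           FUN = function(v) c(median = stats::median(v),
                                               min = min(v), max = max(v)))
  smry <- cbind(smry[c("removed_traits", "index")],
                as.data.frame(smry$percent_variation))
  list(deviations = dev, summary = smry, max_index = maxima,
       baseline = baseline)
}

#' Randomized multi-trait jackknife
#'
#' Draws `reps` uniform random subsets of `n_remove` traits (without
#' replacement within a subset), removes each subset with its rules and
#' penalties, and returns the full distribution of score deviations.
#' Seeded and reproducible; the same seed yields the same subsets and
#' deviations.
#'
#' @inheritParams jackknife_single
#' @param n_remove number of traits removed per replicate, in
#'   `[1, n_traits - 1]`.
#' @param reps number of random subsets, default 50.
#' @param seed integer seed for subset sampling.
#' @return list with `deviations` (per replicate x species x index,
#'   including `replicate_id`), `max_index`, and `baseline`.
#' @export
jackknife_multi <- function(table, rb, n_remove, reps = 50, seed = NULL,
                            denominator = c("baseline", "theoretical")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(table), inherits(rb, "rulebook"))
  n_traits <- length(rb$traits)
  if (!is.numeric(n_remove) || n_remove < 1 || n_remove > n_traits - 1)
    stop(sprintf("n_remove must lie in [1, %d]", n_traits - 1), call. = FALSE)
  n_remove <- as.integer(n_remove)
  rb <- fit_families(rb, table)
  informed <- informed_indices(rb)
  baseline <- score_table_safe(table, rb)
  check_baseline_defined(baseline, informed)
  maxima <- if (denominator == "baseline")
    vapply(stats::setNames(informed, informed),
           function(i) max(baseline[[i]]), numeric(1))
  else stats::setNames(rep(100, length(informed)), informed)
  if (!is.null(seed)) set.seed(seed)
  dev <- do.call(rbind, lapply(seq_len(reps), function(r) {
    removed <- sample(names(rb$traits), n_remove)
    d <- jackknife_one_subset(table, rb, baseline, maxima, removed)
    cbind(replicate_id = r, d)
  }))
  rownames(dev) <- NULL
  list(deviations = dev, max_index = maxima, baseline = baseline)
}
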
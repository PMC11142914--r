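#' Defuzzify accumulated memberships into a crisp index score
#'
#' The four accumulated category memberships are collapsed into one crisp
#' 1-100 score as a membership-weighted average of the category index
#' values (defaults: low = 1, medium = 25, high = 75, very high = 100):
#' `FinInd = sum(AccMem_x * Ind_x) / sum(AccMem_x)`.
#' The score is invariant to uniform rescaling of the memberships and is
#' bounded by the smallest and largest index value among categories with
#' positive membership.  An all-zero membership vector is a data or
#' rulebook defect (the missing-data penalty makes it unreachable for
#' declared traits) and raises an error rather than returning a sentinel.
#'
#' @param degrees named numeric over `low`, `medium`, `high`,
#'   `very_high`: the accumulated memberships for one index.
#' @param indices named numeric of category index values.
#' @return the crisp score (`FinInd`).
#' @examples
#' defuzzify(c(low = 0, medium = 0, high = 0, very_high = 0.5))  # 100
#' @export
defuzzify <- function(degrees,
                      indices = c(low = 1, medium = 25, high = 75,
                                  very_high = 100)) {
  if (!all(FCB_CATEGORIES %in% names(degrees)))
    stop("degrees must be named over low/medium/high/very_high",
         call. = FALSE)
  degrees <- degrees[FCB_CATEGORIES]
  indices <- indices[FCB_CATEGORIES]
  if (anyNA(degrees) || any(degrees < 0))
    stop("degrees must be non-negative and non-missing", call. = FALSE)
  total <- sum(degrees)
  if (total <= 0)
    stop("undefined score: all accumulated memberships are zero",
         call. = FALSE)
  sum(degrees * indices) / total
}

#' Score one species on all three indices
#'
#' Composes [infer_species()] and [defuzzify()].  An index for which no
#' rule fired and no penalty applied has an undefined score; the error is
#' annotated with the species and index so failing rows are identifiable
#' in batch runs.
#'
#' @inheritParams infer_species
#' @return one-row data frame: `species_id`, `taxon`, `f_score`,
#'   `c_score`, `b_score`, `mean_score`.
#' @export
score_species <- function(record, rb, warn_clamp = TRUE) {
  rec <- as.list(record)
  sid <- rec$species_id %||% "<unnamed>"
  acc <- infer_species(record, rb, warn_clamp = warn_clamp)
  scores <- vapply(FCB_INDICES, function(idx) {
    tryCatch(defuzzify(acc[[idx]]$degrees, rb$defuzz_indices),
             error = function(e)
               stop(sprintf("species '%s', index %s: %s", sid, idx,
                            conditionMessage(e)), call. = FALSE))
  }, numeric(1))
  data.frame(species_id = sid, taxon = rec$taxon %||% NA_character_,
             f_score = scores[["F"]], c_score = scores[["C"]],
             b_score = scores[["B"]],
             mean_score = mean(scores), stringsAsFactors = FALSE)
}

#' Score a full species-by-trait table
#'
#' @param table data frame with `species_id`, `taxon`, and trait columns
#'   (see [read_trait_table()]).
#' @param rb a [rulebook()]; families are fitted to `table` on the fly if
#'   not already fitted.
#' @param warn_clamp warn on out-of-domain trait values.
#' @return data frame of [score_species()] rows, one per species, with
#'   the long-format accumulated memberships attached as
#'   `attr(, "memberships")` for auditability (columns `species_id`,
#'   `index`, `category`, `acc_membership`, `n_rules`).
#' @export
score_table <- function(table, rb, warn_clamp = FALSE) {
  stopifnot(is.data.frame(table), inherits(rb, "rulebook"))
  if (!all(c("species_id", "taxon") %in% names(table)))
    stop("table must have species_id and taxon columns", call. = FALSE)
  if (any(vapply(rb$traits, function(tr) is.null(tr$family), logical(1))))
    rb <- fit_families(rb, table)
  rows <- vector("list", nrow(table))
  mems <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    rec <- table[i, , drop = FALSE]
    acc <- infer_species(rec, rb, warn_clamp = warn_clamp)
    scores <- vapply(FCB_INDICES, function(idx) {
      tryCatch(defuzzify(acc[[idx]]$degrees, rb$defuzz_indices),
               error = function(e)
                 stop(sprintf("species '%s', index %s: %s",
                              rec$species_id, idx, conditionMessage(e)),
                      call. = FALSE))
    }, numeric(1))
    rows[[i]] <- data.frame(species_id = rec$species_id, taxon = rec$taxon,
                            f_score = scores[["F"]], c_score = scores[["C"]],
                            b_score = scores[["B"]],
                            mean_score = mean(scores),
                            stringsAsFactors = FALSE)
    mems[[i]] <- do.call(rbind, lapply(FCB_INDICES, function(idx)
      data.frame(species_id = rec$species_id, index = idx,
                 category = FCB_CATEGORIES,
                 acc_membership = unname(acc[[idx]]$degrees),
                 n_rules = unname(acc[[idx]]$n_rules),
                 stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "memberships") <- do.call(rbind, mems)
  out
}
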
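#' Fire one heuristic rule
#'
#' A rule fires only when the premise membership strictly exceeds the
#' firing threshold.  The conclusion membership combines the premise
#' degree with the rule weight: `weight * premise` under the default
#' `"product"` combiner, `min(weight, premise)` under `"min"`.  Either
#' way a fully satisfied premise yields the rule weight, so with the
#' default weight of 0.5 no single rule can contribute more than 0.5 to
#' its conclusion set.
#'
#' @param premise_degree membership of the premise category, in `[0, 1]`.
#' @param weight rule weight in `(0, 1]`.
#' @param threshold firing threshold (strict), default 0.2.
#' @param combiner `"product"` or `"min"`.
#' @return conclusion membership, or `NA_real_` when the rule does not
#'   fire.
#' @export
fire_rule <- function(premise_degree, weight = 0.5, threshold = 0.2,
                      combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  if (!is.numeric(premise_degree) || is.na(premise_degree) ||
      premise_degree < 0 || premise_degree > 1)
    stop("premise_degree must lie in [0, 1]", call. = FALSE)
  if (premise_degree <= threshold) return(NA_real_)
  if (combiner == "product") weight * premise_degree
  else min(weight, premise_degree)
}

#' Low-potential conclusions for a missing trait value
#'
#' Missing trait data is penalized by assigning the species to the
#' low-potential fuzzy set of every index the trait is linked to, with
#' conclusion membership `weight * missing_penalty_degree` (0.5 under the
#' defaults).
#'
#' @param trait_id a trait declared in `rb`.
#' @param rb a [rulebook()].
#' @return data frame with columns `index`, `conclusion`, `membership` —
#'   one low-potential row per linked index.
#' @export
missing_penalty <- function(trait_id, rb) {
  stopifnot(inherits(rb, "rulebook"))
  tr <- rb$traits[[trait_id]]
  if (is.null(tr))
    stop(sprintf("trait '%s' is not declared in the rulebook", trait_id),
         call. = FALSE)
  data.frame(index = tr$linked_indices, conclusion = "low",
             membership = rb$default_weight * rb$missing_penalty_degree,
             stringsAsFactors = FALSE)
}

#' MYCIN accumulation of conclusion memberships
#'
#' Combines the memberships of all conclusions reaching one fuzzy set via
#' the certainty-factor recurrence
#' `AccMem[i+1] = AccMem[i] + m[i+1] * (1 - AccMem[i])`,
#' whose closed form is `1 - prod(1 - m)` (probabilistic OR).  The result
#' is order-invariant, monotone in every input, and stays strictly below
#' 1 whenever every contributing membership is below 1.  An empty list
#' accumulates to 0.
#'
#' @param memberships numeric vector of conclusion memberships in `[0, 1]`.
#' @return the accumulated degree of membership.
#' @examples
#' accumulate_membership(c(0.5, 0.5))  # 0.75
#' @export
accumulate_membership <- function(memberships) {
  if (length(memberships) == 0) return(0)
  if (!is.numeric(memberships) || anyNA(memberships) ||
      any(memberships < 0 | memberships > 1))
    stop("memberships must lie in [0, 1]", call. = FALSE)
  1 - prod(1 - memberships)
}

#' Run the inference engine for one species
#'
#' Fuzzifies every trait the rulebook declares (missing values trigger
#' the low-potential penalty), fires all applicable rules, and MYCIN-
#' accumulates the conclusion memberships per index and potential
#' category.  The result is deterministic and invariant to the order of
#' the trait columns.
#'
#' @param record a single-row data frame or named list with `species_id`,
#'   `taxon`, and one entry per trait (`NA` = missing).  Trait keys must
#'   be a subset of the rulebook's declared traits.
#' @param rb a [rulebook()] with fitted families (see [fit_families()]).
#' @param warn_clamp passed to [fuzzify()].
#' @return named list over `F`, `C`, `B`; each element a list with
#'   `degrees` (named numeric over the four potential categories) and
#'   `n_rules` (count of contributing conclusions per category).
#' @export
infer_species <- function(record, rb, warn_clamp = TRUE) {
  stopifnot(inherits(rb, "rulebook"))
  rec <- as.list(record)
  trait_keys <- intersect(names(rec), names(rb$traits))
  extra <- setdiff(names(rec), c("species_id", "taxon", names(rb$traits)))
  if (length(extra))
    stop("record has trait columns not declared in the rulebook: ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (length(rb$traits) == 0)
    stop("empty record: no declared traits to score", call. = FALSE)

  c_index <- character(0); c_concl <- character(0); c_mem <- numeric(0)
  for (id in names(rb$traits)) {
    tr <- rb$traits[[id]]
    val <- if (id %in% trait_keys) rec[[id]] else NA
    if (is.null(val) || is.na(val)) {
      pen <- missing_penalty(id, rb)
      c_index <- c(c_index, pen$index)
      c_concl <- c(c_concl, pen$conclusion)
      c_mem <- c(c_mem, pen$membership)
      next
    }
    if (is.null(tr$family))
      stop(sprintf("trait '%s' has no fitted fuzzy-set family; call fit_families() first",
                   id), call. = FALSE)
    cm <- fuzzify(val, tr$family, floor = rb$retention_floor,
                  warn_clamp = warn_clamp)
    if (length(cm$degrees) == 0) next
    rr <- rb$rules[rb$rules$trait_id == id, , drop = FALSE]
    prem <- cm$degrees[rr$premise]
    fired <- !is.na(prem) & prem > rb$firing_threshold
    if (!any(fired)) next
    m <- if (rb$combiner == "product") rr$weight[fired] * prem[fired]
         else pmin(rr$weight[fired], prem[fired])
    c_index <- c(c_index, rr$index[fired])
    c_concl <- c(c_concl, rr$conclusion[fired])
    c_mem <- c(c_mem, m)
  }
  out <- lapply(FCB_INDICES, function(idx) {
    degrees <- stats::setNames(numeric(4), FCB_CATEGORIES)
    n_rules <- stats::setNames(integer(4), FCB_CATEGORIES)
    sel <- c_index == idx
    for (cat in FCB_CATEGORIES) {
      m <- c_mem[sel & c_concl == cat]
      degrees[[cat]] <- accumulate_membership(m)
      n_rules[[cat]] <- length(m)
    }
    list(degrees = degrees, n_rules = n_rules)
  })
  stats::setNames(out, FCB_INDICES)
}
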
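#' Declare a trait for a rulebook
#'
#' @param trait_id short unique key.
#' @param display_name human-readable name.
#' @param units measurement units, free text.
#' @param value_domain plausible closed interval for raw values; used to
#'   clamp out-of-range inputs when explicit breakpoints are given.
#' @param linked_indices non-empty subset of `c("F", "C", "B")` — the
#'   goal indices this trait informs.  A trait with no linkage is
#'   rejected at load time.
#' @param breakpoints optional named list (`low`, `medium`, `high`,
#'   `very_high`) of explicit breakpoint vectors; overrides the quantile
#'   recipe.
#' @param fuzziness shoulder width fraction for the quantile recipe, used
#'   when `breakpoints` is `NULL` (see [build_family_from_quantiles()]).
#' @return a `trait_definition` list.
#' @export
trait_definition <- function(trait_id, display_name = trait_id, units = "",
                             value_domain = NULL, linked_indices,
                             breakpoints = NULL, fuzziness = 0.5) {
  if (!is.character(trait_id) || length(trait_id) != 1L || !nzchar(trait_id))
    stop("trait_id must be a non-empty string", call. = FALSE)
  linked_indices <- unique(as.character(linked_indices))
  if (length(linked_indices) == 0 || !all(linked_indices %in% FCB_INDICES))
    stop(sprintf("trait '%s': linked_indices must be a non-empty subset of F, C, B",
                 trait_id), call. = FALSE)
  structure(list(trait_id = trait_id, display_name = display_name,
                 units = units, value_domain = value_domain,
                 linked_indices = linked_indices,
                 breakpoints = breakpoints, fuzziness = fuzziness,
                 family = NULL),
            class = "trait_definition")
}

#' Assemble a rulebook
#'
#' The rulebook is the complete specification of the expert system: the
#' declared traits with their fuzzy-set recipes, the heuristic rules
#' mapping trait categories to FCB potential categories, the rule-firing
#' threshold, the retention floor used at fuzzification, the
#' defuzzification index values, and the missing-data penalty.
#'
#' @param traits list of [trait_definition()]s.
#' @param rules data frame with columns `trait_id`, `premise`, `index`,
#'   `conclusion`, `weight`; missing `weight` entries take
#'   `default_weight`.
#' @param firing_threshold minimum premise membership (strict) for a rule
#'   to fire; default 0.2.
#' @param retention_floor minimum membership (strict) for a category to
#'   be retained at fuzzification; default 0.2 (same value applied at
#'   both stages, independently configurable).
#' @param defuzz_indices named numeric: crisp index value of each
#'   potential category; defaults `low = 1, medium = 25, high = 75,
#'   very_high = 100`.
#' @param missing_penalty_degree premise degree assigned to the
#'   low-potential conclusion when a trait value is missing; default 1
#'   (the strongest admissible low conclusion).
#' @param default_weight rule weight when a rule does not state one;
#'   default 0.5, a 50% level of belief in the rule, capping any single
#'   conclusion membership at 0.5.
#' @param combiner how premise degree and rule weight combine into the
#'   conclusion membership: `"product"` (default) or `"min"`.
#' @return an object of class `rulebook`.
#' @export
rulebook <- function(traits, rules, firing_threshold = 0.2,
                     retention_floor = 0.2,
                     defuzz_indices = c(low = 1, medium = 25, high = 75,
                                        very_high = 100),
                     missing_penalty_degree = 1, default_weight = 0.5,
                     combiner = c("product", "min")) {
  combiner <- match.arg(combiner)
  if (!all(vapply(traits, inherits, logical(1), "trait_definition")))
    stop("traits must be a list of trait_definition objects", call. = FALSE)
  ids <- vapply(traits, `[[`, character(1), "trait_id")
  if (anyDuplicated(ids))
    stop("duplicate trait_id in rulebook: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(traits) <- ids
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  needed <- c("trait_id", "premise", "index", "conclusion")
  if (!all(needed %in% names(rules)))
    stop("rules must have columns trait_id, premise, index, conclusion",
         call. = FALSE)
  if (is.null(rules$weight)) rules$weight <- default_weight
  rules$weight[is.na(rules$weight)] <- default_weight
  rownames(rules) <- NULL
  rb <- structure(list(traits = traits, rules = rules,
                       firing_threshold = firing_threshold,
                       retention_floor = retention_floor,
                       defuzz_indices = defuzz_indices,
                       missing_penalty_degree = missing_penalty_degree,
                       default_weight = default_weight,
                       combiner = combiner),
                  class = "rulebook")
  validate_rulebook(rb)
  rb
}

#' @rdname rulebook
#' @param rb a `rulebook` to validate.
#' @export
validate_rulebook <- function(rb) {
  stopifnot(inherits(rb, "rulebook"))
  if (length(rb$traits) == 0)
    stop("rulebook declares no traits", call. = FALSE)
  if (!(rb$firing_threshold > 0 && rb$firing_threshold < 1))
    stop("firing_threshold must lie in (0, 1)", call. = FALSE)
  if (!(rb$retention_floor >= 0 && rb$retention_floor < 1))
    stop("retention_floor must lie in [0, 1)", call. = FALSE)
  if (!setequal(names(rb$defuzz_indices), FCB_CATEGORIES))
    stop("defuzz_indices must name all four potential categories",
         call. = FALSE)
  if (!(rb$missing_penalty_degree >= 0 && rb$missing_penalty_degree <= 1))
    stop("missing_penalty_degree must lie in [0, 1]", call. = FALSE)
  r <- rb$rules
  if (nrow(r) == 0) stop("rulebook has no rules", call. = FALSE)
  if (!all(r$premise %in% FCB_CATEGORIES) ||
      !all(r$conclusion %in% FCB_CATEGORIES))
    stop("rule premise/conclusion categories must be one of: ",
         paste(FCB_CATEGORIES, collapse = ", "), call. = FALSE)
  if (!all(r$index %in% FCB_INDICES))
    stop("rule index must be one of F, C, B", call. = FALSE)
  unknown <- setdiff(unique(r$trait_id), names(rb$traits))
  if (length(unknown))
    stop("rules reference undeclared traits: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(r))) {
    linked <- rb$traits[[r$trait_id[i]]]$linked_indices
    if (!r$index[i] %in% linked)
      stop(sprintf("rule %d: trait '%s' is not linked to index %s",
                   i, r$trait_id[i], r$index[i]), call. = FALSE)
  }
  if (anyDuplicated(r[, c("trait_id", "premise", "index")]))
    stop("duplicate (trait_id, premise, index) rule", call. = FALSE)
  if (any(r$weight <= 0 | r$weight > 1))
    stop("rule weights must lie in (0, 1]", call. = FALSE)
  invisible(rb)
}

#' Fit fuzzy-set families to an observed trait table
#'
#' Resolves each declared trait's membership functions: explicit
#' breakpoints are taken as-is; traits with a quantile recipe are fitted
#' to the non-missing values of the matching column in `table`.
#'
#' @param rb a [rulebook()].
#' @param table species-by-trait data frame (see [read_trait_table()]).
#' @return the rulebook with a fitted `fuzzy_set_family` attached to
#'   every trait.
#' @export
fit_families <- function(rb, table) {
  stopifnot(inherits(rb, "rulebook"), is.data.frame(table))
  for (id in names(rb$traits)) {
    tr <- rb$traits[[id]]
    if (!is.null(tr$breakpoints)) {
      fam <- family_from_breakpoints(id, tr$breakpoints, tr$value_domain)
    } else {
      if (!id %in% names(table))
        stop(sprintf("trait '%s' uses a quantile recipe but is absent from the table",
                     id), call. = FALSE)
      vals <- table[[id]]
      fam <- build_family_from_quantiles(vals[!is.na(vals)],
                                         fuzziness = tr$fuzziness,
                                         trait_id = id)
    }
    rb$traits[[id]]$family <- fam
  }
  rb
}

family_from_breakpoints <- function(trait_id, breakpoints, value_domain) {
  fns <- list(
    low = membership_function("low", "trapezoid", breakpoints$low),
    medium = membership_function("medium", "triangular", breakpoints$medium),
    high = membership_function("high", "triangular", breakpoints$high),
    very_high = membership_function("very_high", "trapezoid",
                                    breakpoints$very_high)
  )
  if (is.null(value_domain)) {
    bp <- unlist(breakpoints)
    value_domain <- range(bp)
  }
  fuzzy_set_family(trait_id, fns, domain = value_domain,
                   provenance = "explicit breakpoints")
}

#' Remove a trait (and everything it contributes) from a rulebook
#'
#' Removal semantics match the jackknife sensitivity analysis: the trait
#' ceases to exist, so its rules disappear and its missing-data penalty
#' is no longer applied.
#'
#' @param rb a [rulebook()].
#' @param trait_ids character vector of traits to drop.
#' @return the reduced rulebook.
#' @export
remove_trait <- function(rb, trait_ids) {
  stopifnot(inherits(rb, "rulebook"))
  unknown <- setdiff(trait_ids, names(rb$traits))
  if (length(unknown))
    stop("cannot remove undeclared traits: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (length(trait_ids) >= length(rb$traits))
    stop("cannot remove every trait in the rulebook", call. = FALSE)
  rb$traits <- rb$traits[setdiff(names(rb$traits), trait_ids)]
  rb$rules <- rb$rules[!rb$rules$trait_id %in% trait_ids, , drop = FALSE]
  rb
}

#' Read and write rulebooks as YAML
#'
#' The YAML schema mirrors the [rulebook()] constructor: a `traits:`
#' mapping (per trait: `display_name`, `units`, `value_domain`,
#' `linked_indices`, and either `breakpoints:` or `fuzziness:`), a
#' `rules:` list of `{trait, premise, index, conclusion, weight}`
#' entries, and top-level `firing_threshold`, `retention_floor`,
#' `defuzz_indices`, `missing_penalty_degree`, `default_weight`,
#' `combiner`.  Schema problems raise errors naming the offending trait
#' or rule.
#'
#' @param path file path.
#' @return `read_rulebook()` returns a validated [rulebook()];
#'   `write_rulebook()` returns `path` invisibly.
#' @export
read_rulebook <- function(path) {
  if (!file.exists(path)) stop("rulebook file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$traits) || is.null(doc$rules))
    stop("rulebook file must contain 'traits' and 'rules' sections",
         call. = FALSE)
  traits <- lapply(names(doc$traits), function(id) {
    tr <- doc$traits[[id]]
    trait_definition(
      trait_id = id,
      display_name = tr$display_name %||% id,
      units = tr$units %||% "",
      value_domain = if (!is.null(tr$value_domain)) as.numeric(tr$value_domain),
      linked_indices = tr$linked_indices %||%
        stop(sprintf("trait '%s': linked_indices missing", id), call. = FALSE),
      breakpoints = tr$breakpoints,
      fuzziness = tr$fuzziness %||% 0.5
    )
  })
  rules <- do.call(rbind, lapply(seq_along(doc$rules), function(i) {
    r <- doc$rules[[i]]
    for (f in c("trait", "premise", "index", "conclusion"))
      if (is.null(r[[f]]))
        stop(sprintf("rule %d: field '%s' missing", i, f), call. = FALSE)
    data.frame(trait_id = r$trait, premise = r$premise, index = r$index,
               conclusion = r$conclusion,
               weight = r$weight %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  di <- doc$defuzz_indices
  rulebook(
    traits = traits, rules = rules,
    firing_threshold = doc$firing_threshold %||% 0.2,
    retention_floor = doc$retention_floor %||% 0.2,
    defuzz_indices = if (is.null(di))
      c(low = 1, medium = 25, high = 75, very_high = 100)
    else unlist(di)[FCB_CATEGORIES],
    missing_penalty_degree = doc$missing_penalty_degree %||% 1,
    default_weight = doc$default_weight %||% 0.5,
    combiner = doc$combiner %||% "product"
  )
}

#' @rdname read_rulebook
#' @param rb a [rulebook()].
#' @export
write_rulebook <- function(rb, path) {
  stopifnot(inherits(rb, "rulebook"))
  traits <- lapply(rb$traits, function(tr) {
    out <- list(display_name = tr$display_name, units = tr$units,
                linked_indices = as.list(tr$linked_indices))
    if (!is.null(tr$value_domain))
      out$value_domain <- as.list(tr$value_domain)
    if (!is.null(tr$breakpoints)) out$breakpoints <- tr$breakpoints
    else out$fuzziness <- tr$fuzziness
    out
  })
  rules <- lapply(seq_len(nrow(rb$rules)), function(i) {
    r <- rb$rules[i, ]
    list(trait = r$trait_id, premise = r$premise, index = r$index,
         conclusion = r$conclusion, weight = r$weight)
  })
  doc <- list(traits = traits, rules = rules,
              firing_threshold = rb$firing_threshold,
              retention_floor = rb$retention_floor,
              defuzz_indices = as.list(rb$defuzz_indices),
              missing_penalty_degree = rb$missing_penalty_degree,
              default_weight = rb$default_weight,
              combiner = rb$combiner)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Content hash of a rulebook
#'
#' MD5 digest of the canonical YAML serialization, recorded in output
#' headers so downstream artifacts are traceable to the exact rule set.
#'
#' @param rb a [rulebook()].
#' @return a character MD5 string.
#' @export
rulebook_hash <- function(rb) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_rulebook(rb, tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rulebook <- function(x, ...) {
  cat(sprintf("<rulebook> %d traits, %d rules\n", length(x$traits),
              nrow(x$rules)))
  cat(sprintf("  firing threshold %.2g, retention floor %.2g, combiner '%s'\n",
              x$firing_threshold, x$retention_floor, x$combiner))
  cat(sprintf("  defuzz indices: %s\n",
              paste(sprintf("%s=%g", names(x$defuzz_indices), x$defuzz_indices),
                    collapse = ", ")))
  invisible(x)
}
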
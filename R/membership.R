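#' @keywords internal
"_PACKAGE"

# Linguistic categories, in increasing order of potential.
FCB_CATEGORIES <- c("low", "medium", "high", "very_high")
FCB_INDICES <- c("F", "C", "B")

#' Construct a fuzzy membership function
#'
#' A membership function maps a crisp trait value to a degree of belonging
#' in `[0, 1]` for one linguistic category.  The extreme categories
#' (`low`, `very_high`) use trapezoids (a plateau at degree 1 with one
#' linear shoulder); the interior categories (`medium`, `high`) use
#' triangles (a single apex at degree 1 with two linear shoulders).
#'
#' @param category one of `"low"`, `"medium"`, `"high"`, `"very_high"`.
#' @param shape `"trapezoid"` or `"triangular"`.  Trapezoids are only
#'   valid for the extreme categories, triangles only for the interior
#'   ones.
#' @param breakpoints weakly increasing numeric vector: `c(a, b, c, d)`
#'   for a trapezoid (plateau on `[b, c]`), `c(a, b, c)` for a triangle
#'   (apex at `b`).
#' @return an object of class `membership_function`.
#' @seealso [evaluate_membership()], [fuzzy_set_family()]
#' @export
membership_function <- function(category, shape, breakpoints) {
  category <- match.arg(category, FCB_CATEGORIES)
  shape <- match.arg(shape, c("trapezoid", "triangular"))
  breakpoints <- as.numeric(breakpoints)
  n_expected <- if (shape == "trapezoid") 4L else 3L
  if (length(breakpoints) != n_expected)
    stop(sprintf("%s membership function needs %d breakpoints, got %d",
                 shape, n_expected, length(breakpoints)), call. = FALSE)
  if (anyNA(breakpoints) || any(!is.finite(breakpoints)))
    stop("breakpoints must be finite", call. = FALSE)
  if (is.unsorted(breakpoints))
    stop("breakpoints must be weakly increasing", call. = FALSE)
  if (shape == "trapezoid" && !category %in% c("low", "very_high"))
    stop("trapezoid shape is reserved for the 'low' and 'very_high' categories",
         call. = FALSE)
  if (shape == "triangular" && !category %in% c("medium", "high"))
    stop("triangular shape is reserved for the 'medium' and 'high' categories",
         call. = FALSE)
  structure(list(category = category, shape = shape,
                 breakpoints = breakpoints),
            class = "membership_function")
}

#' Evaluate a membership function at crisp values
#'
#' Piecewise-linear evaluation: degree 1 on the plateau (trapezoid) or at
#' the apex (triangle), 0 outside the support, linear on the shoulders.
#' Degenerate (zero-width) shoulders evaluate to the plateau/apex value at
#' the shared breakpoint and 0 beyond it.
#'
#' @param fn a [membership_function()].
#' @param x numeric vector of trait values; must be finite.
#' @return numeric vector of degrees in `[0, 1]`.
#' @export
evaluate_membership <- function(fn, x) {
  stopifnot(inherits(fn, "membership_function"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("x must be finite and non-missing", call. = FALSE)
  bp <- fn$breakpoints
  deg <- numeric(length(x))
  if (fn$shape == "trapezoid") {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]; d <- bp[4]
    if (b > a) {
      i <- x >= a & x < b
      deg[i] <- (x[i] - a) / (b - a)
    }
    deg[x >= b & x <= cc] <- 1
    if (d > cc) {
      i <- x > cc & x <= d
      deg[i] <- (d - x[i]) / (d - cc)
    }
  } else {
    a <- bp[1]; b <- bp[2]; cc <- bp[3]
    if (b > a) {
      i <- x >= a & x < b
      deg[i] <- (x[i] - a) / (b - a)
    }
    deg[x == b] <- 1
    if (cc > b) {
      i <- x > b & x <= cc
      deg[i] <- (cc - x[i]) / (cc - b)
    }
  }
  pmin(pmax(deg, 0), 1)
}

#' Bundle the four membership functions for one trait
#'
#' A fuzzy-set family holds exactly one membership function per linguistic
#' category plus the trait's value domain.  Families must be *fuzzy*
#' (adjacent categories overlap: some value belongs to both with positive
#' degree) and must *cover* the domain (every value in the domain belongs
#' to at least one category with positive degree).  Both invariants are
#' checked on a dense grid at construction.
#'
#' @param trait_id character key for the trait.
#' @param functions named list with components `low`, `medium`, `high`,
#'   `very_high`, each a [membership_function()] of the matching category.
#' @param domain length-2 numeric, the closed value domain; values outside
#'   it are clamped before fuzzification.
#' @param provenance free-text note on how the breakpoints were obtained
#'   (explicit or quantile recipe).
#' @return an object of class `fuzzy_set_family`.
#' @export
fuzzy_set_family <- function(trait_id, functions, domain,
                             provenance = "explicit") {
  if (!setequal(names(functions), FCB_CATEGORIES))
    stop("functions must be a named list with exactly one entry per category",
         call. = FALSE)
  functions <- functions[FCB_CATEGORIES]
  for (cat in FCB_CATEGORIES) {
    fn <- functions[[cat]]
    if (!inherits(fn, "membership_function") || fn$category != cat)
      stop(sprintf("functions$%s must be a membership_function of category '%s'",
                   cat, cat), call. = FALSE)
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2 || anyNA(domain) || domain[1] >= domain[2])
    stop("domain must be c(lo, hi) with lo < hi", call. = FALSE)
  fam <- structure(list(trait_id = trait_id, functions = functions,
                        domain = domain, provenance = provenance),
                   class = "fuzzy_set_family")
  validate_family(fam)
  fam
}

#' @rdname fuzzy_set_family
#' @param family a `fuzzy_set_family` to validate.
#' @param n_grid grid resolution for the overlap and coverage checks.
#' @export
validate_family <- function(family, n_grid = 512L) {
  stopifnot(inherits(family, "fuzzy_set_family"))
  grid <- seq(family$domain[1], family$domain[2], length.out = n_grid)
  degs <- vapply(family$functions,
                 function(fn) evaluate_membership(fn, grid), numeric(n_grid))
  if (any(degs < 0 | degs > 1))
    stop("membership degrees outside [0, 1]", call. = FALSE)
  if (any(apply(degs, 1, max) <= 0))
    stop(sprintf("family '%s' does not cover its value domain",
                 family$trait_id), call. = FALSE)
  for (k in seq_len(length(FCB_CATEGORIES) - 1)) {
    both <- pmin(degs[, k], degs[, k + 1])
    if (max(both) <= 0)
      stop(sprintf("family '%s': categories '%s' and '%s' do not overlap",
                   family$trait_id, FCB_CATEGORIES[k], FCB_CATEGORIES[k + 1]),
           call. = FALSE)
  }
  invisible(family)
}

#' Build a fuzzy-set family from the observed trait distribution
#'
#' Anchors the family to the quartiles of the observed values: the `low`
#' plateau ends at the 25th percentile, the `very_high` plateau begins at
#' the 75th percentile, the `medium` apex sits at the median, and the
#' `high` apex midway between the median and the upper quartile.  All
#' shoulders have width `fuzziness * IQR`; larger `fuzziness` means more
#' overlap between neighbouring categories (more uncertainty in assigning
#' a level of potential).  Quantiles use the linear-interpolation
#' convention (type 7).
#'
#' With the default `fuzziness = 0.5` the overlap and coverage invariants
#' hold for any non-degenerate sample; smaller values can leave coverage
#' gaps on skewed samples, in which case construction fails.
#'
#' @param values numeric vector of at least 4 finite observations, not all
#'   identical and with a positive interquartile range.
#' @param fuzziness shoulder width as a fraction of the IQR, in (0, 1).
#' @param trait_id key stored on the returned family.
#' @return a [fuzzy_set_family()] whose domain is the observed range.
#' @examples
#' fam <- build_family_from_quantiles(1:100, fuzziness = 0.5, trait_id = "demo")
#' evaluate_membership(fam$functions$low, 10)
#' @export
build_family_from_quantiles <- function(values, fuzziness = 0.5,
                                        trait_id = "trait") {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (length(values) < 4)
    stop("need at least 4 values to anchor quartiles", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("degenerate distribution: all values identical", call. = FALSE)
  if (!is.numeric(fuzziness) || fuzziness <= 0 || fuzziness >= 1)
    stop("fuzziness must lie in (0, 1)", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr <= 0)
    stop("degenerate distribution: interquartile range is zero", call. = FALSE)
  w <- fuzziness * iqr
  vmin <- min(values); vmax <- max(values)
  apex_high <- (q[2] + q[3]) / 2
  fns <- list(
    low = membership_function("low", "trapezoid",
                              c(vmin, vmin, q[1], q[1] + w)),
    medium = membership_function("medium", "triangular",
                                 c(q[2] - w, q[2], q[2] + w)),
    high = membership_function("high", "triangular",
                               c(apex_high - w, apex_high, apex_high + w)),
    very_high = membership_function("very_high", "trapezoid",
                                    c(q[3] - w, q[3], vmax, vmax))
  )
  fuzzy_set_family(trait_id, fns, domain = c(vmin, vmax),
                   provenance = sprintf("quantile recipe (fuzziness = %g)",
                                        fuzziness))
}

#' Fuzzify a crisp trait value
#'
#' Evaluates all four category memberships for `x` and retains only the
#' categories whose degree strictly exceeds the retention floor (default
#' 0.2), so a trait value can belong to several overlapping sets at once.
#' Values outside the family's domain are clamped to it (real trait
#' tables contain outliers; clamping keeps scoring deterministic).  A
#' missing value returns a distinguished missing-marker which the
#' inference engine translates into the low-potential penalty.
#'
#' @param x a single trait value, or `NA` for missing.
#' @param family a [fuzzy_set_family()].
#' @param floor retention floor; degrees `<= floor` are dropped.
#' @param warn_clamp warn when a value is clamped into the domain.
#' @return a `category_memberships` object (named degrees over the
#'   retained categories), or a `missing_trait` marker when `x` is `NA`.
#' @export
fuzzify <- function(x, family, floor = 0.2, warn_clamp = TRUE) {
  stopifnot(inherits(family, "fuzzy_set_family"))
  if (length(x) != 1L)
    stop("fuzzify() takes one value at a time", call. = FALSE)
  if (is.na(x))
    return(structure(list(trait_id = family$trait_id),
                     class = "missing_trait"))
  x <- as.numeric(x)
  if (!is.finite(x)) stop("x must be finite or NA", call. = FALSE)
  if (x < family$domain[1] || x > family$domain[2]) {
    if (warn_clamp)
      warning(sprintf("trait '%s': value %g outside domain [%g, %g], clamped",
                      family$trait_id, x, family$domain[1], family$domain[2]),
              call. = FALSE)
    x <- min(max(x, family$domain[1]), family$domain[2])
  }
  degrees <- vapply(family$functions,
                    function(fn) evaluate_membership(fn, x), numeric(1))
  degrees <- degrees[degrees > floor]
  structure(list(trait_id = family$trait_id, degrees = degrees),
            class = "category_memberships")
}

#' @export
print.membership_function <- function(x, ...) {
  cat(sprintf("<membership_function> %s (%s): [%s]\n", x$category, x$shape,
              paste(signif(x$breakpoints, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.fuzzy_set_family <- function(x, ...) {
  cat(sprintf("<fuzzy_set_family> trait '%s', domain [%g, %g] (%s)\n",
              x$trait_id, x$domain[1], x$domain[2], x$provenance))
  for (fn in x$functions) print(fn)
  invisible(x)
}
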
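#' Rank species by score
#'
#' Descending-score ranks (best = 1); ties receive midranks, so the ranks
#' always sum to `n(n+1)/2`.
#'
#' @param scores numeric vector of index scores (higher = better), or a
#'   [score_table()] data frame together with `index`.
#' @param index when `scores` is a data frame: `"F"`, `"C"`, `"B"`, or
#'   `"mean"` for the overall rank based on the mean score.
#' @return numeric vector of ranks, named by species when available.
#' @export
rank_species <- function(scores, index = c("F", "C", "B", "mean")) {
  if (is.data.frame(scores)) {
    index <- match.arg(index)
    col <- c(F = "f_score", C = "c_score", B = "b_score",
             mean = "mean_score")[[index]]
    v <- stats::setNames(scores[[col]], scores$species_id)
  } else v <- scores
  if (length(v) < 1) stop("need at least one score", call. = FALSE)
  rank(-v, ties.method = "average")
}

#' Full rank table across indices
#'
#' @param scores a [score_table()] data frame.
#' @return data frame with per-index and overall (mean-score) ranks,
#'   best = 1.
#' @export
rank_table <- function(scores) {
  data.frame(species_id = scores$species_id, taxon = scores$taxon,
             f_rank = rank_species(scores, "F"),
             c_rank = rank_species(scores, "C"),
             b_rank = rank_species(scores, "B"),
             overall_rank = rank_species(scores, "mean"),
             stringsAsFactors = FALSE)
}

#' Kendall rank correlation between two indices
#'
#' Tie-corrected Kendall tau-b with a p-value from the exact null
#' distribution of the Kendall statistic when `n <= 10` and there are no
#' ties, and from the normal approximation with tie correction
#' otherwise.  Kendall correlations are preferred over Pearson for small
#' samples of non-normal scores, which is the situation these indices
#' are in.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @return data frame with `tau` and `p_value`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector", call. = FALSE)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = (n <= 10 && !has_ties)))
  data.frame(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Pairwise Kendall correlations among the F, C, B indices
#'
#' @param scores a [score_table()] data frame.
#' @return data frame with one row per index pair.
#' @export
index_correlations <- function(scores) {
  cols <- c(F = "f_score", C = "c_score", B = "b_score")
  pairs <- utils::combn(names(cols), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    kt <- kendall_tau(scores[[cols[[a]]]], scores[[cols[[b]]]])
    cbind(data.frame(pair = paste0(a, "-", b)), kt)
  }))
}

# Dunn's post-hoc z tests on the joint ranks underlying a
# Kruskal-Wallis comparison, with tie correction; written out here
# because no post-hoc package is part of this package's dependency set.
dunn_posthoc <- function(v, g, p_adjust = "holm") {
  N <- length(v)
  r <- rank(v)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- levels(g)
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  pairs <- utils::combn(groups, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Compare index scores across taxonomic groups
#'
#' Kruskal-Wallis rank-sum test (tie-corrected H) followed by Dunn's
#' pairwise post-hoc z tests on the same joint ranks, with multiplicity
#' adjustment (default Holm).  Identical scores everywhere are a
#' degenerate comparison and return `H = 0, p = 1` by convention.
#'
#' @param scores numeric vector of index scores.
#' @param taxa group labels, one per score; at least 2 groups with at
#'   least 2 members each.
#' @param p_adjust multiplicity adjustment for the Dunn comparisons:
#'   `"holm"` (default), `"bonferroni"`, `"BH"`, or `"none"`.
#' @return list with `kruskal` (data frame: `H`, `df`, `p_value`) and
#'   `dunn` (pairwise data frame: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
group_compare <- function(scores, taxa, p_adjust = "holm") {
  if (length(scores) != length(taxa))
    stop("scores and taxa must have equal length", call. = FALSE)
  g <- droplevels(factor(taxa))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2))
    stop("every group needs at least 2 members", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    kr <- data.frame(H = 0, df = nlevels(g) - 1L, p_value = 1)
    dn <- dunn_posthoc(scores, g, p_adjust)
    return(list(kruskal = kr, dunn = dn))
  }
  kt <- stats::kruskal.test(scores, g)
  list(kruskal = data.frame(H = unname(kt$statistic),
                            df = unname(kt$parameter),
                            p_value = kt$p.value),
       dunn = dunn_posthoc(scores, g, p_adjust))
}

#' Compare an extreme subset of species against the full set
#'
#' Tests whether the mean score of the `k` highest- (or lowest-) ranked
#' species differs from what a random subset of `k` species would show,
#' via a permutation test on the mean difference: the observed
#' `mean(extreme k) - mean(all)` is compared with the null distribution
#' of the same statistic over random `k`-subsets.  One-sided by
#' construction (`greater` for the top subset, `less` for the bottom).
#'
#' @param scores numeric vector of index scores.
#' @param k subset size, `k < n`; default 10.
#' @param which `"top"` or `"bottom"`.
#' @param n_perm number of random subsets drawn for the null.
#' @param seed optional integer seed.
#' @return data frame with `k`, `which`, `mean_subset`, `mean_all`,
#'   `statistic` (the mean difference), and `p_value` (with the +1
#'   permutation correction).
#' @export
extreme_subset_test <- function(scores, k = 10, which = c("top", "bottom"),
                                n_perm = 10000, seed = NULL) {
  which <- match.arg(which)
  n <- length(scores)
  if (!is.numeric(k) || k < 1 || k >= n)
    stop("k must satisfy 1 <= k < n", call. = FALSE)
  k <- as.integer(k)
  ord <- sort(scores, decreasing = (which == "top"))
  obs <- mean(ord[seq_len(k)]) - mean(scores)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i)
    mean(sample(scores, k)) - mean(scores), numeric(1))
  extreme_count <- if (which == "top") sum(null_stats >= obs)
                   else sum(null_stats <= obs)
  data.frame(k = k, which = which,
             mean_subset = mean(ord[seq_len(k)]), mean_all = mean(scores),
             statistic = obs,
             p_value = (1 + extreme_count) / (n_perm + 1))
}
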
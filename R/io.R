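#' Read a species-by-trait table from CSV
#'
#' Expects a header row with `species_id`, `taxon`, then one numeric
#' column per trait; empty cells are missing values.  Column order does
#' not matter.  When a rulebook is supplied, trait columns it does not
#' declare are rejected by name; non-numeric cells raise an error naming
#' the row and column.  Decimal separator is always the dot.
#'
#' @param path CSV path; lines starting with `#` are ignored.
#' @param rb optional [rulebook()] used to vet the trait columns.
#' @return data frame of typed species records.
#' @export
read_trait_table <- function(path, rb = NULL) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  mandatory <- c("species_id", "taxon")
  absent <- setdiff(mandatory, names(raw))
  if (length(absent))
    stop("trait table lacks mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  trait_cols <- setdiff(names(raw), mandatory)
  if (!is.null(rb)) {
    unknown <- setdiff(trait_cols, names(rb$traits))
    if (length(unknown))
      stop("unknown trait column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  out <- raw[mandatory]
  for (col in trait_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   raw[[col]][bad[1]], col, bad[1]), call. = FALSE)
    out[[col]] <- v
  }
  out
}

provenance_header <- function(rb, seed) {
  c(sprintf("# fcbscore %s",
            as.character(utils::packageVersion("fcbscore"))),
    sprintf("# rulebook_hash: %s",
            if (is.null(rb)) "none" else rulebook_hash(rb)),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed))
}

#' Write a data frame as CSV with a provenance header
#'
#' Output files carry `#` comment lines recording the package version,
#' the rulebook content hash, and the seed, so every artifact is
#' traceable to the exact configuration that produced it.  Numeric
#' columns are written with full (round-trip) precision.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param rb optional [rulebook()] for the hash line.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, rb = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(rb, seed), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    vapply(v, function(x) if (is.na(x)) "" else
      format(x, digits = 17, scientific = FALSE, trim = TRUE), character(1)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  check.names = FALSE, na.strings = c("", "NA"))
}

#' Run the full scoring pipeline
#'
#' Orchestrates score -> sensitivity -> statistics on one trait table and
#' rulebook, writing every artifact to `out_dir`: `scores.csv`,
#' `memberships.csv` (long-format accumulated memberships),
#' `ranks.csv`, `correlations.csv`, `group_tests.csv`, `dunn_tests.csv`,
#' `jackknife_deviations.csv`, and `jackknife_summary.csv`.  Every file
#' carries the provenance header (version, rulebook hash, seed); the run
#' is deterministic given the seed.
#'
#' @param traits_csv path to the trait table, or a data frame.
#' @param rb a [rulebook()], a path to a rulebook YAML, or `NULL` for
#'   the shipped [default_rulebook()].
#' @param out_dir output directory, created if needed.
#' @param stages subset of `c("score", "jackknife", "stats")`.
#' @param seed integer seed for the stochastic stages.
#' @param jackknife_reps replicates for the multi-trait jackknife.
#' @param jackknife_n_remove traits removed per replicate; `NULL` skips
#'   the multi-trait stage and runs only the exhaustive single-trait
#'   analysis.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(traits_csv, rb = NULL, out_dir = ".",
                         stages = c("score", "jackknife", "stats"),
                         seed = 1, jackknife_reps = 50,
                         jackknife_n_remove = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(rb)) rb <- read_rulebook(rb)
  if (is.null(rb)) rb <- default_rulebook()
  table <- if (is.data.frame(traits_csv)) traits_csv
           else read_trait_table(traits_csv, rb)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rb <- fit_families(rb, table)
  results <- list(rulebook_hash = rulebook_hash(rb))
  message(sprintf("[score] scoring %d species with %d traits, %d rules",
                  nrow(table), length(rb$traits), nrow(rb$rules)))
  scores <- score_table(table, rb)
  results$scores <- scores
  if ("score" %in% stages) {
    write_table_csv(scores, file.path(out_dir, "scores.csv"), rb, seed)
    write_table_csv(attr(scores, "memberships"),
                    file.path(out_dir, "memberships.csv"), rb, seed)
  }
  if ("jackknife" %in% stages) {
    message("[jackknife] exhaustive single-trait removal")
    jk <- jackknife_single(table, rb)
    results$jackknife_single <- jk
    write_table_csv(jk$deviations,
                    file.path(out_dir, "jackknife_deviations.csv"), rb, seed)
    write_table_csv(jk$summary,
                    file.path(out_dir, "jackknife_summary.csv"), rb, seed)
    if (!is.null(jackknife_n_remove)) {
      message(sprintf("[jackknife] %d random removals of %d traits",
                      jackknife_reps, jackknife_n_remove))
      jm <- jackknife_multi(table, rb, n_remove = jackknife_n_remove,
                            reps = jackknife_reps, seed = seed)
      results$jackknife_multi <- jm
      write_table_csv(jm$deviations,
                      file.path(out_dir, "jackknife_multi_deviations.csv"),
                      rb, seed)
    }
  }
  if ("stats" %in% stages) {
    message("[stats] ranks, correlations, group comparisons")
    ranks <- rank_table(scores)
    corrs <- index_correlations(scores)
    write_table_csv(ranks, file.path(out_dir, "ranks.csv"), rb, seed)
    write_table_csv(corrs, file.path(out_dir, "correlations.csv"), rb, seed)
    results$ranks <- ranks
    results$correlations <- corrs
    if (length(unique(table$taxon)) >= 2 && all(table(table$taxon) >= 2)) {
      gc_rows <- list(); dunn_rows <- list()
      for (idx in c("F", "C", "B")) {
        col <- c(F = "f_score", C = "c_score", B = "b_score")[[idx]]
        g <- group_compare(scores[[col]], scores$taxon)
        gc_rows[[idx]] <- cbind(data.frame(index = idx), g$kruskal)
        dunn_rows[[idx]] <- cbind(data.frame(index = idx), g$dunn)
      }
      results$group_tests <- do.call(rbind, gc_rows)
      results$dunn_tests <- do.call(rbind, dunn_rows)
      write_table_csv(results$group_tests,
                      file.path(out_dir, "group_tests.csv"), rb, seed)
      write_table_csv(results$dunn_tests,
                      file.path(out_dir, "dunn_tests.csv"), rb, seed)
    } else {
      message("[stats] skipping group comparison: need >= 2 taxa with >= 2 members")
    }
  }
  invisible(results)
}
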
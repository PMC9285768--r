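#' Synthetic literature-review observation table
#'
#' Emulates the aggregate classification of a review of warming effects on
#' zooplankton community size structure: 164 observations (from 136
#' articles) classified by level (interspecific vs intraspecific), study
#' design (experimental vs observational) and outcome (shift to smaller,
#' shift to larger, or no effect). The level-by-outcome marginals are the
#' published counts: interspecific 123 = 91 smaller + 14 larger + 18 none;
#' intraspecific 41 = 20 smaller + 17 larger + 4 none. The per-design split
#' within each cell is not published and is synthetic, fixed so that the
#' excess of smaller-shift observations is strongest among observational
#' studies; the seed controls only the assignment of observation ids to
#' cells.
#'
#' @param seed integer seed for the id assignment.
#' @return data frame with columns \code{observation_id}, \code{level},
#'   \code{design}, \code{outcome}; attribute \code{n_articles} = 136.
#' @export
generate_review_fixture <- function(seed = 1) {
  cells <- data.frame(
    level = rep(c("interspecific", "intraspecific"), each = 6),
    design = rep(c("observational", "experimental"), 6),
    outcome = rep(rep(c("smaller", "larger", "none"), each = 2), 2),
    # published level x outcome marginals; design split synthetic
    n = c(68, 23, 6, 8, 12, 6,   # interspecific: 91 smaller, 14 larger, 18 none
          9, 11, 8, 9, 2, 2)     # intraspecific: 20 smaller, 17 larger, 4 none
  )
  stopifnot(sum(cells$n) == 164)
  rows <- cells[rep(seq_len(nrow(cells)), cells$n), c("level", "design", "outcome")]
  set.seed(seed)
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rows$observation_id <- sprintf("obs%03d", seq_len(nrow(rows)))
  rows <- rows[, c("observation_id", "level", "design", "outcome")]
  rownames(rows) <- NULL
  attr(rows, "n_articles") <- 136
  attr(rows, "design_split") <- "synthetic"
  rows
}

#' Tally a review observation table
#'
#' Exact counts by level, design and outcome with cross-checked totals.
#'
#' @param table a data frame with columns \code{level}, \code{design},
#'   \code{outcome} (as from [generate_review_fixture()]).
#' @return list with \code{total}, \code{by_level} (named totals),
#'   \code{by_level_outcome} (level x outcome matrix) and \code{counts}
#'   (level x design x outcome contingency table).
#' @export
tally_review <- function(table) {
  need <- c("level", "design", "outcome")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- list(level = c("interspecific", "intraspecific"),
             design = c("experimental", "observational"),
             outcome = c("smaller", "larger", "none"))
  for (col in need) {
    bad <- which(!table[[col]] %in% ok[[col]])
    if (length(bad) > 0)
      stop(sprintf("invalid %s value '%s' in row %d", col,
                   table[[col]][bad[1]], bad[1]))
  }
  lv <- factor(table$level, ok$level)
  ds <- factor(table$design, ok$design)
  oc <- factor(table$outcome, ok$outcome)
  counts <- table(level = lv, design = ds, outcome = oc)
  by_level <- as.vector(table(lv)); names(by_level) <- ok$level
  by_level_outcome <- table(level = lv, outcome = oc)
  total <- nrow(table)
  stopifnot(sum(by_level) == total, sum(by_level_outcome) == total)
  list(total = total, by_level = by_level,
       by_level_outcome = by_level_outcome, counts = counts)
}
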
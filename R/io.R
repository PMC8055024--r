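#' Winner-loser interaction matrix
#'
#' The interchange format between the simulator, the hierarchy metrics
#' and the synthetic generator: a square non-negative integer matrix in
#' which entry `[i, j]` counts the decided fights individual `i` won
#' over individual `j`, together with individual identifiers and sexes.
#'
#' @param counts square integer matrix, zero diagonal.
#' @param ids character vector of identifiers; defaults to the row
#'   names of `counts`.
#' @param sexes character vector (`"male"`/`"female"`); if missing,
#'   inferred from the leading letter of each id (`"m..."`/`"f..."`).
#' @return An object of class `interaction_matrix`.
#' @examples
#' m <- interaction_matrix(rbind(c(0, 3), c(1, 0)), ids = c("m1", "f1"))
#' m$sexes
#' @export
interaction_matrix <- function(counts, ids = rownames(counts), sexes = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (is.null(ids)) ids <- sprintf("i%d", seq_len(nrow(counts)))
  ids <- as.character(ids)
  if (length(ids) != nrow(counts)) stop("ids length must match matrix dimension")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (is.null(sexes)) sexes <- .sex_from_id(ids)
  sexes <- as.character(sexes)
  if (length(sexes) != length(ids)) stop("sexes length must match ids")
  if (!all(sexes %in% c("male", "female")))
    stop("sexes must be 'male' or 'female'")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; first offending cell [%d, %d]",
                 bad[1, 1], bad[1, 2]))
  if (any(diag(counts) != 0)) stop("diagonal must be zero")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, ids)
  structure(list(ids = ids, sexes = sexes, counts = counts),
            class = "interaction_matrix")
}

.sex_from_id <- function(ids) {
  first <- tolower(substr(ids, 1, 1))
  if (!all(first %in% c("m", "f")))
    stop("cannot infer sexes: ids must start with 'm' or 'f' (e.g. \"m1\", \"f2\")")
  ifelse(first == "m", "male", "female")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("Interaction matrix: %d individuals (%d males, %d females), %d fights\n",
              length(x$ids), sum(x$sexes == "male"),
              sum(x$sexes == "female"), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @export
dim.interaction_matrix <- function(x) dim(x$counts)

#' Write an interaction matrix to CSV
#'
#' Plain-text layout: a header row of ids, then one row per individual
#' with its id in the first column. Sexes are carried by the id naming
#' convention (ids starting with `m`/`f`).
#'
#' @param m an [interaction_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  if (!inherits(m, "interaction_matrix")) stop("m must be an interaction_matrix")
  df <- data.frame(id = m$ids, m$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interaction matrix from CSV
#'
#' Inverse of [write_interaction_matrix()]: expects a square layout with
#' identical row and column ids and non-negative integer cells; sexes
#' are inferred from the id prefix (`m`/`f`).
#'
#' @param path CSV file.
#' @return An [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs an id column plus count columns")
  ids_row <- as.character(df[[1]])
  ids_col <- colnames(df)[-1]
  if (length(ids_row) != length(ids_col))
    stop(sprintf("non-square matrix: %d rows vs %d columns",
                 length(ids_row), length(ids_col)))
  mism <- which(ids_row != ids_col)
  if (length(mism) > 0)
    stop(sprintf("row/column id mismatch at position %d: '%s' vs '%s'",
                 mism[1], ids_row[mism[1]], ids_col[mism[1]]))
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(apply(counts, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at [%d, %d]", bad[1, 1], bad[1, 2]))
  }
  interaction_matrix(counts, ids = ids_row)
}

#' Packaged field summaries: capuchin group-periods
#'
#' Loads the two tables of per-group-period summaries from three wild
#' populations of robust capuchin monkeys (genus *Sapajus*) that ship
#' with the package: `periods` (site, group, study period, adult
#' composition, observation hours) and `summaries` (proportion of males,
#' adult counts, female dominance index `fd`, the sex-classed aggression
#' fractions `mm_ago` = male-male aggression per total male aggression
#' and `fm_ago` = female-male aggression per total female aggression,
#' number of decided aggressive interactions, and the percentage of
#' dyads with no observed interaction). Both tables cover the same 14
#' group-periods; `n_females` is derived as adults minus males, and the
#' printed proportion of males is checked against `n_males / adults`.
#'
#' @return A list of class `capuchin_tables` with data frames `periods`
#'   and `summaries`.
#' @examples
#' tab <- load_capuchin_tables()
#' nrow(tab$summaries)
#' @export
load_capuchin_tables <- function() {
  f2 <- system.file("extdata", "capuchin_group_periods.csv",
                    package = "domhier", mustWork = TRUE)
  f3 <- system.file("extdata", "capuchin_dominance_summaries.csv",
                    package = "domhier", mustWork = TRUE)
  periods <- utils::read.csv(f2, stringsAsFactors = FALSE)
  summaries <- utils::read.csv(f3, stringsAsFactors = FALSE)
  need2 <- c("site", "group", "study_period", "n_males", "n_females", "hours")
  need3 <- c("site", "group", "period", "prop_males", "n_adults", "n_males",
             "fd", "mm_ago", "fm_ago", "n_interactions", "pct_unknown")
  m2 <- setdiff(need2, names(periods))
  if (length(m2) > 0) stop("periods table missing column(s): ",
                           paste(m2, collapse = ", "))
  m3 <- setdiff(need3, names(summaries))
  if (length(m3) > 0) stop("summaries table missing column(s): ",
                           paste(m3, collapse = ", "))
  if (nrow(periods) != 14 || nrow(summaries) != 14)
    stop("packaged tables must each have 14 group-period rows")
  summaries$n_females <- summaries$n_adults - summaries$n_males
  if (any(abs(summaries$prop_males -
              summaries$n_males / summaries$n_adults) > 0.005 + 1e-9))
    stop("prop_males inconsistent with n_males / n_adults")
  if (any(summaries$fd < 0 | summaries$fd > 1))
    stop("fd must lie in [0, 1]")
  structure(list(periods = periods, summaries = summaries),
            class = "capuchin_tables")
}

#' @export
print.capuchin_tables <- function(x, ...) {
  cat("Capuchin group-period tables:",
      nrow(x$summaries), "group-periods,",
      length(unique(x$summaries$site)), "sites,",
      sum(x$periods$hours), "observation hours\n")
  invisible(x)
}
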
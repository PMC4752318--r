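# Reading, validating and writing the labeled-matrix dialect used by the
# public drug-target benchmark files: tab-separated, first row column labels
# (with an optional corner token), first column row labels, numeric body.

#' Read a labeled tab-separated matrix
#'
#' Parses the benchmark dialect: a header line of column labels (an optional
#' corner token is tolerated), then one line per row beginning with the row
#' label followed by numeric cells. The canonical in-memory orientation puts
#' drugs on rows; the public benchmark files are target-major, so
#' `orientation = "rows_are_targets"` transposes on read.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @param orientation `"rows_are_drugs"` (default, file kept as is) or
#'   `"rows_are_targets"` (file transposed so drugs index rows).
#' @return a numeric matrix with row and column labels as `dimnames`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_labeled_matrix(matrix(1:6 / 10, 2, 3,
#'   dimnames = list(c("d1", "d2"), c("t1", "t2", "t3"))), tf)
#' read_labeled_matrix(tf)
read_labeled_matrix <- function(path, orientation = c("rows_are_drugs", "rows_are_targets")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_io("cannot read labeled matrix: no such file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  while (length(lines) > 0 && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 2) stop_parse("file '%s' has no data rows", path)

  toks <- strsplit(lines, "\t", fixed = TRUE)
  body <- toks[-1]
  widths <- lengths(body)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop_parse("ragged row in '%s': line %d has %d cells but line 2 has %d",
               path, bad + 1L, widths[bad], widths[1])
  }
  ncol_body <- widths[1] - 1L
  if (ncol_body < 1) stop_parse("file '%s' has rows without data cells", path)

  header <- toks[[1]]
  # header may or may not carry a corner token above the row-label column
  if (length(header) == ncol_body + 1L) header <- header[-1]
  if (length(header) != ncol_body) {
    stop_parse("header of '%s' has %d labels but rows have %d data cells",
               path, length(header), ncol_body)
  }

  row_labels <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(row_labels)) {
    stop_validation("duplicate row labels in '%s': %s", path,
                    paste(unique(row_labels[duplicated(row_labels)]), collapse = ", "))
  }
  if (anyDuplicated(header)) {
    stop_validation("duplicate column labels in '%s': %s", path,
                    paste(unique(header[duplicated(header)]), collapse = ", "))
  }

  cells <- vapply(body, function(tk) {
    suppressWarnings(as.numeric(tk[-1]))
  }, numeric(ncol_body))
  # vapply gives cells as ncol x nrow; transpose to rows-in-file orientation
  mat <- if (ncol_body == 1L) matrix(cells, ncol = 1L) else t(cells)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_parse("non-numeric cell in '%s' at row '%s' (line %d), column '%s'",
               path, row_labels[bad[1]], bad[1] + 1L, header[bad[2]])
  }
  dimnames(mat) <- list(row_labels, header)
  if (orientation == "rows_are_targets") mat <- t(mat)
  mat
}

#' Write a labeled matrix in the benchmark tab-separated dialect
#'
#' Inverse of [read_labeled_matrix()]: header line with an empty corner
#' token, then row label plus cells. Values are written with 17 significant
#' digits so doubles round-trip exactly.
#'
#' @param mat numeric matrix with complete `dimnames`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(mat, path) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_validation("matrix must carry row and column labels to be written")
  }
  lines <- c(
    paste(c("", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format_num(mat[i, ])), collapse = "\t")
    }, character(1))
  )
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write labeled matrix to '%s'", path)
  invisible(path)
}

#' Construct a drug-target interaction dataset
#'
#' Bundles the binary interaction matrix `Y` (drugs on rows, targets on
#' columns), the drug-drug chemical similarity matrix `Sd` and the
#' target-target sequence similarity matrix `St`, validating shapes, the
#' 0/1 coding of `Y` and the `[0, 1]` range of similarities. Similarity
#' diagonals are overwritten to 1: self-similarity is definitional and
#' neighborhoods exclude self regardless.
#'
#' @param Y binary numeric matrix, drugs x targets, entries in \{0, 1\}.
#' @param Sd drug similarity matrix, entries in `[0, 1]`.
#' @param St target similarity matrix, entries in `[0, 1]`.
#' @param drug_ids,target_ids identifier vectors; default taken from the
#'   `dimnames` of `Y`.
#' @return an object of class `dti_dataset`.
#' @export
dti_dataset <- function(Y, Sd, St,
                        drug_ids = rownames(Y), target_ids = colnames(Y)) {
  Y <- as.matrix(Y); Sd <- as.matrix(Sd); St <- as.matrix(St)
  storage.mode(Y) <- "double"
  storage.mode(Sd) <- "double"
  storage.mode(St) <- "double"
  m <- nrow(Y); n <- ncol(Y)
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(m))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(n))
  if (anyNA(Y) || anyNA(Sd) || anyNA(St)) {
    stop_validation("dataset matrices must not contain missing values")
  }
  if (!all(Y %in% c(0, 1))) {
    bad <- which(!(Y %in% c(0, 1)))[1]
    ij <- arrayInd(bad, dim(Y))
    stop_validation("Y must be binary; entry (%s, %s) is %g",
                    drug_ids[ij[1]], target_ids[ij[2]], Y[bad])
  }
  if (nrow(Sd) != m || ncol(Sd) != m) {
    stop_validation("Sd must be %d x %d to match the %d drugs of Y", m, m, m)
  }
  if (nrow(St) != n || ncol(St) != n) {
    stop_validation("St must be %d x %d to match the %d targets of Y", n, n, n)
  }
  if (any(Sd < 0 | Sd > 1) || any(St < 0 | St > 1)) {
    stop_validation("similarity entries must lie in [0, 1]")
  }
  diag(Sd) <- 1
  diag(St) <- 1
  dimnames(Y) <- list(drug_ids, target_ids)
  dimnames(Sd) <- list(drug_ids, drug_ids)
  dimnames(St) <- list(target_ids, target_ids)
  structure(
    list(drug_ids = as.character(drug_ids), target_ids = as.character(target_ids),
         Y = Y, Sd = Sd, St = St),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat(sprintf("<dti_dataset> %d drugs x %d targets, %d known interactions (%.2f%% sparse)\n",
              length(x$drug_ids), length(x$target_ids), sum(x$Y),
              100 * (1 - sum(x$Y) / length(x$Y))))
  invisible(x)
}

#' Load a dataset from three labeled matrix files
#'
#' Reads the interaction matrix and the two similarity matrices, aligns the
#' similarity labels to the order of the interaction matrix (files whose rows
#' are a permutation are reordered, any label mismatch is an error naming the
#' symmetric difference) and validates everything through [dti_dataset()].
#'
#' @param y_path path to the interaction matrix file.
#' @param sd_path path to the drug similarity file.
#' @param st_path path to the target similarity file.
#' @param orientation orientation of the interaction file, see
#'   [read_labeled_matrix()]; similarity files are square and label-aligned,
#'   so the flag applies to `Y` only.
#' @return a `dti_dataset`.
#' @export
load_dataset <- function(y_path, sd_path, st_path,
                         orientation = c("rows_are_drugs", "rows_are_targets")) {
  orientation <- match.arg(orientation)
  Y <- read_labeled_matrix(y_path, orientation)
  Sd <- read_labeled_matrix(sd_path)
  St <- read_labeled_matrix(st_path)

  align <- function(S, ids, what, path) {
    missing_ids <- setdiff(ids, rownames(S))
    extra_ids <- setdiff(rownames(S), ids)
    if (length(missing_ids) > 0 || length(extra_ids) > 0) {
      stop_validation(
        "%s labels in '%s' do not match Y: missing {%s}, unexpected {%s}",
        what, path, paste(missing_ids, collapse = ", "),
        paste(extra_ids, collapse = ", "))
    }
    if (!identical(sort(rownames(S)), sort(colnames(S)))) {
      stop_validation("%s matrix in '%s' must carry the same row and column labels",
                      what, path)
    }
    S[ids, ids, drop = FALSE]
  }

  Sd <- align(Sd, rownames(Y), "drug similarity", sd_path)
  St <- align(St, colnames(Y), "target similarity", st_path)
  dti_dataset(Y, Sd, St)
}

#' Index sets of entities with and without known interactions
#'
#' Drugs (rows of `Y`) with at least one known interaction form the positive
#' drug set; the remainder are "new" drugs with no training interactions.
#' Same for targets on columns. Always computed from the matrix passed in,
#' so a training-masked `Y` yields the training-time sets that drive
#' cold-start smoothing.
#'
#' @param Y binary interaction matrix (or a `dti_dataset`).
#' @return list with integer index vectors `positive_drugs`,
#'   `negative_drugs`, `positive_targets`, `negative_targets`.
#' @export
positive_sets <- function(Y) {
  if (inherits(Y, "dti_dataset")) Y <- Y$Y
  rs <- rowSums(Y); cs <- colSums(Y)
  list(
    positive_drugs = unname(which(rs > 0)),
    negative_drugs = unname(which(rs == 0)),
    positive_targets = unname(which(cs > 0)),
    negative_targets = unname(which(cs == 0))
  )
}

#' Descriptive statistics of an interaction dataset
#'
#' The eight derived quantities conventionally reported for the benchmark
#' collections: counts, interaction averages per entity, sparsity of `Y`,
#' and the percentage of drugs/targets with exactly one known interaction.
#' Stored at full precision; see [format_dataset_stats()] for the 2-decimal
#' display convention.
#'
#' @param ds a `dti_dataset`.
#' @return a one-row tibble.
#' @export
compute_dataset_stats <- function(ds) {
  Y <- ds$Y
  m <- nrow(Y); n <- ncol(Y); k <- sum(Y)
  tibble::tibble(
    n_drugs = m,
    n_targets = n,
    n_interactions = k,
    avg_drugs_per_target = if (n > 0) k / n else 0,
    avg_targets_per_drug = if (m > 0) k / m else 0,
    sparsity_pct = if (m * n > 0) 100 * (1 - k / (m * n)) else 100,
    pct_drugs_one_interaction = if (m > 0) 100 * sum(rowSums(Y) == 1) / m else 0,
    pct_targets_one_interaction = if (n > 0) 100 * sum(colSums(Y) == 1) / n else 0
  )
}

#' Format dataset statistics for display
#'
#' Rounds the derived statistics half-up to two decimals, matching the
#' convention of the benchmark summary tables.
#'
#' @param stats one-row tibble from [compute_dataset_stats()].
#' @return a two-column tibble (`statistic`, `value`) of formatted strings.
#' @export
format_dataset_stats <- function(stats) {
  tibble::tibble(
    statistic = c(
      "Number of drugs", "Number of targets", "Number of interaction pairs",
      "Average number of drugs per target", "Average number of targets per drug",
      "Sparsity of the interaction matrix",
      "Percentage of drugs that have only one interaction target",
      "Percentage of targets that have only one interaction drug"),
    value = c(
      as.character(stats$n_drugs), as.character(stats$n_targets),
      as.character(stats$n_interactions),
      sprintf("%.2f", round_half_up(stats$avg_drugs_per_target)),
      sprintf("%.2f", round_half_up(stats$avg_targets_per_drug)),
      sprintf("%.2f%%", round_half_up(stats$sparsity_pct)),
      sprintf("%.2f%%", round_half_up(stats$pct_drugs_one_interaction)),
      sprintf("%.2f%%", round_half_up(stats$pct_targets_one_interaction)))
  )
}

#' Write a prediction ranking to a tab-separated file
#'
#' @param ranking tibble with columns `rank`, `drug_id`, `target_id`,
#'   `probability`, sorted by descending probability (as produced by
#'   [rank_novel_interactions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ranking, path) {
  need <- c("rank", "drug_id", "target_id", "probability")
  if (!all(need %in% names(ranking))) {
    stop_validation("ranking must have columns %s", paste(need, collapse = ", "))
  }
  if (is.unsorted(rev(ranking$probability))) {
    stop_validation("ranking must be sorted by descending probability")
  }
  lines <- c(
    "rank\tdrug_id\ttarget_id\tprobability",
    sprintf("%d\t%s\t%s\t%.6f", ranking$rank, ranking$drug_id,
            ranking$target_id, ranking$probability)
  )
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write predictions to '%s'", path)
  invisible(path)
}

#' Read a prediction ranking written by [write_predictions()]
#'
#' @param path path to the tab-separated ranking file.
#' @return a tibble with columns `rank`, `drug_id`, `target_id`, `probability`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_io("no such prediction file '%s'", path)
  df <- utils::read.delim(path, colClasses = c("integer", "character", "character", "numeric"))
  tibble::as_tibble(df)
}
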
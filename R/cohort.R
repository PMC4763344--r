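#' Cohort feature table
#'
#' The tabular substrate of all cohort-level statistics: per-subject diagnosis
#' labels (`NC`, `MCI`, `AD`) plus one `N x K` feature matrix per view, all
#' interpreted against a shared [roi_atlas()].
#'
#' @param data A data frame in long layout with columns `subject_id`,
#'   `diagnosis`, `view`, then the `K` ROI columns in atlas order (named
#'   `roi_<id>`); one row per subject x view.
#' @param atlas An [roi_atlas()].
#'
#' @return An object of class `cohort_table` with elements `subjects` (a
#'   tibble of `subject_id` and `diagnosis`), `views` (a named list of
#'   `N x K` matrices) and `atlas`.
#' @seealso [read_feature_table()], [write_feature_table()],
#'   [generate_cohort()]
#' @export
cohort_table <- function(data, atlas) {
  assert_that(is_roi_atlas(atlas), "atlas must be an roi_atlas")
  data <- as.data.frame(data, check.names = FALSE)
  roi_cols <- atlas_columns(atlas)
  need <- c("subject_id", "diagnosis", "view", roi_cols)
  missing_cols <- setdiff(need, names(data))
  assert_that(length(missing_cols) == 0, class = "crossview_schema_error",
              "feature table is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  bad_dx <- setdiff(unique(as.character(data$diagnosis)), DIAGNOSIS_LEVELS)
  assert_that(length(bad_dx) == 0, class = "crossview_schema_error",
              "unknown diagnosis label(s): ", paste(bad_dx, collapse = ", "),
              " (expected NC, MCI, AD)")
  dup <- duplicated(data[c("subject_id", "view")])
  assert_that(!any(dup), class = "crossview_schema_error",
              "duplicate subject x view row(s): ",
              paste(utils::head(paste(data$subject_id[dup], data$view[dup],
                                      sep = "/"), 5), collapse = ", "))
  views <- split(seq_len(nrow(data)), data$view)
  assert_that(length(views) >= 1, class = "crossview_schema_error",
              "feature table contains no views")
  subj_tbl <- unique(data[c("subject_id", "diagnosis")])
  assert_that(!anyDuplicated(subj_tbl$subject_id),
              class = "crossview_schema_error",
              "subject(s) with conflicting diagnosis labels across rows")
  subjects <- tibble::tibble(
    subject_id = as.character(subj_tbl$subject_id),
    diagnosis = factor(subj_tbl$diagnosis, levels = DIAGNOSIS_LEVELS))
  view_mats <- lapply(views, function(rows) {
    block <- data[rows, roi_cols, drop = FALSE]
    m <- as.matrix(block)
    if (!is.numeric(m)) {
      m2 <- suppressWarnings(apply(block, 2, function(col) as.numeric(col)))
      bad <- which(is.na(m2) & !is.na(as.matrix(block)), arr.ind = TRUE)
      assert_that(nrow(bad) == 0, class = "crossview_parse_error",
                  "non-numeric feature cell at table row ", rows[bad[1, 1]],
                  ", column ", roi_cols[bad[1, 2]])
      m <- m2
      dim(m) <- dim(as.matrix(block))
    }
    assert_that(all(is.finite(m)), class = "crossview_parse_error",
                "non-finite feature values after ingestion")
    rownames(m) <- as.character(data$subject_id[rows])
    colnames(m) <- roi_cols
    # align rows to the canonical subject order
    assert_that(setequal(rownames(m), subjects$subject_id),
                class = "crossview_schema_error",
                "view '", data$view[rows[1]],
                "' does not cover the same subjects as the other views")
    m[subjects$subject_id, , drop = FALSE]
  })
  structure(list(subjects = subjects, views = view_mats, atlas = atlas),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$subjects$diagnosis)
  cat("<cohort_table> N =", nrow(x$subjects), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "); K =",
      length(x$atlas), "ROIs; M =", length(x$views), "view(s):\n  ",
      paste(names(x$views), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
#' @rdname cohort_table
#' @param x A `cohort_table`.
#' @param ... Unused.
#' @importFrom tibble as_tibble
as_tibble.cohort_table <- function(x, ...) {
  purrr::imap_dfr(x$views, function(m, vname) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = x$subjects$subject_id,
                     diagnosis = as.character(x$subjects$diagnosis),
                     view = vname),
      tibble::as_tibble(m))
  })
}

#' @rdname cohort_table
#' @export
view_names <- function(x) names(x$views)

#' Extract one view's feature matrix
#'
#' @param x A [cohort_table()].
#' @param view View name.
#' @return The `N x K` feature matrix of that view.
#' @export
view_matrix <- function(x, view) {
  assert_that(view %in% names(x$views),
              "view '", view, "' not present; available: ",
              paste(names(x$views), collapse = ", "))
  x$views[[view]]
}

#' Read / write cohort feature tables
#'
#' Feature tables travel as tab-separated UTF-8 text in long layout: a header
#' `subject_id  diagnosis  view  roi_<id>...` (ROI columns in atlas order)
#' and one row per subject x view. `write_feature_table()` emits the same
#' dialect `read_feature_table()` consumes, at 17 significant digits so a
#' round trip is value-identical.
#'
#' @param path File path.
#' @param atlas An [roi_atlas()] declaring the expected ROI columns.
#' @return `read_feature_table()` returns a [cohort_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @examples
#' atlas <- roi_atlas(1:3)
#' tab <- generate_cohort(cohort_spec(n_per_group = c(3, 3, 3), K = 3))$table
#' f <- tempfile(fileext = ".tsv")
#' write_feature_table(tab, f)
#' tab2 <- read_feature_table(f, atlas)
#' @export
read_feature_table <- function(path, atlas) {
  assert_that(file.exists(path), "feature table not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  expected <- c("subject_id", "diagnosis", "view", atlas_columns(atlas))
  assert_that(ncol(raw) == length(expected), class = "crossview_schema_error",
              "column count mismatch: file has ", ncol(raw),
              " columns, atlas implies ", length(expected),
              " (subject_id, diagnosis, view + K = ", length(atlas), " ROIs)")
  assert_that(identical(names(raw), expected), class = "crossview_schema_error",
              "header mismatch; expected columns: ",
              paste(utils::head(expected, 6), collapse = ", "), ", ...")
  cohort_table(raw, atlas)
}

#' @rdname read_feature_table
#' @param table A [cohort_table()].
#' @export
write_feature_table <- function(table, path) {
  assert_that(inherits(table, "cohort_table"), "table must be a cohort_table")
  assert_that(length(table$views) >= 1, "cohort table has no views to write")
  roi_cols <- atlas_columns(table$atlas)
  rows <- purrr::imap(table$views, function(m, vname) {
    vals <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    paste(table$subjects$subject_id, as.character(table$subjects$diagnosis),
          vname, vals, sep = "\t")
  })
  header <- paste(c("subject_id", "diagnosis", "view", roi_cols),
                  collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, unlist(rows, use.names = FALSE)), con,
             useBytes = TRUE)
  invisible(path)
}
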
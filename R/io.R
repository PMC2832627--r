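#' Read and write profile matrices as TSV
#'
#' The on-disk format is a tab-separated table with sera as rows: a header
#' line `serum_id` followed by the antigen ids, then one line per serum.
#' Reading validates the table strictly — ragged rows, non-numeric cells
#' and duplicate serum ids are errors reported with their line number —
#' and restores integer storage when every cell is a whole number, so
#' `write_profile_matrix()` followed by `read_profile_matrix()` is the
#' identity (including serum order and integer/real typing).
#'
#' @param path TSV file path.
#' @param x Numeric matrix, sera as rows, antigens as columns, with
#'   dimnames.
#' @return `read_profile_matrix` returns the matrix; `write_profile_matrix`
#'   returns `path` invisibly.
#' @export
read_profile_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("profile matrix file '", path,
         "' must contain a header and at least one serum", call. = FALSE)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header)
  if (n_col < 2L) {
    stop("header must name at least one antigen (line 1)", call. = FALSE)
  }
  antigens <- header[-1L]
  n_sera <- length(lines) - 1L
  ids <- character(n_sera)
  m <- matrix(NA_real_, n_sera, n_col - 1L)
  for (i in seq_len(n_sera)) {
    row <- cells[[i + 1L]]
    if (length(row) != n_col) {
      stop("ragged row: expected ", n_col, " fields but found ", length(row),
           " (line ", i + 1L, ")", call. = FALSE)
    }
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      stop("non-numeric intensity value '", row[-1L][which(is.na(vals))[1L]],
           "' (line ", i + 1L, ")", call. = FALSE)
    }
    m[i, ] <- vals
  }
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop("duplicate serum id '", ids[dup[1L]], "' (line ", dup[1L] + 1L, ")",
         call. = FALSE)
  }
  dimnames(m) <- list(ids, antigens)
  if (all(m == round(m)) && max(abs(m)) < .Machine$integer.max) {
    storage.mode(m) <- "integer"
  }
  m
}

#' @rdname read_profile_matrix
#' @export
write_profile_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("serum_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, scientific = FALSE,
                                   digits = 15)),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write serum group labels as TSV
#'
#' Two-column tab-separated table `serum_id`, `group`.
#'
#' @param path TSV file path.
#' @param serum_ids Character vector of serum ids.
#' @param groups Factor/character of group labels, parallel to
#'   `serum_ids`.
#' @return `read_labels` returns a factor named by serum id (level order =
#'   order of first appearance); `write_labels` returns `path` invisibly.
#' @export
read_labels <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("serum_id", "group") %in% names(d))) {
    stop("labels file must have columns 'serum_id' and 'group'",
         call. = FALSE)
  }
  stats::setNames(factor(d$group, levels = unique(d$group)), d$serum_id)
}

#' @rdname read_labels
#' @export
write_labels <- function(serum_ids, groups, path) {
  stopifnot(length(serum_ids) == length(groups))
  utils::write.table(data.frame(serum_id = serum_ids, group = groups),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an AUC report table
#'
#' Tab-separated `antigen_id`, `auc`, `informative` table as produced by
#' [auc_table()].
#'
#' @param tab Data frame from [auc_table()].
#' @param path TSV file path.
#' @export
write_auc_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-spot measurements
#'
#' Tab-separated per-spot table from [quantify_image()].
#'
#' @param q A `quantified_array`.
#' @param path TSV file path.
#' @export
write_measurements <- function(q, path) {
  stopifnot(inherits(q, "quantified_array"))
  utils::write.table(q$measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
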
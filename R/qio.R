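# Readers and writers for the plain-text inputs and outputs: the ancestry
# proportion matrix (ADMIXTURE .Q dialect), the individual label file
# (.ind dialect), the sorted proportion table and the color scheme file.

#' Read an ancestry proportion matrix (.Q file)
#'
#' Parses a whitespace-delimited matrix of ancestry proportions with one row
#' per individual and K columns, the format written by ADMIXTURE and
#' compatible programs. The file has no header and no individual identifiers;
#' blank lines are skipped. Every row must sum to one within `tolerance`
#' unless `renormalize` is set, in which case each row is divided by its sum.
#'
#' @param path Path to the Q file.
#' @param renormalize If `TRUE`, divide each row by its sum so rows sum to
#'   one exactly (up to machine precision). If `FALSE` (default), a row whose
#'   sum deviates from one by more than `tolerance` is an error.
#' @param tolerance Maximum allowed absolute deviation of a row sum from one
#'   when `renormalize` is off. The default 1e-4 accommodates the rounding of
#'   typical ADMIXTURE output (6 decimal places).
#' @return A numeric N x K matrix of class `"ancestry_matrix"`. When the
#'   values were taken verbatim from the file (no renormalization) the
#'   original text tokens are kept in the `"tokens"` attribute so that
#'   downstream writers can echo the input precision exactly.
#' @seealso [write_q_matrix()], [read_individual_file()], [bind_dataset()]
#' @export
#' @examples
#' qf <- tempfile(fileext = ".Q")
#' writeLines(c("0.1 0.7 0.2", "0.5 0.25 0.25"), qf)
#' q <- read_q_matrix(qf)
#' dim(q)
read_q_matrix <- function(path, renormalize = FALSE, tolerance = 1e-4) {
  if (!file.exists(path)) {
    stop("Q matrix file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop("Q matrix file is empty: ", path, call. = FALSE)
  }
  tok <- strsplit(lines, "[[:space:]]+")
  nfield <- lengths(tok)
  if (any(nfield != nfield[1L])) {
    bad <- which(nfield != nfield[1L])[1L]
    stop(sprintf(
      "ragged Q matrix in '%s': line %d has %d fields but line %d has %d",
      path, lineno[bad], nfield[bad], lineno[1L], nfield[1L]
    ), call. = FALSE)
  }
  if (nfield[1L] < 2L) {
    stop("a Q matrix needs at least K = 2 ancestry columns; found ",
         nfield[1L], call. = FALSE)
  }
  tokens <- do.call(rbind, tok)
  vals <- suppressWarnings(
    matrix(as.numeric(tokens), nrow = nrow(tokens), ncol = ncol(tokens))
  )
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0L)[1L]
    stop(sprintf("non-numeric value in Q matrix '%s' at line %d",
                 path, lineno[bad]), call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0L)[1L]
    stop(sprintf("negative ancestry proportion at line %d of '%s'",
                 lineno[bad], path), call. = FALSE)
  }
  rs <- rowSums(vals)
  if (renormalize) {
    zero <- rs <= 0
    if (any(zero)) {
      stop(sprintf("cannot renormalize all-zero row at line %d of '%s'",
                   lineno[which(zero)[1L]], path), call. = FALSE)
    }
    vals <- vals / rs
    tokens <- NULL
  } else {
    off <- abs(rs - 1) > tolerance
    if (any(off)) {
      i <- which(off)[1L]
      stop(sprintf(
        paste0("row %d of '%s' sums to %.8f, not 1 (tolerance %g); ",
               "proportions across ancestries must sum to one, or use ",
               "renormalize = TRUE"),
        i, path, rs[i], tolerance
      ), call. = FALSE)
    }
  }
  new_ancestry_matrix(vals, tokens = tokens)
}

new_ancestry_matrix <- function(values, tokens = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  structure(values,
            tokens = tokens,
            class = c("ancestry_matrix", "matrix", "array"))
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("ancestry matrix: %d individuals x %d ancestries\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... (%d more rows)\n", nrow(x) - 6L))
  invisible(x)
}

#' Write an ancestry proportion matrix in the .Q dialect
#'
#' Writes whitespace-delimited rows readable by [read_q_matrix()]. Where the
#' matrix carries the verbatim tokens of the file it was read from, those are
#' echoed unchanged; otherwise values are printed with 17 significant digits
#' so the parse-serialize round trip is lossless.
#'
#' @param matrix An `"ancestry_matrix"` or plain numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(matrix, path) {
  tokens <- attr(matrix, "tokens")
  if (is.null(tokens)) {
    tokens <- apply(unclass(matrix), c(1, 2), function(v) sprintf("%.17g", v))
  }
  lines <- apply(tokens, 1L, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an individual label file (.ind dialect)
#'
#' Each non-blank line describes one individual, row-aligned with the Q
#' matrix. The first whitespace-separated column is the individual
#' identifier and the last column is the predefined group identifier
#' (population label, sampling location, or any other class label); middle
#' columns -- such as the sex column of the three-column EIGENSTRAT `.ind`
#' layout -- are ignored. A minimal two-column `id group` layout is accepted.
#'
#' @param path Path to the label file.
#' @return A data frame with character columns `individual_id` and
#'   `group_label`, one row per individual in file order.
#' @export
read_individual_file <- function(path) {
  if (!file.exists(path)) {
    stop("individual file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop("individual file is empty: ", path, call. = FALSE)
  }
  tok <- strsplit(lines, "[[:space:]]+")
  short <- lengths(tok) < 2L
  if (any(short)) {
    stop(sprintf(
      "line %d of '%s' has fewer than 2 columns (need id and group label)",
      lineno[which(short)[1L]], path
    ), call. = FALSE)
  }
  ids <- vapply(tok, `[[`, character(1), 1L)
  groups <- vapply(tok, function(x) x[[length(x)]], character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate individual id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  data.frame(individual_id = ids, group_label = groups,
             stringsAsFactors = FALSE)
}

#' Bind a proportion matrix and its individual labels into one dataset
#'
#' @param matrix An `"ancestry_matrix"` (or plain numeric matrix) with one
#'   row per individual.
#' @param individuals A data frame as returned by [read_individual_file()],
#'   row-aligned with `matrix`.
#' @return An object of class `"ancestry_dataset"`: a list with elements
#'   `Q` (the matrix) and `individuals` (the label data frame).
#' @export
bind_dataset <- function(matrix, individuals) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("'matrix' must be a numeric matrix of ancestry proportions",
         call. = FALSE)
  }
  if (!all(c("individual_id", "group_label") %in% names(individuals))) {
    stop("'individuals' needs columns individual_id and group_label",
         call. = FALSE)
  }
  if (nrow(matrix) != nrow(individuals)) {
    stop(sprintf(
      "Q matrix has %d rows but the individual file lists %d individuals",
      nrow(matrix), nrow(individuals)
    ), call. = FALSE)
  }
  if (!inherits(matrix, "ancestry_matrix")) {
    matrix <- new_ancestry_matrix(matrix)
  }
  structure(list(Q = matrix, individuals = individuals),
            class = "ancestry_dataset")
}

#' @export
print.ancestry_dataset <- function(x, ...) {
  cat(sprintf(
    "ancestry dataset: %d individuals, %d populations, K = %d ancestries\n",
    nrow(x$Q), length(unique(x$individuals$group_label)), ncol(x$Q)
  ))
  invisible(x)
}

#' Population labels of a dataset, in file order of first appearance
#' @param dataset An `"ancestry_dataset"`.
#' @return Character vector of unique group labels.
#' @export
population_labels <- function(dataset) {
  unique(dataset$individuals$group_label)
}

#' Write the sorted proportion table
#'
#' Writes a tab-separated file with one row per individual in final plotting
#' order: individual id, group label, then the K ancestry proportions.
#' Proportions are echoed at the precision of the input file where available,
#' otherwise printed with 6 decimal places.
#'
#' @param dataset An `"ancestry_dataset"`.
#' @param order A `"plot_order"` from [resolve_order()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sorted_table <- function(dataset, order, path) {
  rows <- order$individual_sequence
  tokens <- attr(dataset$Q, "tokens")
  if (is.null(tokens)) {
    tokens <- apply(unclass(dataset$Q), c(1, 2),
                    function(v) sprintf("%.6f", v))
  }
  lines <- vapply(rows, function(r) {
    paste(c(dataset$individuals$individual_id[r],
            dataset$individuals$group_label[r],
            tokens[r, ]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
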
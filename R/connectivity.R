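#' Read a square numeric matrix from delimited text
#'
#' Accepts comma- or whitespace-delimited numeric text. A single leading
#' header row is auto-detected (first token non-numeric) and dropped. Errors
#' name the offending row for ragged or non-numeric input.
#'
#' @param path file to read.
#' @param expected_n if given, the matrix must be `expected_n` x `expected_n`.
#' @return A numeric N x N matrix.
#' @export
read_matrix <- function(path, expected_n = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("empty matrix file: %s", path))
  split_row <- function(l) {
    l <- trimws(l)
    if (grepl(",", l, fixed = TRUE)) trimws(strsplit(l, ",")[[1]])
    else strsplit(l, "[[:space:]]+")[[1]]
  }
  toks <- lapply(lines, split_row)
  # header row: first token not parseable as a number
  if (is.na(suppressWarnings(as.numeric(toks[[1]][1])))) toks <- toks[-1]
  widths <- lengths(toks)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged matrix file %s: row %d has %d fields, expected %d",
                  path, bad, widths[bad], widths[1]))
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- which(vapply(vals, function(v) any(is.na(v)), logical(1)))
  if (length(bad)) {
    abort(sprintf("non-numeric cell in %s at row %d", path, bad[1]))
  }
  m <- do.call(rbind, vals)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("matrix in %s is %d x %d, not square", path, nrow(m), ncol(m)))
  }
  if (!all(is.finite(m))) abort(sprintf("non-finite entries in %s", path))
  if (!is.null(expected_n) && nrow(m) != expected_n) {
    abort(sprintf("matrix in %s is %d x %d, expected %d x %d",
                  path, nrow(m), ncol(m), expected_n, expected_n))
  }
  unname(m)
}

#' Write a numeric matrix as delimited text
#'
#' Full double precision, whitespace-delimited, no header; bit-stable given
#' the same input, and round-trips through [read_matrix()].
#'
#' @param m numeric matrix.
#' @param path output file.
#' @export
write_matrix <- function(m, path) {
  rows <- apply(m, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(rows, path)
  invisible(path)
}

#' Validate and construct a structural connectome
#'
#' Accepts a square nonnegative coupling matrix, symmetrizes tiny numerical
#' asymmetry (max |C - t(C)| <= 1e-6, averaged with its transpose, with a
#' warning), zeroes the diagonal, and rejects negatives or gross asymmetry.
#' Region identity is positional; duplicate label strings are allowed.
#'
#' @param C square numeric matrix of coupling weights.
#' @param labels,abbrevs optional region names / abbreviations (length N).
#' @param coords optional N x 3 matrix of spatial positions.
#' @return An object of class `structural_connectome`.
#' @export
validate_sc <- function(C, labels = NULL, abbrevs = NULL, coords = NULL) {
  if (!is_square(C)) abort("`C` must be a square matrix")
  if (!all(is.finite(C))) abort("`C` must be finite")
  if (any(C < 0)) abort("`C` must be nonnegative")
  asym <- max(abs(C - t(C)))
  if (asym > 1e-6) {
    abort(sprintf("`C` is asymmetric (max |C - t(C)| = %.3g > 1e-6)", asym))
  }
  if (asym > 0) {
    warn(sprintf("symmetrizing `C` (max asymmetry %.3g)", asym))
    C <- (C + t(C)) / 2
  }
  diag(C) <- 0
  N <- nrow(C)
  labels <- labels %||% paste0("ROI", seq_len(N))
  abbrevs <- abbrevs %||% paste0("R", seq_len(N))
  if (length(labels) != N || length(abbrevs) != N) {
    abort("`labels` and `abbrevs` must have length N")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != N || ncol(coords) != 3) abort("`coords` must be N x 3")
  }
  structure(list(C = unname(C), labels = labels, abbrevs = abbrevs,
                 coords = coords),
            class = "structural_connectome")
}

#' Alias constructor for a structural connectome
#' @inheritParams validate_sc
#' @return An object of class `structural_connectome`.
#' @export
structural_connectome <- function(C, labels = NULL, abbrevs = NULL,
                                  coords = NULL) {
  validate_sc(C, labels, abbrevs, coords)
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d regions, density %.2f, max weight %.3g\n",
              nrow(x$C), mean(x$C[upper.tri(x$C)] > 0), max(x$C)))
  invisible(x)
}

#' Functional connectivity from BOLD
#'
#' Pearson correlation matrix over the regional BOLD series.
#'
#' @param bold a [simulate_bold()] result or a T x N numeric matrix (T >= 3).
#' @param labels optional region labels.
#' @return An object of class `fc_matrix`: list with correlation matrix `R`
#'   (unit diagonal, symmetric) and `labels`.
#' @export
compute_fc <- function(bold, labels = NULL) {
  Y <- if (inherits(bold, "bold_time_series")) bold$Y else as.matrix(bold)
  if (nrow(Y) < 3) abort("need at least 3 BOLD samples to correlate")
  sds <- apply(Y, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant BOLD series in region(s): %s",
                  paste(which(sds == 0), collapse = ", ")))
  }
  R <- cor(Y)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  fc_matrix(R, labels = labels %||% colnames(Y))
}

#' Construct a functional-connectivity matrix object
#'
#' @param R square correlation matrix (symmetric, unit diagonal, entries in
#'   `[-1, 1]`).
#' @param labels optional region labels.
#' @return An object of class `fc_matrix`.
#' @export
fc_matrix <- function(R, labels = NULL) {
  if (!is_square(R)) abort("`R` must be square")
  if (max(abs(R - t(R))) > 1e-9) abort("`R` must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-9) abort("`R` must have unit diagonal")
  if (any(R < -1 - 1e-12) || any(R > 1 + 1e-12)) {
    abort("`R` entries must lie in [-1, 1]")
  }
  structure(list(R = unname(clip(R, -1, 1)),
                 labels = labels %||% paste0("R", seq_len(nrow(R)))),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  ut <- upper_tri_vec(x$R)
  cat(sprintf("<fc_matrix> %d regions, mean off-diagonal r = %.3f\n",
              nrow(x$R), mean(ut)))
  invisible(x)
}

#' Similarity between two FC matrices
#'
#' Pearson correlation between the strictly-upper-triangle vectors of the two
#' matrices (the unit diagonal is excluded: it carries no information and
#' would inflate the similarity). This is the objective the model fit
#' maximizes.
#'
#' @param sim,emp `fc_matrix` objects (or bare square matrices) of equal N.
#' @return Scalar in `[-1, 1]`.
#' @export
fc_similarity <- function(sim, emp) {
  A <- if (inherits(sim, "fc_matrix")) sim$R else sim
  B <- if (inherits(emp, "fc_matrix")) emp$R else emp
  if (!identical(dim(A), dim(B))) abort("FC matrices differ in size")
  a <- upper_tri_vec(A); b <- upper_tri_vec(B)
  if (sd(a) == 0 || sd(b) == 0) {
    abort("an FC upper triangle is constant; similarity undefined")
  }
  cor(a, b)
}

#' Elementwise average of a list of matrices
#'
#' Used for the group-average structural and functional connectomes.
#'
#' @param matrices non-empty list of same-shaped numeric matrices.
#' @return The elementwise arithmetic mean.
#' @export
group_average <- function(matrices) {
  if (!length(matrices)) abort("`matrices` must be non-empty")
  dims <- lapply(matrices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all matrices must share the same shape")
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Read / write ROI metadata tables
#'
#' Tab-separated with columns `index`, `name`, `abbrev`, and optionally `x`,
#' `y`, `z`. Indices in files are 1-based for display; internal region
#' identity is positional (row order).
#'
#' @param path TSV file.
#' @return A tibble with the ROI metadata.
#' @export
read_roi_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("index", "name", "abbrev")
  if (!all(req %in% names(df))) {
    abort(sprintf("ROI table %s must have columns: %s", path,
                  paste(req, collapse = ", ")))
  }
  if (anyDuplicated(df$index) || !identical(sort(df$index), seq_len(nrow(df)))) {
    abort("ROI indices must be unique and contiguous starting at 1")
  }
  tibble::as_tibble(df[order(df$index), , drop = FALSE])
}

#' @rdname read_roi_table
#' @param roi data frame with the required columns.
#' @export
write_roi_table <- function(roi, path) {
  write.table(roi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write subject tables
#'
#' Tab-separated with columns `id`, `age`, `sex`, `sc_path`, `fc_path`.
#' Paths are interpreted relative to the table's directory.
#'
#' @param path TSV file.
#' @return A tibble with one row per subject.
#' @export
read_subject_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("id", "age", "sex", "sc_path", "fc_path")
  if (!all(req %in% names(df))) {
    abort(sprintf("subject table %s must have columns: %s", path,
                  paste(req, collapse = ", ")))
  }
  if (any(!is.finite(df$age)) || any(df$age < 0)) {
    abort("subject ages must be finite and >= 0")
  }
  tibble::as_tibble(df)
}

#' @rdname read_subject_table
#' @param subjects data frame with the required columns.
#' @export
write_subject_table <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
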
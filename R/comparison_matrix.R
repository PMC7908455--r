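#' Construct and validate a pairwise-comparison matrix
#'
#' A comparison matrix is a square positive reciprocal matrix: `a[i, i] == 1`
#' and `a[i, j] * a[j, i] == 1` for every pair, with `a[i, j]` the judged
#' importance of factor i over factor j on the Saaty scale. This constructor
#' validates those properties, fills missing lower-triangle cells from their
#' reciprocals, forces the diagonal to exactly 1, and attaches factor labels.
#'
#' Entries may be numeric or questionnaire-style strings (`"3"`, `"1/3"`);
#' strings are parsed with [parse_judgment()].
#'
#' @param entries square numeric or character matrix (or an object coercible
#'   with `as.matrix()`, e.g. a list of equal-length rows passed through
#'   `do.call(rbind, ...)` by the caller). `NA` below the diagonal is filled
#'   as the reciprocal of the mirror cell.
#' @param labels optional character vector of factor identifiers; defaults to
#'   existing dimnames or `F1..Fn`.
#' @param tol reciprocity tolerance: `|a_ij * a_ji - 1|` must not exceed it.
#'   Survey-derived matrices transcribed at limited precision may need a
#'   looser value than the 1e-6 default.
#' @param check_saaty one of `"warn"` (default: entries outside the 17-value
#'   Saaty scale trigger one warning), `"strict"` (they are an error), or
#'   `"none"` (no scale check; used for synthetic perturbed matrices).
#' @return a `comparison_matrix`: a numeric matrix with factor labels as
#'   dimnames.
#' @examples
#' comparison_matrix(rbind(
#'   c(1, 2, 1 / 4),
#'   c(1 / 2, 1, 1 / 3),
#'   c(4, 3, 1)
#' ), labels = c("W1", "W2", "W3"))
#' @export
comparison_matrix <- function(entries, labels = NULL, tol = 1e-6,
                              check_saaty = c("warn", "strict", "none")) {
  check_saaty <- match.arg(check_saaty)
  if (is.list(entries) && !is.data.frame(entries)) {
    lens <- lengths(entries)
    if (length(unique(lens)) != 1L) {
      swot_abort("matrix rows have unequal lengths", "swotahp_shape_error")
    }
    entries <- do.call(rbind, lapply(entries, function(r) unlist(r, use.names = FALSE)))
  }
  m <- as.matrix(entries)
  if (nrow(m) != ncol(m) || nrow(m) < 2L) {
    swot_abort(
      sprintf("comparison matrix must be square with order >= 2; got %d x %d",
              nrow(m), ncol(m)),
      "swotahp_shape_error"
    )
  }
  n <- nrow(m)
  if (is.character(m)) {
    a <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        cell <- m[i, j]
        if (!is.na(cell) && nzchar(trimws(cell))) {
          a[i, j] <- parse_judgment(cell, where = sprintf("cell (%d, %d)", i, j))
        }
      }
    }
    m <- a
  } else {
    storage.mode(m) <- "double"
  }

  # fill missing mirror cells from reciprocals (either triangle may be given)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (is.na(m[i, j]) && !is.na(m[j, i])) m[i, j] <- 1 / m[j, i]
    }
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    swot_abort(
      sprintf("missing judgment at (%d, %d) with no mirror cell", idx[1], idx[2]),
      "swotahp_input_error"
    )
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    idx <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)[1, ]
    swot_abort(
      sprintf("entry at (%d, %d) is not strictly positive", idx[1], idx[2]),
      "swotahp_domain_error"
    )
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(m[i, j] * m[j, i] - 1) > tol) {
        swot_abort(
          sprintf(
            "reciprocity violated at (%d, %d): a_ij * a_ji = %.6g (tolerance %g)",
            i, j, m[i, j] * m[j, i], tol
          ),
          "swotahp_reciprocity_error"
        )
      }
    }
  }
  diag(m) <- 1

  if (check_saaty != "none") {
    off <- m[upper.tri(m)]
    outside <- !is_saaty_value(off, tol = 1e-6)
    if (any(outside)) {
      msg <- sprintf(
        "%d judgment(s) outside the Saaty 1/9..9 scale (e.g. %.4g)",
        sum(outside), off[outside][1]
      )
      if (check_saaty == "strict") {
        swot_abort(msg, "swotahp_domain_error")
      }
      warning(msg, call. = FALSE)
    }
  }

  if (is.null(labels)) {
    labels <- rownames(m) %||% paste0("F", seq_len(n))
  }
  if (length(labels) != n) {
    swot_abort(
      sprintf("%d labels supplied for a matrix of order %d", length(labels), n),
      "swotahp_shape_error"
    )
  }
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("comparison_matrix", "matrix", "array"))
}

#' @export
print.comparison_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise comparison matrix (order %d)\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Read a comparison matrix from CSV
#'
#' Expects a header row and a leading label column, mirroring how judgment
#' matrices are usually transcribed from questionnaires; cells may be decimals
#' or fraction strings like `"1/3"`. Lower-triangle cells may be left empty
#' and are filled by reciprocity.
#'
#' @param path CSV file path.
#' @inheritParams comparison_matrix
#' @return a [comparison_matrix()].
#' @export
read_matrix_csv <- function(path, tol = 1e-6,
                            check_saaty = c("warn", "strict", "none")) {
  if (!file.exists(path)) {
    swot_abort(paste0("matrix file not found: ", path), "swotahp_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(unname(colnames(m)), unname(labels))) {
    swot_abort(
      "CSV row labels and column headers disagree",
      "swotahp_shape_error"
    )
  }
  m[m == ""] <- NA_character_
  comparison_matrix(m, labels = labels, tol = tol, check_saaty = check_saaty)
}
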
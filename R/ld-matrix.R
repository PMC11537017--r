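#' Pairwise LD (r-squared) matrix
#'
#' Validates and wraps a square matrix of squared correlations between
#' variants: symmetric, unit diagonal, all values in \[0, 1\].
#'
#' @param r2 Square numeric matrix of squared correlations.
#' @param variant_ids Variant identifiers for rows/columns; defaults to the
#'   matrix dimnames.
#' @return The matrix with class `ld_matrix` and variant ids as dimnames.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2)) {
    abort_input("LD matrix must be square")
  }
  if (is.null(variant_ids) || length(variant_ids) != nrow(r2)) {
    abort_input("LD matrix needs one variant id per row")
  }
  if (anyDuplicated(variant_ids)) abort_input("LD variant ids must be unique")
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort_input("LD r-squared values must lie in [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) abort_input("LD matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    abort_input("LD matrix diagonal must be exactly 1")
  }
  dimnames(r2) <- list(variant_ids, variant_ids)
  diag(r2) <- 1
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read / write an LD matrix as TSV
#'
#' The on-disk format is a square tab-separated matrix with a header row of
#' variant ids and the ids repeated in the first column.
#'
#' @param path File path.
#' @return `read_ld_matrix()` returns an `ld_matrix`; `write_ld_matrix()`
#'   returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  ld_matrix(m, variant_ids = ids)
}

#' @rdname read_ld_matrix
#' @param x An `ld_matrix`.
#' @export
write_ld_matrix <- function(x, path) {
  out <- tibble(variant_id = rownames(x))
  out <- dplyr::bind_cols(out, as_tibble(unclass(x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# r2 lookup treating pairs absent from the matrix as independent.
ld_r2_lookup <- function(ld, id_a, id_b) {
  if (is.null(ld)) return(0)
  ok_a <- id_a %in% rownames(ld)
  ok_b <- id_b %in% rownames(ld)
  out <- numeric(length(id_b))
  out[ok_a & ok_b] <- ld[id_a, id_b[ok_a & ok_b]]
  out
}
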
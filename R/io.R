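## CSV matrix I/O. Square numeric matrices with an optional label row and
## column, auto-detected from the first cell; values written with 17
## significant digits so round-trips are exact.

#' Read a square symmetric matrix from CSV
#'
#' Accepts both dialects: a bare numeric matrix, or one with a label
#' header row and label first column (detected by a non-numeric first
#' cell). Symmetry is checked within tolerance.
#'
#' @param path CSV file path.
#' @param tol Symmetry tolerance.
#' @return Numeric matrix with dimnames.
#' @export
read_network_matrix <- function(path, tol = 1e-8) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]][1]
  labeled <- is.na(suppressWarnings(as.numeric(first)))
  m <- if (labeled) {
    as.matrix(utils::read.csv(path, row.names = 1, header = TRUE,
                              check.names = FALSE))
  } else {
    as.matrix(utils::read.csv(path, header = FALSE))
  }
  if (!is.numeric(m)) stop(sprintf("non-numeric cells in %s", path))
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is not square (%d x %d)", path, nrow(m),
                 ncol(m)))
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("matrix in %s is asymmetric: worst entry (%d, %d), |diff| = %g",
                 path, ij[1], ij[2], max(asym)))
  }
  if (!labeled)
    dimnames(m) <- list(paste0("V", seq_len(nrow(m))),
                        paste0("V", seq_len(nrow(m))))
  m
}

#' Write a square matrix to CSV with labels
#'
#' Values are written with 17 significant digits, so
#' [read_network_matrix()] recovers them exactly.
#'
#' @param m Numeric matrix.
#' @param path Output CSV path.
#' @export
write_network_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("V", seq_len(nrow(m)))
  body <- apply(m, 1, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = ","))
  lines <- c(paste(c("", labels), collapse = ","),
             paste(labels, body, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write Betti curves to CSV
#'
#' Columns `level`, `beta0`, `beta1`, `edges`.
#'
#' @param curve A `betti_curve` from [betti_curves()].
#' @param path Output CSV path.
#' @export
write_betti_curves <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
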
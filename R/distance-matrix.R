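#' Labeled symmetric distance matrices
#'
#' A `distance_matrix` is a square numeric matrix with matching row/column
#' labels, zero diagonal, symmetry within 1e-9, and non-negative entries. It
#' holds both community dissimilarities (Bray-Curtis, in \[0,1\]) and genetic
#' distances (substitutions/site). `NA` entries mark undefined pairs
#' (saturated genetic distances, no overlapping sites).
#'
#' @param d square numeric matrix.
#' @param labels unique character labels; default dimnames of `d`.
#' @return a `distance_matrix` object.
#' @export
distance_matrix <- function(d, labels = rownames(d)) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("`d` must be a square matrix")
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(d)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (length(labels) != nrow(d)) stop("label length mismatch")
  if (any(!is.na(d) & d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-9, na.rm = TRUE)) stop("non-zero diagonal")
  diag(d) <- 0
  asym <- abs(d - t(d))
  if (any(asym > 1e-9, na.rm = TRUE)) stop("matrix not symmetric within 1e-9")
  d <- (d + t(d)) / 2  # symmetrize exactly
  if (any(is.na(d) != is.na(t(d)))) stop("asymmetric NA pattern")
  dimnames(d) <- list(labels, labels)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d x %d%s\n", nrow(x), ncol(x),
              if (anyNA(x)) sprintf(", %d undefined entries", sum(is.na(x)))
              else ""))
  print(round(unclass(x)[seq_len(min(nrow(x), 8L)),
                         seq_len(min(ncol(x), 8L)), drop = FALSE], 4L), ...)
  invisible(x)
}

#' Strictly-lower-triangle entries of a distance matrix
#' @param d a `distance_matrix`.
#' @param drop_na drop undefined entries.
#' @return numeric vector.
#' @export
lower_triangle <- function(d, drop_na = TRUE) {
  v <- d[lower.tri(d)]
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Read / write a distance matrix as square labeled TSV
#' @param path file path.
#' @return a `distance_matrix` ([read_distance_matrix()]) or `path`
#'   ([write_distance_matrix()]).
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  distance_matrix(m, rownames(m))
}

#' @rdname read_distance_matrix
#' @param d a `distance_matrix`.
#' @export
write_distance_matrix <- function(d, path) {
  header <- paste(c("label", colnames(d)), collapse = "\t")
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(rownames(d)[i], formatC(d[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

# reconcile two distance matrices to a common label order
reconcile_labels <- function(d1, d2) {
  if (!setequal(rownames(d1), rownames(d2)))
    stop("label sets differ between the two matrices")
  ord <- rownames(d1)
  list(d1 = d1, d2 = distance_matrix(unclass(d2)[ord, ord], ord))
}
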
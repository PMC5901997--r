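#' Sample-by-taxon abundance tables
#'
#' An `abundance_table` is a numeric matrix with samples as rows and taxa as
#' columns, tagged with a `mode`: `"count"` for raw observation counts
#' (microscopy valves, sequencing reads) or `"percent"` for relative
#' abundances summing to 100 per sample. Both observation channels of a
#' biofilm survey (morphology-based and metabarcoding-based) use the same
#' container, so every community statistic in the package applies to either.
#'
#' @param values numeric matrix, samples x taxa, non-negative.
#' @param sample_ids,taxon_ids unique character labels; default to the
#'   dimnames of `values`.
#' @param mode `"count"` or `"percent"`. In percent mode every row must sum
#'   to 100 within a relative tolerance of 1e-6.
#' @return an `abundance_table` object (a matrix with class and `mode`
#'   attributes).
#' @examples
#' abundance_table(matrix(c(50, 50, 25, 75), 2, byrow = TRUE,
#'                        dimnames = list(c("s1", "s2"), c("a", "b"))),
#'                 mode = "percent")
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxon_ids = colnames(values),
                            mode = c("count", "percent")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(taxon_ids))
    stop("sample and taxon ids are required")
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(values) || length(taxon_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon id: ", taxon_ids[duplicated(taxon_ids)][1L])
  if (anyNA(values))
    stop("missing values are not allowed (absent taxa are 0)")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at sample '%s', taxon '%s'",
                 sample_ids[bad[1L]], taxon_ids[bad[2L]]))
  }
  if (mode == "percent") {
    # printed tables carry 1-decimal rounding, so rows may sum to 100 +/- 0.1
    rs <- rowSums(values)
    off <- abs(rs - 100) > 0.1 + 1e-9
    if (any(off))
      stop(sprintf("percent-mode row '%s' sums to %g, not 100",
                   sample_ids[which(off)[1L]], rs[which(off)[1L]]))
  }
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(values, mode = mode, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, mode = %s\n",
              nrow(x), ncol(x), table_mode(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE]), ...)
  invisible(x)
}

#' Mode of an abundance table
#' @param t an `abundance_table`.
#' @return `"count"` or `"percent"`.
#' @export
table_mode <- function(t) attr(t, "mode")

#' Read an abundance table from a delimited text file
#'
#' Expects a header row of taxon ids and one row per sample whose first field
#' is the sample id. The canonical dialect is TSV with `.` decimals; CSV is
#' accepted via `sep = ","`. Validation failures (duplicate ids, negative or
#' non-numeric values, ragged rows) raise errors naming the offending
#' row/cell.
#'
#' @param path file path.
#' @param mode `"count"`, `"percent"`, or `"infer"`: infer chooses percent
#'   when every row sum lies in \[99.9, 100.1\], count otherwise.
#' @param sep field separator, tab by default.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, mode = c("infer", "count", "percent"),
                                 sep = "\t") {
  mode <- match.arg(mode)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("table needs a header and at least one sample row: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  taxa <- trimws(header[-1L])
  n_col <- length(header)
  rows <- fields[-1L]
  sample_ids <- character(length(rows))
  values <- matrix(NA_real_, length(rows), length(taxa))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != n_col)
      stop(sprintf("ragged row %d ('%s'): %d fields, expected %d",
                   i + 1L, f[1L], length(f), n_col))
    sample_ids[i] <- trimws(f[1L])
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   f[-1L][which(is.na(v))[1L]], sample_ids[i],
                   taxa[which(is.na(v))[1L]]))
    values[i, ] <- v
  }
  if (mode == "infer") {
    rs <- rowSums(values)
    mode <- if (all(rs >= 99.9 - 1e-9 & rs <= 100.1 + 1e-9)) "percent"
            else "count"
  }
  abundance_table(values, sample_ids, taxa, mode = mode)
}

#' Write an abundance table as TSV
#'
#' Full `%.17g` precision so that read -> write -> read round-trips exactly.
#'
#' @param t an `abundance_table`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(t, path, sep = "\t") {
  header <- paste(c("sample", colnames(t)), collapse = sep)
  body <- vapply(seq_len(nrow(t)), function(i) {
    paste(c(rownames(t)[i], formatC(t[i, ], format = "g", digits = 17)),
          collapse = sep)
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Convert counts to relative abundances (percent)
#'
#' Each row is rescaled to sum to 100, the representation used by all
#' downstream community statistics. Idempotent on percent-mode tables.
#'
#' @param t an `abundance_table`.
#' @return percent-mode `abundance_table`.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  rs <- rowSums(t)
  if (any(rs == 0))
    stop("zero-sum row for sample '", rownames(t)[which(rs == 0)[1L]], "'")
  abundance_table(100 * unclass(t) / rs, rownames(t), colnames(t),
                  mode = "percent")
}

#' Integer mean of a total over samples
#'
#' Rounds half away from zero, the convention under which a total of 209,095
#' reads over 7 samples averages 29,871.
#'
#' @param total non-negative numeric total.
#' @param n_samples positive integer.
#' @return integer mean.
#' @export
mean_per_sample <- function(total, n_samples) {
  if (length(n_samples) != 1L || n_samples < 1 || n_samples != round(n_samples))
    stop("`n_samples` must be a positive integer")
  if (any(total < 0)) stop("`total` must be non-negative")
  x <- total / n_samples
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Per-sample taxon richness
#'
#' Counts taxa with abundance > 0 in each sample; invariant under
#' normalization, so count- and percent-mode views of the same data agree.
#'
#' @param t an `abundance_table`.
#' @return list with `counts` (named integer vector), `min`, `max`, and
#'   `mean` (1 decimal).
#' @export
richness_summary <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  counts <- rowSums(unclass(t) > 0)
  storage.mode(counts) <- "integer"
  list(counts = counts, min = min(counts), max = max(counts),
       mean = round(mean(counts), 1L))
}
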
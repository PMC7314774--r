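#' Construct a validated abundance table
#'
#' An abundance table holds nonnegative microbiota abundances as a
#' samples-by-taxa matrix, either on the raw hybridization-signal scale
#' (`scale = "signal"`) or closed to relative abundances
#' (`scale = "relative"`, every row summing to one).
#'
#' @param values numeric matrix, samples in rows, taxa in columns; must
#'   carry unique row and column names (sample and taxon identifiers).
#' @param scale `"signal"` or `"relative"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `sample_ids`, `taxon_ids`, `scale`.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 1, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB", "taxC")))
#' abundance_table(m, scale = "signal")
#' @export
abundance_table <- function(values, scale = c("signal", "relative")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must have sample (row) and taxon (column) names")
  x <- structure(
    list(values = values, sample_ids = rownames(values),
         taxon_ids = colnames(values), scale = scale),
    class = "abundance_table")
  validate_abundance_table(x)
  x
}

validate_abundance_table <- function(x) {
  v <- x$values
  bad <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-finite abundance at sample '%s', taxon '%s'",
          rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]])
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stopf("negative abundance at sample '%s', taxon '%s' (value %g)",
          rownames(v)[neg[1, 1]], colnames(v)[neg[1, 2]], v[neg[1, , drop = FALSE]])
  if (anyDuplicated(x$sample_ids))
    stopf("duplicated sample id(s): %s",
          paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  if (anyDuplicated(x$taxon_ids))
    stopf("duplicated taxon id(s): %s",
          paste(unique(x$taxon_ids[duplicated(x$taxon_ids)]), collapse = ", "))
  if (x$scale == "relative") {
    rs <- rowSums(v)
    off <- which(abs(rs - 1) > 1e-9)
    if (length(off) > 0L)
      stopf("relative-scale rows must sum to 1; sample '%s' sums to %.12g",
            rownames(v)[off[1]], rs[off[1]])
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from a tab-separated file
#'
#' The file must have one header row and a leading identifier column.
#' HITChip-style exports conventionally store taxa as rows; the
#' `orientation` flag states which layout the file uses, and the returned
#' table is always samples-by-taxa.
#'
#' @param path path to a TSV file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param scale passed to [abundance_table()].
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                                 scale = c("signal", "relative")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("'%s' does not look like an id column plus data", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicated row id(s) in '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric entries in '%s'", path)
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  abundance_table(m, scale = scale)
}

#' Write an abundance table to a tab-separated file
#'
#' @param x an [abundance_table()].
#' @param path output path.
#' @param orientation layout to write; the complement of what
#'   [read_abundance_table()] expects for a round trip.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "abundance_table"))
  m <- if (orientation == "taxa_rows") t(x$values) else x$values
  df <- data.frame(id = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- if (orientation == "taxa_rows") "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
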
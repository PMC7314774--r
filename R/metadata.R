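#' Validate per-sample cohort metadata
#'
#' Metadata is a data frame with one row per fecal sample and the columns
#' `sample_id`, `infant_id`, `group` (CC = center-based childcare,
#' HOME = home care), `timepoint` (PRE / POST), `age_days`, `bf_rate`,
#' `bf_rate_prior_period`, `sibling`, `csection`. The two breastfeeding
#' columns are average breast-feedings per day: `bf_rate` for the period
#' immediately preceding the sample and `bf_rate_prior_period` for the
#' earlier period (identical to `bf_rate` on PRE rows, where only one
#' period exists). Breastfeeding columns may be `NA` (missing); every
#' other column must be complete. Each infant must appear exactly once
#' per timepoint, with POST age strictly greater than PRE age.
#'
#' @param meta a data frame as described above.
#' @return `meta`, normalised (character columns for ids, factor group and
#'   timepoint, logical sibling/csection), invisibly classed
#'   `sample_metadata`.
#' @export
validate_metadata <- function(meta) {
  req <- c("sample_id", "infant_id", "group", "timepoint", "age_days",
           "bf_rate", "bf_rate_prior_period", "sibling", "csection")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L)
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$infant_id <- as.character(meta$infant_id)
  if (anyDuplicated(meta$sample_id))
    stopf("duplicated sample_id(s): %s",
          paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  gr <- as.character(meta$group)
  if (!all(gr %in% c("CC", "HOME")))
    stopf("unknown group label(s): %s",
          paste(unique(setdiff(gr, c("CC", "HOME"))), collapse = ", "))
  tp <- as.character(meta$timepoint)
  if (!all(tp %in% c("PRE", "POST")))
    stopf("unknown timepoint label(s): %s",
          paste(unique(setdiff(tp, c("PRE", "POST"))), collapse = ", "))
  meta$group <- factor(gr, levels = c("HOME", "CC"))
  meta$timepoint <- factor(tp, levels = c("PRE", "POST"))
  meta$sibling <- as.logical(meta$sibling)
  meta$csection <- as.logical(meta$csection)
  for (col in c("age_days", "sibling", "csection"))
    if (anyNA(meta[[col]])) stopf("column '%s' must be complete", col)
  if (any(meta$age_days <= 0)) stopf("age_days must be positive")
  for (col in c("bf_rate", "bf_rate_prior_period")) {
    v <- meta[[col]]
    if (any(v[!is.na(v)] < 0)) stopf("'%s' must be nonnegative when present", col)
  }
  tab <- table(meta$infant_id, meta$timepoint)
  bad <- rownames(tab)[rowSums(tab == 1L) != 2L | rowSums(tab) != 2L]
  if (length(bad) > 0L)
    stopf("infant(s) without exactly one PRE and one POST sample: %s",
          paste(bad, collapse = ", "))
  grp_per_infant <- tapply(as.character(meta$group), meta$infant_id,
                           function(g) length(unique(g)))
  if (any(grp_per_infant != 1L))
    stopf("infant(s) assigned to more than one group: %s",
          paste(names(grp_per_infant)[grp_per_infant != 1L], collapse = ", "))
  o <- order(meta$infant_id, meta$timepoint)
  m2 <- meta[o, ]
  pre <- m2[m2$timepoint == "PRE", ]
  post <- m2[m2$timepoint == "POST", ]
  nonmono <- pre$infant_id[post$age_days <= pre$age_days]
  if (length(nonmono) > 0L)
    stopf("POST age must exceed PRE age; violated for infant(s): %s",
          paste(nonmono, collapse = ", "))
  class(meta) <- unique(c("sample_metadata", class(meta)))
  invisible(meta)
}

#' Read per-sample metadata from CSV
#'
#' Empty cells in the breastfeeding columns are read as missing values;
#' they are never zero-filled. See [validate_metadata()] for the required
#' columns and invariants.
#'
#' @param path path to a CSV file.
#' @return A validated `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_metadata(df)
}

#' Write per-sample metadata to CSV
#'
#' Missing breastfeeding values are written as empty cells.
#'
#' @param meta a `sample_metadata` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, na = "")
  invisible(path)
}
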
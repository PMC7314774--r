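#' Close an abundance table to relative abundances
#'
#' Divides every sample (row) by its total. Already-relative tables are
#' returned unchanged (the operation is idempotent).
#'
#' @param table an [abundance_table()].
#' @return An [abundance_table()] with `scale = "relative"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  rs <- rowSums(table$values)
  zero <- which(rs == 0)
  if (length(zero) > 0L)
    stopf("sample '%s' has zero total abundance", table$sample_ids[zero[1]])
  abundance_table(table$values / rs, scale = "relative")
}

#' Centered log-ratio transform
#'
#' Per sample, `log(x + pseudocount)` minus its mean over taxa, so every
#' transformed row sums to zero. With `pseudocount = 0` this is the exact
#' clr; the default pseudocount (half the smallest positive relative
#' abundance in the table) guards against zeros, which hybridization
#' signals never contain but synthetic or sequencing-derived data may.
#'
#' @param table an [abundance_table()] on the relative scale.
#' @param pseudocount nonnegative offset added before taking logs; must be
#'   positive if the table contains zeros.
#' @return An object of class `clr_matrix`: list with `values` (rows sum
#'   to zero), `sample_ids`, `taxon_ids`, `pseudocount`.
#' @examples
#' m <- matrix(c(1, 2, 4) / 7, 1, dimnames = list("s1", c("a", "b", "c")))
#' clr_transform(abundance_table(m, "relative"), pseudocount = 0)$values
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "relative")
    stopf("clr_transform expects a relative-scale table; see to_relative_abundance()")
  v <- table$values
  if (is.null(pseudocount)) {
    pos <- v[v > 0]
    pseudocount <- if (any(v == 0)) min(pos) / 2 else 0
  }
  if (pseudocount < 0) stopf("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(v == 0))
    stopf("zeros present: a positive pseudocount is required")
  lg <- log(v + pseudocount)
  out <- lg - rowMeans(lg)
  structure(list(values = out, sample_ids = table$sample_ids,
                 taxon_ids = table$taxon_ids, pseudocount = pseudocount),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("<clr_matrix> %d samples x %d taxa (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Shannon alpha diversity
#'
#' `H = -sum(p * log(p))` per sample, with `0 * log(0) := 0`. Natural
#' logarithm by default.
#'
#' @param table an [abundance_table()] on the relative scale.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return Named numeric vector of per-sample Shannon indices.
#' @export
shannon_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "relative")
    stopf("shannon_diversity expects a relative-scale table")
  p <- table$values
  pl <- p * log(p, base = base)
  pl[p == 0] <- 0
  h <- -rowSums(pl)
  names(h) <- table$sample_ids
  h
}

#' Detection-threshold richness
#'
#' For each feature (probe or taxon), the detection threshold is that
#' feature's `detection_quantile` quantile across samples (type-7
#' linear-interpolation quantile); a feature is counted as present in a
#' sample when its signal strictly exceeds its own threshold. Richness is
#' the number of present features per sample. A constant feature is never
#' detected anywhere: nothing strictly exceeds its own quantile.
#'
#' @param table an [abundance_table()] on the signal scale.
#' @param detection_quantile quantile in (0, 1); default 0.8.
#' @return Named integer vector of per-sample richness counts.
#' @export
richness <- function(table, detection_quantile = 0.8) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (nrow(v) < 2L)
    stopf("richness needs at least two samples to define per-feature quantiles")
  if (detection_quantile <= 0 || detection_quantile >= 1)
    stopf("detection_quantile must be in (0, 1)")
  thr <- apply(v, 2L, stats::quantile, probs = detection_quantile,
               names = FALSE, type = 7)
  present <- sweep(v, 2L, thr, `>`)
  r <- as.integer(rowSums(present))
  names(r) <- table$sample_ids
  r
}

#' Coefficient of variation per taxon
#'
#' The across-sample sample standard deviation (n-1 denominator) divided
#' by the across-sample mean, a scale-free measure of how dynamic each
#' taxon is at the population level. Taxa with zero mean have no defined
#' CoV and are returned as `NA` with a warning rather than silently
#' propagating `NaN`.
#'
#' @param table an [abundance_table()] on the relative scale.
#' @return Named numeric vector of per-taxon CoV values.
#' @export
coefficient_of_variation <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$scale != "relative")
    stopf("coefficient_of_variation expects a relative-scale table")
  v <- table$values
  mu <- colMeans(v)
  sdv <- apply(v, 2L, stats::sd)
  cov <- sdv / mu
  cov[mu == 0] <- NA_real_
  if (any(mu == 0))
    warnf("%d taxa have zero mean; their CoV is undefined (NA)", sum(mu == 0))
  names(cov) <- table$taxon_ids
  cov
}
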
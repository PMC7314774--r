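#' Redundancy analysis (constrained ordination)
#'
#' RDA is a principal component analysis of the fitted values from a
#' multivariate least-squares regression of a (column-centered) response
#' matrix on explanatory variables. With a conditioning matrix `Z`
#' (partial RDA), both response and predictors are first replaced by
#' their residuals from regression on `Z`, so the reported constrained
#' variance is what `X` explains beyond `Z`.
#'
#' Inertia is reported on the variance scale (sums of squares divided by
#' n - 1). `R2` is the constrained variance as a fraction of the *total*
#' variance of the centered response (including any conditioned part), so
#' conditional effects are directly comparable with simple effects.
#' The pseudo-F statistic is
#' `(constrained / df_X) / (residual / (n - 1 - df_X - df_Z))`.
#'
#' @param Y a `clr_matrix`, or a numeric samples-by-variables matrix.
#' @param X numeric design matrix (no intercept column; columns are
#'   centered internally).
#' @param Z optional conditioning matrix, same rows as `Y`.
#' @param scores compute ordination scores (set `FALSE` to skip the
#'   singular decomposition, e.g. inside permutation loops).
#' @return An object of class `rda_fit` with elements `total_inertia`,
#'   `conditioned_inertia`, `constrained_inertia`, `residual_inertia`,
#'   `R2`, `adj_R2`, `F`, `df` (numerator, denominator), `eig`,
#'   `site_scores`, `species_scores`, `biplot_scores`.
#' @export
fit_rda <- function(Y, X, Z = NULL, scores = TRUE) {
  Y <- as_response_matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stopf("Y and X must have the same number of rows")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != nrow(Y)) stopf("Y and Z must have the same number of rows")
  }
  n <- nrow(Y)
  df_x <- ncol(X)
  df_z <- if (is.null(Z)) 0L else qr(scale(Z, scale = FALSE))$rank
  if (n <= df_x + df_z + 1L)
    stopf("need n > df(X) + df(Z) + 1 (n = %d)", n)

  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  const <- which(apply(Xc, 2L, function(col) all(abs(col) < 1e-12)))
  if (length(const) > 0L)
    stopf("constant design column(s) after centering: %s",
          paste(colnames(X)[const] %||% const, collapse = ", "))
  total <- sum(Yc^2)

  cond <- 0
  if (!is.null(Z)) {
    qz <- qr(scale(Z, scale = FALSE))
    fit_z <- qr.fitted(qz, Yc)
    cond <- sum(fit_z^2)
    Yc <- Yc - fit_z
    Xc <- Xc - qr.fitted(qz, Xc)
  }
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(Xc)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(dropped %||% "unnamed", collapse = ", "))
  }
  fitted <- qr.fitted(qx, Yc)
  constrained <- sum(fitted^2)
  residual <- sum((Yc - fitted)^2)

  df_res <- n - 1L - df_x - df_z
  Fstat <- (constrained / df_x) / (residual / df_res)
  R2 <- constrained / total
  adj_R2 <- 1 - (1 - R2) * (n - 1) / (n - 1 - df_x - df_z)

  site <- species <- biplot <- NULL
  eig <- NULL
  if (scores) {
    sv <- svd(fitted / sqrt(n - 1))
    pos <- sv$d^2 > max(sv$d^2, 0) * 1e-12
    d <- sv$d[pos]
    eig <- d^2
    site <- sv$u[, pos, drop = FALSE] %*% diag(d * sqrt(n - 1), sum(pos))
    species <- sv$v[, pos, drop = FALSE] %*% diag(d, sum(pos))
    rownames(site) <- rownames(Y)
    rownames(species) <- colnames(Y)
    ax <- paste0("RDA", seq_len(sum(pos)))
    colnames(site) <- colnames(species) <- ax
    biplot <- if (sum(pos) > 0) stats::cor(Xc, site) else NULL
  }

  structure(list(total_inertia = total / (n - 1),
                 conditioned_inertia = cond / (n - 1),
                 constrained_inertia = constrained / (n - 1),
                 residual_inertia = residual / (n - 1),
                 R2 = R2, adj_R2 = adj_R2, F = Fstat,
                 df = c(df_x, df_res), eig = eig,
                 site_scores = site, species_scores = species,
                 biplot_scores = biplot, n = n),
            class = "rda_fit")
}

as_response_matrix <- function(Y) {
  if (inherits(Y, "clr_matrix")) return(Y$values)
  if (inherits(Y, "abundance_table")) return(Y$values)
  as.matrix(Y)
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis\n")
  cat(sprintf("  inertia (variance): total %.4f | conditioned %.4f | constrained %.4f | residual %.4f\n",
              x$total_inertia, x$conditioned_inertia, x$constrained_inertia,
              x$residual_inertia))
  cat(sprintf("  R2 = %.4f (adjusted %.4f), F(%d, %d) = %.4f\n",
              x$R2, x$adj_R2, x$df[1], x$df[2], x$F))
  invisible(x)
}

#' Permutation test for (partial) RDA
#'
#' Simple effects (`Z = NULL`) permute rows of the response; conditional
#' effects use reduced-model permutation: the response is decomposed into
#' fitted values on `Z` plus residuals, the residuals are permuted, and
#' the conditioning structure is retained. The p-value uses the add-one
#' convention `p = (1 + #{F* >= F}) / (1 + n_perm)`, so its floor is
#' `1 / (n_perm + 1)`.
#'
#' In a repeated-measures cohort, the two samples of one infant are
#' correlated, so rows are *not* freely exchangeable when testing a
#' between-infant factor: free permutation is anti-conservative there.
#' Supplying `blocks` (the infant identifier) restricts the permutations:
#' `type = "blocks"` permutes whole infants as units (for between-infant
#' factors such as childcare group), `type = "within"` permutes rows
#' within each infant (for pure within-infant factors such as time).
#'
#' @inheritParams fit_rda
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param blocks optional factor of length `nrow(Y)` defining
#'   exchangeability blocks (e.g. infant ids; equal block sizes required
#'   for `type = "blocks"`).
#' @param type `"free"` (default), `"blocks"` or `"within"`; ignored when
#'   `blocks` is `NULL`.
#' @return List with `F`, `p`, `n_perm`, and the observed `rda_fit`.
#' @export
permutation_test <- function(Y, X, Z = NULL, n_perm = 999L, seed = 1L,
                             blocks = NULL, type = c("free", "blocks", "within")) {
  type <- match.arg(type)
  if (is.null(blocks)) type <- "free"
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  obs <- fit_rda(Y, X, Z)
  Y <- as_response_matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  if (is.null(Z) || type != "free") {
    # raw-response permutation (Manly). For restricted schemes the
    # reduced-model residuals are *not* exchangeable under the block
    # structure when a conditioning covariate is aligned with it (age
    # runs along the within-infant direction), which badly miscalibrates
    # the residual scheme; permuting raw rows within the exchangeability
    # structure is the robust choice.
    base <- Yc
    add <- 0
  } else {
    # Freedman-Lane: permute reduced-model residuals, keep the fitted part
    qz <- qr(scale(as.matrix(Z), scale = FALSE))
    add <- qr.fitted(qz, Yc)
    base <- Yc - add
  }
  next_idx <- permutation_sampler(n, blocks, type)
  f_perm <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Yp <- base[next_idx(), , drop = FALSE] + add
      f_perm[b] <- fit_rda(Yp, X, Z, scores = FALSE)$F
    }
  })
  p <- (1 + sum(f_perm >= obs$F)) / (1 + n_perm)
  list(F = obs$F, p = p, n_perm = as.integer(n_perm), fit = obs)
}

# returns a closure drawing one permutation index vector per call
permutation_sampler <- function(n, blocks, type) {
  if (type == "free") return(function() sample.int(n))
  blocks <- as.factor(blocks)
  split_idx <- split(seq_len(n), blocks)
  if (type == "blocks") {
    sizes <- lengths(split_idx)
    if (length(unique(sizes)) != 1L)
      stopf("block permutation requires equal block sizes")
    J <- length(split_idx)
    pos <- unlist(split_idx, use.names = FALSE)
    function() {
      idx <- integer(n)
      idx[pos] <- unlist(split_idx[sample.int(J)], use.names = FALSE)
      idx
    }
  } else {
    function() {
      idx <- integer(n)
      for (g in split_idx) idx[g] <- g[sample.int(length(g))]
      idx
    }
  }
}

#' Build the standard covariate blocks for ordination
#'
#' Expands cohort metadata into named predictor blocks: `Time`, `CC`,
#' `Age`, `Sibling`, `Birth-mode`, `Breastfeeding` (two columns — the
#' feeding rates before and during the investigative period) and
#' `CC x Time` (three columns: group, time and their product, tested as
#' one block). Binary variables use 0/1 treatment coding; continuous
#' variables stay on their raw scale (RDA results are invariant to
#' location/scale of single-column predictors).
#'
#' @param meta a validated `sample_metadata` frame (breastfeeding complete;
#'   rows with missing breastfeeding are rejected — impute or drop first).
#' @param include_cc_time include the `CC x Time` interaction block.
#' @return Named list of numeric matrices with aligned rows.
#' @export
design_blocks <- function(meta, include_cc_time = TRUE) {
  if (anyNA(meta$bf_rate) || anyNA(meta$bf_rate_prior_period))
    stopf("breastfeeding covariates contain missing values; impute (pmm_impute) or subset first")
  cc <- as.numeric(meta$group == "CC")
  tm <- as.numeric(meta$timepoint == "POST")
  blocks <- list(
    Time = cbind(time = tm),
    CC = cbind(cc = cc),
    Age = cbind(age = meta$age_days),
    Sibling = cbind(sib = as.numeric(meta$sibling)),
    `Birth-mode` = cbind(csec = as.numeric(meta$csection)),
    Breastfeeding = cbind(bf_rate = meta$bf_rate,
                          bf_prior = meta$bf_rate_prior_period))
  if (include_cc_time)
    blocks$`CC x Time` <- cbind(cc = cc, time = tm, `cc:time` = cc * tm)
  blocks
}

#' Simple and conditional effects of covariate blocks
#'
#' For each predictor block, computes the simple effect (the block alone)
#' and the conditional effect (all other blocks partialled out). Blocks
#' sharing a column name with the tested block — e.g. the `CC x Time`
#' interaction block contains the `CC` and `Time` columns — are excluded
#' from the conditioning set to avoid self-conditioning.
#'
#' @param Y response (`clr_matrix` or matrix).
#' @param blocks named list of design matrices, e.g. from
#'   [design_blocks()].
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param exchange_blocks optional factor (e.g. infant ids) defining
#'   exchangeability blocks for the permutation tests. Terms whose
#'   columns all vary within every block (pure within-infant factors,
#'   i.e. Time) are then permuted within blocks; all other terms permute
#'   whole blocks as units. `NULL` permutes rows freely.
#' @return A data frame with one row per block and mode (`simple` /
#'   `conditional`) and columns `term`, `mode`, `df`, `variance`, `F`,
#'   `p`, `R2`, `adj_R2`.
#' @export
effects_table <- function(Y, blocks, n_perm = 999L, seed = 1L,
                          exchange_blocks = NULL) {
  stopifnot(is.list(blocks), length(blocks) >= 1L, !is.null(names(blocks)))
  rows <- list()
  for (bi in seq_along(blocks)) {
    nm <- names(blocks)[bi]
    B <- as.matrix(blocks[[bi]])
    others <- blocks[-bi]
    keep <- vapply(others, function(o)
      length(intersect(colnames(o), colnames(B))) == 0L, logical(1))
    Zmat <- if (length(others[keep]) > 0L) do.call(cbind, others[keep]) else NULL
    ptype <- if (is.null(exchange_blocks)) "free"
             else if (varies_within_all_blocks(B, exchange_blocks)) "within"
             else "blocks"
    for (mode in c("simple", "conditional")) {
      Zu <- if (mode == "simple") NULL else Zmat
      if (mode == "conditional" && is.null(Zu)) next
      pt <- permutation_test(Y, B, Zu, n_perm = n_perm,
                             seed = derive_seed(seed, paste(nm, mode)),
                             blocks = exchange_blocks, type = ptype)
      rows[[length(rows) + 1L]] <- data.frame(
        term = nm, mode = mode, df = pt$fit$df[1],
        variance = pt$fit$constrained_inertia, F = pt$F, p = pt$p,
        R2 = pt$fit$R2, adj_R2 = pt$fit$adj_R2, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance partitioning over predictor blocks
#'
#' Fits an RDA for every nonempty subset of 2-4 predictor blocks and
#' decomposes the full-model explained variance into unique and shared
#' Venn fractions by Moebius inversion (inclusion-exclusion) on subset
#' R-squared values. Small negative fractions can legitimately arise and
#' are reported as-is, not clipped. Both raw and Ezekiel-adjusted
#' fractions are returned; the adjusted ones are the convention of
#' ecology's variance-partitioning literature.
#'
#' @inheritParams effects_table
#' @return List with `regions` (data frame: one row per Venn region,
#'   columns `region`, `fraction`, `fraction_adj`), `unique` and `simple`
#'   per-block fractions, and `full_R2` / `full_adj_R2`.
#' @export
variance_partition <- function(Y, blocks) {
  nb <- length(blocks)
  if (nb < 2L || nb > 4L)
    stopf("variance_partition supports 2-4 blocks (got %d)", nb)
  nms <- names(blocks)
  subsets <- lapply(seq_len(2^nb - 1L), function(m) which(bitwAnd(m, 2^(seq_len(nb) - 1L)) > 0))
  Ym <- as_response_matrix(Y)
  Yc <- scale(Ym, scale = FALSE)
  tot <- sum(Yc^2)
  n <- nrow(Ym)
  # subset models may be collinear across blocks (overlapping predictors);
  # project onto the column space via pivoted QR instead of erroring
  subset_r2 <- function(X) {
    Xc <- scale(as.matrix(X), scale = FALSE)
    q <- qr(Xc)
    R2 <- sum(qr.fitted(q, Yc)^2) / tot
    c(R2, 1 - (1 - R2) * (n - 1) / (n - 1 - q$rank))
  }
  r2 <- adj <- numeric(2^nb - 1L)
  for (i in seq_along(subsets)) {
    both <- subset_r2(do.call(cbind, blocks[subsets[[i]]]))
    r2[i] <- both[1]
    adj[i] <- both[2]
  }
  g <- function(set, vals) if (length(set) == 0L) 0 else vals[[match_subset(set, subsets)]]
  full_idx <- match_subset(seq_len(nb), subsets)
  # h(C) = R2(all) - R2(all \ C); Moebius inversion over the subset lattice
  region_val <- function(vals) {
    h <- function(C) vals[full_idx] - g(setdiff(seq_len(nb), C), vals)
    sapply(subsets, function(T) {
      subs_of_T <- Filter(function(U) all(U %in% T), c(list(integer(0)), subsets))
      sum(vapply(subs_of_T, function(U)
        (-1)^(length(T) - length(U)) * (if (length(U) == 0L) 0 else h(U)),
        numeric(1)))
    })
  }
  fr <- region_val(r2)
  fr_adj <- region_val(adj)
  region_names <- vapply(subsets, function(s) paste(nms[s], collapse = ":"),
                         character(1))
  regions <- data.frame(region = region_names, fraction = fr,
                        fraction_adj = fr_adj, stringsAsFactors = FALSE)
  uniq <- fr[vapply(subsets, length, integer(1)) == 1L]
  names(uniq) <- nms
  simple <- r2[vapply(subsets, length, integer(1)) == 1L]
  names(simple) <- nms
  list(regions = regions, unique = uniq, simple = simple,
       full_R2 = r2[full_idx], full_adj_R2 = adj[full_idx])
}

# TRUE when every column of B is non-constant inside every block
varies_within_all_blocks <- function(B, blocks) {
  split_rows <- split(seq_len(nrow(B)), as.factor(blocks))
  all(vapply(split_rows, function(g) {
    if (length(g) < 2L) return(FALSE)
    all(apply(B[g, , drop = FALSE], 2L, function(col) length(unique(col)) > 1L))
  }, logical(1)))
}

match_subset <- function(set, subsets) {
  for (i in seq_along(subsets))
    if (length(subsets[[i]]) == length(set) && all(subsets[[i]] == sort(set)))
      return(i)
  stopf("internal: subset not found")
}
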
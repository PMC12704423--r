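#' Log2-transform a raw abundance matrix
#'
#' @param am An [abundance_matrix()] on the raw scale.
#' @return The same object with `log2(intensity)` values and `log2 = TRUE`.
#'   Missing entries are preserved.
#' @export
log2_transform <- function(am) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (am$log2) stop("matrix is already on the log2 scale")
  bad <- which(!is.na(am$intensities) & am$intensities <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive intensity for protein '%s', sample '%s'",
                 rownames(am$intensities)[bad[1L, 1L]],
                 colnames(am$intensities)[bad[1L, 2L]]))
  am$intensities <- log2(am$intensities)
  am$log2 <- TRUE
  am
}

group_columns <- function(am, group) {
  idx <- which(am$design == group)
  if (!length(idx)) stop("no samples in group '", group, "'")
  idx
}

#' Per-protein log2 fold change between two groups
#'
#' The fold change is the difference of per-group means of log2 intensities
#' (test minus reference), not the log2 of the ratio of mean raw intensities.
#' Proteins with fewer than two present values in either group are returned
#' as `NA` (untestable).
#'
#' @param am A log2-scale [abundance_matrix()].
#' @param reference_group,test_group Group labels in the design.
#' @return Named numeric vector of log2 fold changes, one per protein.
#' @export
group_log2fc <- function(am, reference_group, test_group) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (!am$log2) stop("log2-transform the matrix first")
  ref <- am$intensities[, group_columns(am, reference_group), drop = FALSE]
  tst <- am$intensities[, group_columns(am, test_group), drop = FALSE]
  n_ref <- rowSums(!is.na(ref))
  n_tst <- rowSums(!is.na(tst))
  fc <- rowMeans(tst, na.rm = TRUE) - rowMeans(ref, na.rm = TRUE)
  fc[n_ref < 2L | n_tst < 2L] <- NA_real_
  fc
}

#' Express a log2 fold change as percent of the reference level
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return `2^log2fc * 100`, full precision. Use [format_percent()] for the
#'   conventional reporting style (one decimal below 10%, integer above).
#' @export
percent_of_reference <- function(log2fc) 2^log2fc * 100

#' Round a percentage for reporting
#'
#' One decimal place below 10, integer at or above 10.
#'
#' @param pct Numeric vector of percentages.
#' @return Numeric vector of rounded percentages.
#' @export
format_percent <- function(pct) ifelse(abs(pct) < 10, round(pct, 1L), round(pct))

#' Differential protein abundance between two genotype groups
#'
#' Two-sample t-test per protein on log2 intensities (Student's pooled-variance
#' test by default, the standard choice for this kind of matrix; Welch
#' available via `var_equal = FALSE`), Benjamini-Hochberg adjustment over all
#' testable proteins, and a significance flag requiring both the FDR and the
#' fold-change cut-off.
#'
#' @param am A log2-scale [abundance_matrix()].
#' @param reference_group,test_group Group labels in the design.
#' @param fdr_threshold Significance requires `q < fdr_threshold` (default 0.1).
#' @param fc_threshold Significance requires `|log2fc| > fc_threshold`
#'   (default 0.5, strict).
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return Data frame with one row per protein: `protein`, `log2fc`,
#'   `percent_of_reference`, `percent_reduction`, `t_statistic`, `p_value`,
#'   `q_value`, `significant`, `untestable`. Untestable proteins (fewer than
#'   two present values in a group) carry `NA` statistics and are excluded
#'   from the BH family.
#' @export
differential_test <- function(am, reference_group, test_group,
                              fdr_threshold = 0.1, fc_threshold = 0.5,
                              var_equal = TRUE) {
  stopifnot(inherits(am, "abundance_matrix"))
  if (!am$log2) stop("log2-transform the matrix first")
  ref <- am$intensities[, group_columns(am, reference_group), drop = FALSE]
  tst <- am$intensities[, group_columns(am, test_group), drop = FALSE]
  fc <- group_log2fc(am, reference_group, test_group)
  n <- nrow(am$intensities)
  t_stat <- p_val <- rep(NA_real_, n)
  testable <- rowSums(!is.na(ref)) >= 2L & rowSums(!is.na(tst)) >= 2L
  for (i in which(testable)) {
    x <- tst[i, !is.na(tst[i, ])]
    y <- ref[i, !is.na(ref[i, ])]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # identical constant groups carry no evidence; avoid t.test error
      t_stat[i] <- 0
      p_val[i] <- 1
      if (mean(x) != mean(y)) { t_stat[i] <- Inf * sign(mean(x) - mean(y)); p_val[i] <- 0 }
      next
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    t_stat[i] <- unname(tt$statistic)
    p_val[i] <- tt$p.value
  }
  q_val <- rep(NA_real_, n)
  q_val[testable] <- stats::p.adjust(p_val[testable], method = "BH")
  pct <- percent_of_reference(fc)
  data.frame(
    protein = rownames(am$intensities),
    log2fc = unname(fc),
    percent_of_reference = unname(pct),
    percent_reduction = 100 - unname(pct),
    t_statistic = t_stat,
    p_value = p_val,
    q_value = q_val,
    significant = !is.na(q_val) & q_val < fdr_threshold & abs(fc) > fc_threshold,
    untestable = !testable,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardize a log2 abundance matrix for heatmap display
#'
#' `center_rows` subtracts the per-protein mean across samples.
#' `dataset_zscore_then_row_center` first standardizes each dataset by
#' subtracting the global mean and dividing by the global variance across all
#' of its values, then subtracts each row's within-dataset mean; used when
#' juxtaposing matrices from different experiments.
#'
#' @param mat Numeric matrix of log2 abundances (proteins x samples).
#' @param mode `"center_rows"` or `"dataset_zscore_then_row_center"`.
#' @param datasets For the dataset mode, a vector assigning each column to a
#'   dataset; default treats the whole matrix as one dataset.
#' @return Matrix of the same shape.
#' @export
standardize_for_heatmap <- function(mat,
                                    mode = c("center_rows",
                                             "dataset_zscore_then_row_center"),
                                    datasets = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (mode == "center_rows")
    return(mat - rowMeans(mat, na.rm = TRUE))
  if (is.null(datasets)) datasets <- rep("dataset", ncol(mat))
  stopifnot(length(datasets) == ncol(mat))
  out <- mat
  for (d in unique(datasets)) {
    cols <- datasets == d
    block <- mat[, cols, drop = FALSE]
    v <- stats::var(as.vector(block), na.rm = TRUE)
    if (!is.finite(v) || v == 0) stop("zero variance in dataset '", d, "'")
    block <- (block - mean(block, na.rm = TRUE)) / v
    block <- block - rowMeans(block, na.rm = TRUE)
    out[, cols] <- block
  }
  out
}

#' Pearson correlation of two paired log2 fold-change vectors
#'
#' Pairs with a missing or non-finite value on either side are dropped.
#'
#' @param fc_a,fc_b Numeric vectors. If both are named, they are matched on
#'   the intersection of names; otherwise they must be the same length.
#' @return List with `r`, `p_value` and `n` (pairs used).
#' @export
correlate_log2fc <- function(fc_a, fc_b) {
  if (!is.null(names(fc_a)) && !is.null(names(fc_b))) {
    shared <- intersect(names(fc_a), names(fc_b))
    fc_a <- fc_a[shared]; fc_b <- fc_b[shared]
  } else if (length(fc_a) != length(fc_b)) {
    stop("unnamed fold-change vectors must have equal length")
  }
  keep <- is.finite(fc_a) & is.finite(fc_b)
  if (sum(keep) < 3L) stop("fewer than 3 finite shared pairs")
  ct <- stats::cor.test(fc_a[keep], fc_b[keep], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}
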
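#' Per-cell QC on scRNA-seq summary metrics
#'
#' A cell passes when total reads >= 4 million, mitochondrial reads < 2%,
#' rRNA < 10%, percent of genes measured within \[37, 50\] (closed), and
#' uniquely mapped reads > 70%. Every violated bound is listed.
#'
#' @param metrics Data frame with columns `cell_id`, `total_reads`,
#'   `pct_mito`, `pct_rrna`, `pct_genes_measured`, `pct_unique_mapped`.
#' @param min_reads,max_mito,max_rrna,genes_measured_range,min_unique_mapped
#'   Threshold overrides.
#' @return Data frame `cell_id`, `pass`, `reasons` (semicolon-separated
#'   violated bounds, empty when passing).
#' @export
qc_cells <- function(metrics, min_reads = 4e6, max_mito = 2, max_rrna = 10,
                     genes_measured_range = c(37, 50),
                     min_unique_mapped = 70) {
  need <- c("cell_id", "total_reads", "pct_mito", "pct_rrna",
            "pct_genes_measured", "pct_unique_mapped")
  stopifnot(all(need %in% names(metrics)))
  checks <- list(
    reads = metrics$total_reads >= min_reads,
    mito = metrics$pct_mito < max_mito,
    rrna = metrics$pct_rrna < max_rrna,
    genes_measured = metrics$pct_genes_measured >= genes_measured_range[1L] &
      metrics$pct_genes_measured <= genes_measured_range[2L],
    unique_mapped = metrics$pct_unique_mapped > min_unique_mapped)
  ok <- Reduce(`&`, checks)
  reasons <- apply(do.call(cbind, checks), 1L, function(row)
    paste(names(checks)[!row], collapse = ";"))
  data.frame(cell_id = metrics$cell_id, pass = ok, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Marker-based NSN/SN staging of oocyte transcriptomes
#'
#' Expression is normalized to log1p counts-per-million; each marker gene is
#' z-scored across cells (zero-variance genes contribute 0); the staging
#' score is the mean z of SN markers minus the mean z of NSN markers. Cells
#' score SN above `margin`, NSN below `-margin`, and are otherwise
#' ambiguous. Cells with no marker counts at all are ambiguous by
#' definition.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param nsn_markers,sn_markers Disjoint marker gene id sets, each with at
#'   least 3 genes present in the matrix.
#' @param margin Symmetric score margin (default 0.5).
#' @return Data frame `cell_id`, `stage` (`"NSN"`, `"SN"`, `"ambiguous"`),
#'   `score`.
#' @export
stage_cells <- function(counts, nsn_markers, sn_markers, margin = 0.5) {
  if (length(intersect(nsn_markers, sn_markers)))
    stop("marker sets must be disjoint")
  nsn <- intersect(nsn_markers, rownames(counts))
  sn <- intersect(sn_markers, rownames(counts))
  if (length(nsn) < 3L || length(sn) < 3L)
    stop("each marker set needs at least 3 genes present in the matrix")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  lcpm <- log1p(t(t(counts) / lib) * 1e6)
  zrow <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z <- t(apply(lcpm[c(nsn, sn), , drop = FALSE], 1L, zrow))
  score <- colMeans(z[sn, , drop = FALSE]) - colMeans(z[nsn, , drop = FALSE])
  no_signal <- colSums(counts[c(nsn, sn), , drop = FALSE]) == 0
  score[no_signal] <- 0
  stage <- ifelse(score > margin, "SN", ifelse(score < -margin, "NSN", "ambiguous"))
  data.frame(cell_id = colnames(counts), stage = stage, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Threshold per-gene differential expression results
#'
#' Benjamini-Hochberg adjustment of the supplied p-values, then a
#' significance flag with inclusive cut-offs: `q <= fdr` and
#' `|log2fc| >= fc`.
#'
#' @param results Data frame with columns `gene`, `log2fc`, `p`.
#' @param fdr FDR cut-off (default 0.05, inclusive).
#' @param fc Absolute log2 fold-change cut-off (default 0.5, inclusive).
#' @return `results` with added `q` and `significant` columns.
#' @export
threshold_degs <- function(results, fdr = 0.05, fc = 0.5) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(results)))
  if (any(results$p < 0 | results$p > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  results$q <- stats::p.adjust(results$p, method = "BH")
  results$significant <- !is.na(results$q) & results$q <= fdr &
    abs(results$log2fc) >= fc
  results
}

#' Combine stage-wise DEG sets
#'
#' @param nsn_degs,sn_degs Character vectors of gene ids.
#' @return List with `union` (unique genes significant in either stage) and
#'   `shared` (genes significant in both).
#' @export
combine_stage_degs <- function(nsn_degs, sn_degs) {
  list(union = union(nsn_degs, sn_degs),
       shared = intersect(nsn_degs, sn_degs))
}

#' Surrogate per-gene differential expression test
#'
#' A simple library-size-normalized test: log2(CPM + 1) per cell, then a
#' Welch t-test per gene between the two groups. This is a deliberately
#' plain surrogate for a negative-binomial DE model -- it does not reproduce
#' shrinkage-based estimators, and externally computed per-gene result
#' tables in the same schema can be used with [threshold_degs()] instead.
#' Genes with zero counts in all cells are excluded.
#'
#' @param counts Genes x cells count matrix.
#' @param groups Character vector of group labels, one per cell.
#' @param reference_group,test_group Labels to compare; `log2fc` is test
#'   minus reference mean log2(CPM + 1).
#' @return Data frame `gene`, `log2fc`, `p` for tested genes.
#' @export
surrogate_de_test <- function(counts, groups, reference_group, test_group) {
  stopifnot(ncol(counts) == length(groups))
  a <- which(groups == reference_group)
  b <- which(groups == test_group)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 cells per group")
  keep <- rowSums(counts) > 0
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  lcpm <- log2(t(t(counts[keep, , drop = FALSE]) / lib) * 1e6 + 1)
  welch <- function(x_cols, y_cols) {
    nx <- length(x_cols); ny <- length(y_cols)
    mx <- rowMeans(lcpm[, x_cols, drop = FALSE])
    my <- rowMeans(lcpm[, y_cols, drop = FALSE])
    vx <- apply(lcpm[, x_cols, drop = FALSE], 1L, stats::var)
    vy <- apply(lcpm[, y_cols, drop = FALSE], 1L, stats::var)
    se2 <- vx / nx + vy / ny
    t_stat <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
    p[se2 == 0] <- 1  # identical constant expression carries no evidence
    list(fc = mx - my, p = p)
  }
  w <- welch(b, a)
  data.frame(gene = rownames(lcpm), log2fc = unname(w$fc), p = unname(w$p),
             stringsAsFactors = FALSE)
}
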
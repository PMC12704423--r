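#' Hypergeometric overlap test between two feature sets
#'
#' Tests whether the overlap `k` between `set_a` (size `K`) and `set_b`
#' (size `n`) drawn from a universe of size `N` is larger than expected:
#' upper-tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. A depletion
#' (lower-tail) test is available via `alternative = "depletion"`.
#'
#' @param set_a,set_b Character vectors of feature ids; both must be subsets
#'   of `universe`.
#' @param universe Character vector of all eligible features.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return List of class `overlap_result`: `N`, `K`, `n`, `k`, `expected`
#'   overlap and `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe,
                                   alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad))
    stop("features outside the universe: ", paste(utils::head(bad, 5L), collapse = ", "))
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- if (alternative == "enrichment")
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  structure(list(N = N, K = K, n = n, k = k,
                 expected = K * n / max(N, 1L), p_value = p,
                 alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of sets sized %d and %d in universe %d (expected %.2f)\n",
              x$k, x$K, x$n, x$N, x$expected))
  cat(sprintf("hypergeometric %s p = %.4g\n", x$alternative, x$p_value))
  invisible(x)
}

#' Pair transcript and protein fold changes across omic layers
#'
#' Joins per-gene and per-protein differential results through a one-to-one
#' feature map and reports the paired table plus the Pearson correlation of
#' the log2 fold changes (via [correlate_log2fc()]).
#'
#' @param deg_records Data frame with `gene`, `log2fc` and optionally
#'   `significant`.
#' @param dap_records Data frame with `protein`, `log2fc` and optionally
#'   `significant`.
#' @param map Data frame with columns `gene_id`, `protein_id`; the mapping
#'   must be one-to-one on the mapped subset.
#' @return List with `pairs` (feature, rna_log2fc, protein_log2fc,
#'   both_significant), `r`, `p_value`, `n`.
#' @export
paired_fc_scatter <- function(deg_records, dap_records, map) {
  stopifnot(all(c("gene_id", "protein_id") %in% names(map)))
  if (anyDuplicated(map$gene_id) || anyDuplicated(map$protein_id))
    stop("feature map must be one-to-one")
  gi <- match(map$gene_id, deg_records$gene)
  pi <- match(map$protein_id, dap_records$protein)
  ok <- !is.na(gi) & !is.na(pi)
  pairs <- data.frame(
    gene_id = map$gene_id[ok], protein_id = map$protein_id[ok],
    rna_log2fc = deg_records$log2fc[gi[ok]],
    protein_log2fc = dap_records$log2fc[pi[ok]],
    both_significant =
      (if ("significant" %in% names(deg_records))
         deg_records$significant[gi[ok]] else FALSE) &
      (if ("significant" %in% names(dap_records))
         dap_records$significant[pi[ok]] else FALSE),
    stringsAsFactors = FALSE)
  finite <- is.finite(pairs$rna_log2fc) & is.finite(pairs$protein_log2fc)
  if (sum(finite) < 3L) stop("fewer than 3 mapped pairs with finite fold changes")
  ct <- correlate_log2fc(pairs$rna_log2fc[finite], pairs$protein_log2fc[finite])
  list(pairs = pairs, r = ct$r, p_value = ct$p_value, n = ct$n)
}
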
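#' Pearson chi-square test on a 2x2 table of methylation calls
#'
#' Degrees of freedom 1, no continuity correction; the convention used for
#' pseudo-bulk differential methylation calls.
#'
#' @param a,b Methylated and unmethylated calls in group A.
#' @param c,d Methylated and unmethylated calls in group B.
#' @return List with `chi2` and `p` (two-sided).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("degenerate margin: every row and column sum must be positive")
  res <- chi2_2x2_vec(a, b, c, d)
  list(chi2 = res$chi2, p = res$p)
}

# Vectorized Pearson chi-square; degenerate margins yield chi2 = 0, p = 1
# (no methylation difference is expressible on such a table).
chi2_2x2_vec <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0 & n > 0
  chi2 <- rep(0, length(a))
  e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2)[ok, , drop = FALSE] / n[ok]
  o <- cbind(a, b, c, d)[ok, , drop = FALSE]
  chi2[ok] <- rowSums((o - e)^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[!ok] <- 1
  list(chi2 = chi2, p = p)
}

# Shared chi-square + BH machinery for tiles and regions.
diff_meth_table <- function(id, meth_a, unmeth_a, meth_b, unmeth_b,
                            alpha, min_diff) {
  calls_a <- meth_a + unmeth_a
  calls_b <- meth_b + unmeth_b
  pct_a <- ifelse(calls_a > 0, 100 * meth_a / calls_a, NA_real_)
  pct_b <- ifelse(calls_b > 0, 100 * meth_b / calls_b, NA_real_)
  cs <- chi2_2x2_vec(meth_a, unmeth_a, meth_b, unmeth_b)
  q <- stats::p.adjust(cs$p, method = "BH")
  delta <- pct_b - pct_a
  data.frame(id = id, pct_a = pct_a, pct_b = pct_b, delta = delta,
             calls_a = calls_a, calls_b = calls_b,
             chi2 = cs$chi2, p = cs$p, q = q,
             significant = q < alpha & abs(delta) > min_diff,
             stringsAsFactors = FALSE)
}

#' Call differentially methylated 100-CpG tiles between two pseudo-bulks
#'
#' Per tile, a Pearson chi-square test (df 1, no continuity correction) on
#' the 2x2 table of pooled methylated/unmethylated calls, Benjamini-Hochberg
#' adjustment over all tested tiles, and a call requiring adjusted p below
#' `alpha` and an absolute methylation difference strictly above `min_diff`
#' percentage points. Tiles below `min_calls` in either group are excluded
#' before testing, as are tiles outside `domain_filter` when given.
#'
#' @param tileset A [build_tiles()] result.
#' @param bulk_a,bulk_b Pseudo-bulk [cell_methylome()] objects (reference
#'   group first; `delta = pct_b - pct_a`).
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @param min_diff Strict percentage-point difference cut-off (default 25).
#' @param min_calls Minimum calls per tile in each group (default 30).
#' @param domain_filter Optional [region_set()]; only tiles fully contained
#'   in a `hypo_domain` / `hyper_domain` row are tested.
#' @return Data frame with per-tile percentages, `delta`, `chi2`, `p`, `q`
#'   and `significant`.
#' @export
call_dmrs <- function(tileset, bulk_a, bulk_b, alpha = 0.05, min_diff = 25,
                      min_calls = 30L, domain_filter = NULL) {
  ca <- tile_counts(tileset, bulk_a)
  cb <- tile_counts(tileset, bulk_b)
  keep <- (ca$meth + ca$unmeth) >= min_calls & (cb$meth + cb$unmeth) >= min_calls
  if (!is.null(domain_filter)) {
    dom <- domain_filter[domain_filter$class %in% c("hypo_domain", "hyper_domain"), ,
                         drop = FALSE]
    tiles <- tileset$tiles
    inside <- vapply(seq_len(nrow(tiles)), function(i) {
      any(dom$chrom == tiles$chrom[i] & dom$start <= tiles$start[i] &
            dom$end >= tiles$end[i])
    }, logical(1))
    keep <- keep & inside
  }
  res <- diff_meth_table(tileset$tiles$tile_id[keep],
                         ca$meth[keep], ca$unmeth[keep],
                         cb$meth[keep], cb$unmeth[keep], alpha, min_diff)
  names(res)[1L] <- "tile_id"
  res
}

#' Quantify percent methylation over annotated regions
#'
#' Calls are pooled over all CpG sites inside each region (1-based,
#' inclusive); regions with fewer than `min_calls` calls are missing.
#'
#' @param regions A [region_set()].
#' @param cell A [cell_methylome()] (typically a pseudo-bulk).
#' @param min_calls Minimum pooled calls (default 20, the germline-DMR
#'   setting).
#' @return Data frame `name`, `class`, `chrom`, `start`, `end`, `meth`,
#'   `calls`, `pct` (`NA` below `min_calls`), `calls_per_kb`.
#' @export
quantify_regions <- function(regions, cell, min_calls = 20L) {
  stopifnot(min_calls >= 1L)
  s <- cell$sites
  meth <- calls <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    rsel <- which(regions$chrom == ch)
    ssel <- which(s$chrom == ch)
    if (!length(ssel)) next
    pos <- s$pos[ssel]
    o <- order(pos)
    pos <- pos[o]
    cm <- cumsum(s$meth[ssel][o])
    ct <- cumsum((s$meth + s$unmeth)[ssel][o])
    lo <- findInterval(regions$start[rsel] - 1L, pos)
    hi <- findInterval(regions$end[rsel], pos)
    meth[rsel] <- c(0, cm)[hi + 1L] - c(0, cm)[lo + 1L]
    calls[rsel] <- c(0, ct)[hi + 1L] - c(0, ct)[lo + 1L]
  }
  width_kb <- (regions$end - regions$start + 1L) / 1000
  data.frame(name = regions$name, class = regions$class, chrom = regions$chrom,
             start = regions$start, end = regions$end,
             meth = meth, calls = calls,
             pct = ifelse(calls >= min_calls, 100 * meth / calls, NA_real_),
             calls_per_kb = calls / width_kb, stringsAsFactors = FALSE)
}

#' Test germline DMRs for differential methylation between two pseudo-bulks
#'
#' Chi-square and Benjamini-Hochberg as for tiles, computed over whole
#' regions with a minimum of `min_calls` calls per region per group. A region
#' is only called significant when it is also highly covered: strictly more
#' than `min_density` calls per kilobase, in both groups by default
#' (`density_mode = "either"` relaxes this to one group).
#'
#' @param gdmrs A [region_set()] (rows with class `gDMR` are used).
#' @param bulk_a,bulk_b Pseudo-bulk [cell_methylome()] objects (reference
#'   first).
#' @param alpha,min_diff As in [call_dmrs()].
#' @param min_calls Minimum calls per region per group (default 20).
#' @param min_density Coverage filter, calls per 1,000 bp (default 100,
#'   strict).
#' @param density_mode `"both"` (default) or `"either"`.
#' @return Data frame with per-region percentages, `delta`, coverage
#'   densities, `chi2`, `p`, `q`, `coverage_pass` and `significant`.
#' @export
test_gdmrs <- function(gdmrs, bulk_a, bulk_b, alpha = 0.05, min_diff = 25,
                       min_calls = 20L, min_density = 100,
                       density_mode = c("both", "either")) {
  density_mode <- match.arg(density_mode)
  gdmrs <- gdmrs[gdmrs$class == "gDMR", , drop = FALSE]
  qa <- quantify_regions(gdmrs, bulk_a, min_calls = min_calls)
  qb <- quantify_regions(gdmrs, bulk_b, min_calls = min_calls)
  keep <- !is.na(qa$pct) & !is.na(qb$pct)
  res <- diff_meth_table(gdmrs$name[keep],
                         qa$meth[keep], qa$calls[keep] - qa$meth[keep],
                         qb$meth[keep], qb$calls[keep] - qb$meth[keep],
                         alpha, min_diff)
  names(res)[1L] <- "name"
  res$calls_per_kb_a <- qa$calls_per_kb[keep]
  res$calls_per_kb_b <- qb$calls_per_kb[keep]
  res$coverage_pass <- if (density_mode == "both")
    res$calls_per_kb_a > min_density & res$calls_per_kb_b > min_density
  else
    res$calls_per_kb_a > min_density | res$calls_per_kb_b > min_density
  res$significant <- res$significant & res$coverage_pass
  res
}

#' Keep CpG islands hypermethylated in at least one group
#'
#' @param names Region names.
#' @param pct_a,pct_b Percent methylation per group.
#' @param min_pct Strict threshold (default 75).
#' @return Character vector of retained names.
#' @export
filter_hyper_cgis <- function(names, pct_a, pct_b, min_pct = 75) {
  keep <- (!is.na(pct_a) & pct_a > min_pct) | (!is.na(pct_b) & pct_b > min_pct)
  names[keep]
}

#' Global methylation per cell and a two-group comparison
#'
#' Per cell, the unweighted mean percent methylation across informative
#' 100-CpG tiles (at least `min_calls` calls). Cells with no informative
#' tile are excluded with a warning. The group comparison reports a Welch
#' t-test p-value and the difference of group medians (second group minus
#' first).
#'
#' @param cells List of [cell_methylome()] objects with group labels.
#' @param tileset A [build_tiles()] result.
#' @param min_calls Informativeness threshold per tile (default 5).
#' @param groups Optional length-2 character vector fixing group order
#'   (reference first); defaults to sorted unique labels.
#' @return List with `per_cell` (cell, group, n informative tiles, mean pct),
#'   `median_difference`, `p_value`, `groups`.
#' @export
global_methylation <- function(cells, tileset, min_calls = 5L, groups = NULL) {
  per_cell <- do.call(rbind, lapply(cells, function(cell) {
    q <- quantify_tiles(tileset, cell, min_calls = min_calls)
    pct <- q$pct[!is.na(q$pct)]
    data.frame(cell_id = cell$cell_id, group = cell$group,
               n_tiles = length(pct),
               mean_pct = if (length(pct)) mean(pct) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_cell) <- NULL
  if (any(per_cell$n_tiles == 0L)) {
    warning("excluding ", sum(per_cell$n_tiles == 0L),
            " cell(s) with no informative tiles")
    per_cell <- per_cell[per_cell$n_tiles > 0L, ]
  }
  if (is.null(groups)) groups <- sort(unique(per_cell$group))
  if (length(groups) != 2L)
    stop("exactly two groups are required for the comparison")
  a <- per_cell$mean_pct[per_cell$group == groups[1L]]
  b <- per_cell$mean_pct[per_cell$group == groups[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 cells per group for the Welch test")
  p <- if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) 1 else 0   # degenerate: both groups constant
  } else stats::t.test(b, a)$p.value
  list(per_cell = per_cell,
       median_difference = stats::median(b) - stats::median(a),
       p_value = p, groups = groups)
}
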
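#' Read-count QC filter for single-cell methylomes
#'
#' @param cell A [cell_methylome()].
#' @param min_cpgs Minimum CpGs covered (default 600,000; the boundary value
#'   passes).
#' @return `TRUE` (pass) or `FALSE`.
#' @export
qc_read_filter <- function(cell, min_cpgs = 600000L) {
  cell$n_cpgs_covered >= min_cpgs
}

#' X-chromosome CpG-island contamination criterion
#'
#' X-linked CpG islands are essentially unmethylated in oocytes but carry
#' substantial methylation in somatic cells, so pooled methylation above the
#' threshold flags somatic DNA contamination.
#'
#' @param cell A [cell_methylome()].
#' @param regions A [region_set()]; rows with class `CGI` and `x_chrom = TRUE`
#'   are used.
#' @param max_pct Strict flagging threshold in percent (default 10).
#' @return List with `pct` (pooled percent methylation over X CGIs, `NA` when
#'   no calls) and `status` in `"pass"`, `"fail"`, `"untestable"`.
#' @export
qc_x_cgi <- function(cell, regions, max_pct = 10) {
  x_cgi <- regions[regions$class == "CGI" & regions$x_chrom, , drop = FALSE]
  if (!nrow(x_cgi)) return(list(pct = NA_real_, status = "untestable"))
  q <- quantify_regions(x_cgi, cell, min_calls = 1L)
  meth <- sum(q$meth); calls <- sum(q$calls)
  if (calls == 0L) return(list(pct = NA_real_, status = "untestable"))
  pct <- 100 * meth / calls
  list(pct = pct, status = if (pct > max_pct) "fail" else "pass")
}

#' Cytosine-context contamination criterion
#'
#' Oocytes show comparatively high non-CpG methylation; somatic DNA pulls the
#' CHG/CHH fractions down and the CpG fraction up. The normal oocyte ratios
#' are mCpG < 40%, mCHG > 3%, mCHH > 4% (all strict).
#'
#' @param cell A [cell_methylome()] with a context summary.
#' @param max_cpg,min_chg,min_chh Bounds in percent.
#' @return List with the three percentages and `status` in `"pass"`,
#'   `"fail"`, `"untestable"` (missing summary).
#' @export
qc_context <- function(cell, max_cpg = 40, min_chg = 3, min_chh = 4) {
  ctx <- cell$context
  if (is.null(ctx))
    return(list(mCpG = NA_real_, mCHG = NA_real_, mCHH = NA_real_,
                status = "untestable"))
  ok <- ctx[["mCpG"]] < max_cpg && ctx[["mCHG"]] > min_chg && ctx[["mCHH"]] > min_chh
  list(mCpG = ctx[["mCpG"]], mCHG = ctx[["mCHG"]], mCHH = ctx[["mCHH"]],
       status = if (ok) "pass" else "fail")
}

#' Bimodality contamination criterion on 100-CpG tiles
#'
#' Oocyte methylomes are bimodal, with tile methylation peaking at 0% and
#' 100%; somatic contamination pushes tiles into the mid-range. Over
#' informative tiles (at least `min_calls` calls), the fractions of tiles
#' with methylation at or below 25% (`low`), at or above 75% (`high`), and in
#' between (`mid`) are computed; the cell passes when `mid <= max_mid` and
#' both tails hold at least `min_tail` of the tiles.
#'
#' @param cell A [cell_methylome()].
#' @param tileset A [build_tiles()] result.
#' @param min_calls Informativeness threshold per tile (default 5, the
#'   individual-oocyte setting).
#' @param min_tiles Minimum informative tiles to judge the histogram
#'   (default 50; fewer gives `"untestable"`).
#' @param max_mid,min_tail Histogram thresholds (defaults 0.20 and 0.05).
#' @return List with `low`, `mid`, `high`, `n_tiles` and `status`.
#' @export
qc_bimodality <- function(cell, tileset, min_calls = 5L, min_tiles = 50L,
                          max_mid = 0.20, min_tail = 0.05) {
  q <- quantify_tiles(tileset, cell, min_calls = min_calls)
  pct <- q$pct[!is.na(q$pct)]
  if (length(pct) < min_tiles)
    return(list(low = NA_real_, mid = NA_real_, high = NA_real_,
                n_tiles = length(pct), status = "untestable"))
  low <- mean(pct <= 25)
  high <- mean(pct >= 75)
  mid <- 1 - low - high
  ok <- mid <= max_mid && low >= min_tail && high >= min_tail
  list(low = low, mid = mid, high = high, n_tiles = length(pct),
       status = if (ok) "pass" else "fail")
}

#' Screen single-cell methylomes for coverage and somatic contamination
#'
#' Applies the read-count filter and the three independent contamination
#' criteria (X-CGI methylation, cytosine-context ratios, tile bimodality). A
#' cell is retained only when the read filter and all three criteria pass;
#' criteria returning `"untestable"` exclude the cell conservatively. When a
#' cell fails the read filter, the contamination criteria are reported as
#' untested (`NA`) unless `evaluate_failed_reads = TRUE`.
#'
#' @param cells List of [cell_methylome()] objects.
#' @param regions A [region_set()] with X-chromosome CGIs.
#' @param tileset A [build_tiles()] result.
#' @param min_cpgs Read filter threshold (default 600,000).
#' @param evaluate_failed_reads Evaluate contamination criteria even for
#'   low-coverage cells (default `FALSE`).
#' @param ... Threshold overrides passed to [qc_x_cgi()], [qc_context()],
#'   [qc_bimodality()] (`max_pct`, `max_cpg`, `min_chg`, `min_chh`,
#'   `min_calls`, `min_tiles`, `max_mid`, `min_tail`).
#' @return List with `report` (one row per cell: values and verdicts for
#'   every criterion plus `retained`) and `retained` (the retained cells).
#' @export
screen_cells <- function(cells, regions, tileset, min_cpgs = 600000L,
                         evaluate_failed_reads = FALSE, ...) {
  dots <- list(...)
  arg <- function(name, default) if (name %in% names(dots)) dots[[name]] else default
  rows <- lapply(cells, function(cell) {
    read_pass <- qc_read_filter(cell, min_cpgs = min_cpgs)
    if (!read_pass && !evaluate_failed_reads) {
      x <- list(pct = NA_real_, status = NA_character_)
      ctx <- list(mCpG = NA_real_, mCHG = NA_real_, mCHH = NA_real_,
                  status = NA_character_)
      bim <- list(low = NA_real_, mid = NA_real_, high = NA_real_,
                  n_tiles = NA_integer_, status = NA_character_)
    } else {
      x <- qc_x_cgi(cell, regions, max_pct = arg("max_pct", 10))
      ctx <- qc_context(cell, max_cpg = arg("max_cpg", 40),
                        min_chg = arg("min_chg", 3), min_chh = arg("min_chh", 4))
      bim <- qc_bimodality(cell, tileset, min_calls = arg("min_calls", 5L),
                           min_tiles = arg("min_tiles", 50L),
                           max_mid = arg("max_mid", 0.20),
                           min_tail = arg("min_tail", 0.05))
    }
    retained <- read_pass &&
      identical(x$status, "pass") && identical(ctx$status, "pass") &&
      identical(bim$status, "pass")
    data.frame(cell_id = cell$cell_id, group = cell$group,
               n_cpgs_covered = cell$n_cpgs_covered, read_pass = read_pass,
               x_cgi_pct = x$pct, x_cgi_status = x$status,
               mCpG = ctx$mCpG, mCHG = ctx$mCHG, mCHH = ctx$mCHH,
               context_status = ctx$status,
               tile_low = bim$low, tile_mid = bim$mid, tile_high = bim$high,
               bimodality_status = bim$status,
               retained = retained, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, retained = cells[report$retained])
}
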
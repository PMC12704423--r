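#' Build contiguous 100-CpG tiles from a reference CpG map
#'
#' Each chromosome's sorted CpG positions are grouped into consecutive,
#' non-overlapping windows of exactly `tile_cpgs` sites; a trailing group
#' with fewer sites is dropped. A tile spans its first to last contained CpG
#' (1-based, inclusive).
#'
#' @param cpg_map Named list, one sorted integer vector of CpG positions per
#'   chromosome.
#' @param tile_cpgs CpGs per tile (default 100).
#' @return Object of class `tile_set`: list with `tiles` (data frame
#'   `tile_id`, `chrom`, `start`, `end`, `n_cpgs`) and the `cpg_map`.
#' @export
build_tiles <- function(cpg_map, tile_cpgs = 100L) {
  stopifnot(is.list(cpg_map), !is.null(names(cpg_map)), tile_cpgs >= 1L)
  rows <- lapply(names(cpg_map), function(chrom) {
    pos <- as.integer(cpg_map[[chrom]])
    if (is.unsorted(pos, strictly = TRUE))
      stop("CpG positions on '", chrom, "' are not strictly increasing")
    k <- length(pos) %/% tile_cpgs
    if (k == 0L) return(NULL)
    first <- (seq_len(k) - 1L) * tile_cpgs + 1L
    last <- first + tile_cpgs - 1L
    data.frame(chrom = chrom, start = pos[first], end = pos[last],
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, rows)
  if (is.null(tiles))
    tiles <- data.frame(chrom = character(), start = integer(), end = integer())
  tiles$tile_id <- if (nrow(tiles))
    sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end) else character()
  tiles$n_cpgs <- rep(as.integer(tile_cpgs), nrow(tiles))
  tiles <- tiles[, c("tile_id", "chrom", "start", "end", "n_cpgs")]
  rownames(tiles) <- NULL
  structure(list(tiles = tiles, cpg_map = cpg_map, tile_cpgs = as.integer(tile_cpgs)),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set: %d tiles of %d CpGs over %d chromosome(s)\n",
              nrow(x$tiles), x$tile_cpgs, length(x$cpg_map)))
  invisible(x)
}

# Map site positions to tile row indices (NA when outside any tile).
assign_tiles <- function(tileset, chrom, pos) {
  tiles <- tileset$tiles
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    rows <- which(tiles$chrom == ch)
    if (!length(rows)) next
    sel <- chrom == ch
    i <- findInterval(pos[sel], tiles$start[rows])
    ok <- i >= 1L & pos[sel] <= tiles$end[rows][pmax(i, 1L)]
    idx <- rep(NA_integer_, sum(sel))
    idx[ok] <- rows[i[ok]]
    out[sel] <- idx
  }
  out
}

# Pooled (meth, unmeth) per tile for one methylome.
tile_counts <- function(tileset, cell) {
  s <- cell$sites
  tile <- assign_tiles(tileset, s$chrom, s$pos)
  n <- nrow(tileset$tiles)
  meth <- unmeth <- integer(n)
  keep <- !is.na(tile)
  if (any(keep)) {
    m <- rowsum(s$meth[keep], tile[keep])
    u <- rowsum(s$unmeth[keep], tile[keep])
    idx <- as.integer(rownames(m))
    meth[idx] <- m[, 1L]
    unmeth[idx] <- u[, 1L]
  }
  data.frame(tile_id = tileset$tiles$tile_id, meth = meth, unmeth = unmeth,
             stringsAsFactors = FALSE)
}

#' Quantify percent methylation over 100-CpG tiles
#'
#' Calls are pooled over each tile's CpG sites; tiles with fewer than
#' `min_calls` total calls are reported as missing (`NA`), the
#' informativeness criterion used throughout the pipeline (30 calls for
#' pseudo-bulk analyses, 5 for individual oocytes).
#'
#' @param tileset A [build_tiles()] result.
#' @param cell A [cell_methylome()] (single cell or pseudo-bulk).
#' @param min_calls Minimum total calls per tile (default 30).
#' @return Data frame `tile_id`, `chrom`, `start`, `end`, `meth`, `unmeth`,
#'   `calls`, `pct` (`NA` below `min_calls`).
#' @export
quantify_tiles <- function(tileset, cell, min_calls = 30L) {
  stopifnot(min_calls >= 1L)
  counts <- tile_counts(tileset, cell)
  calls <- counts$meth + counts$unmeth
  pct <- ifelse(calls >= min_calls, 100 * counts$meth / calls, NA_real_)
  cbind(tileset$tiles[, c("tile_id", "chrom", "start", "end")],
        meth = counts$meth, unmeth = counts$unmeth, calls = calls, pct = pct)
}

#' Segment quantified tiles into hypo- and hypermethylated domains
#'
#' Maximal runs of consecutive informative tiles on the same chromosome with
#' percent methylation in \[0, 25\] become hypomethylated domains; runs in
#' \[75, 100\] hypermethylated domains (closed intervals). Runs are broken by
#' missing or mid-range tiles. Domain boundaries span the first to the last
#' tile of the run.
#'
#' @param tile_quant Output of [quantify_tiles()] for a reference entity.
#' @return A [region_set()] with classes `hypo_domain` / `hyper_domain`.
#' @export
segment_domains <- function(tile_quant) {
  band <- rep(NA_character_, nrow(tile_quant))
  band[!is.na(tile_quant$pct) & tile_quant$pct <= 25] <- "hypo_domain"
  band[!is.na(tile_quant$pct) & tile_quant$pct >= 75] <- "hyper_domain"
  key <- paste(tile_quant$chrom, band)
  key[is.na(band)] <- NA
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  if (!any(keep))
    return(region_set(character(), integer(), integer(), character(), character()))
  starts <- starts[keep]; ends <- ends[keep]
  cls <- band[starts]
  region_set(chrom = tile_quant$chrom[starts],
             start = tile_quant$start[starts],
             end = tile_quant$end[ends],
             name = sprintf("%s_%d", cls, seq_along(starts)),
             class = cls)
}
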
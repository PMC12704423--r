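#' Construct a single-cell CpG methylome
#'
#' @param cell_id Cell identifier.
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `meth`,
#'   `unmeth` (non-negative call counts, at least one call per site).
#' @param group Optional group label (e.g. genotype).
#' @param context Optional named numeric vector `c(mCpG=, mCHG=, mCHH=)` of
#'   percentages of methylated cytosines per context, as reported by the
#'   aligner's QC summary.
#' @return Object of class `cell_methylome` with fields `cell_id`, `group`,
#'   `sites`, `context`, `n_cpgs_covered`.
#' @export
cell_methylome <- function(cell_id, sites, group = NA_character_, context = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "meth", "unmeth") %in% names(sites)))
  if (nrow(sites)) {
    if (any(sites$meth < 0 | sites$unmeth < 0))
      stop("negative call counts")
    if (any(sites$meth + sites$unmeth < 1))
      stop("sites must carry at least one call")
  }
  if (!is.null(context)) {
    if (!all(c("mCpG", "mCHG", "mCHH") %in% names(context)))
      stop("context summary needs mCpG, mCHG, mCHH")
    if (any(context < 0 | context > 100)) stop("context percentages must be in [0,100]")
  }
  structure(list(cell_id = as.character(cell_id),
                 group = as.character(group),
                 sites = sites[, c("chrom", "pos", "meth", "unmeth")],
                 context = context,
                 n_cpgs_covered = nrow(sites)),
            class = "cell_methylome")
}

#' @export
print.cell_methylome <- function(x, ...) {
  cat(sprintf("cell_methylome '%s' (group %s): %d CpGs covered, %d calls\n",
              x$cell_id, x$group, x$n_cpgs_covered,
              sum(x$sites$meth) + sum(x$sites$unmeth)))
  if (!is.null(x$context))
    cat(sprintf("context: mCpG %.2f%%, mCHG %.2f%%, mCHH %.2f%%\n",
                x$context[["mCpG"]], x$context[["mCHG"]], x$context[["mCHH"]]))
  invisible(x)
}

#' Read a Bismark-style coverage file into a cell methylome
#'
#' Expects the six-column tab-separated dialect
#' `chrom start end methylation_percentage count_methylated count_unmethylated`
#' with 1-based coordinates. The percentage column is ignored and methylation
#' is recomputed from the counts downstream.
#'
#' @param path Coverage file path.
#' @param cell_id Cell identifier; defaults to the file name without extension.
#' @param group,context Passed to [cell_methylome()].
#' @return A [cell_methylome()].
#' @export
read_coverage <- function(path, cell_id = NULL, group = NA_character_,
                          context = NULL) {
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(cell_methylome(cell_id,
                          data.frame(chrom = character(), pos = integer(),
                                     meth = integer(), unmeth = integer()),
                          group = group, context = context))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop(sprintf("malformed coverage line %d in '%s' (expected 6 fields, got %d)",
                 which(nf != 6L)[1L], path, nf[nf != 6L][1L]))
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 5L]))
  unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop(sprintf("malformed coverage line %d in '%s' (non-numeric field)",
                 bad[1L], path))
  cell_methylome(cell_id,
                 data.frame(chrom = m[, 1L], pos = pos, meth = meth,
                            unmeth = unmeth, stringsAsFactors = FALSE),
                 group = group, context = context)
}

#' Write a cell methylome as a Bismark-style coverage file
#'
#' @param cell A [cell_methylome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cell, path) {
  s <- cell$sites
  pct <- ifelse(s$meth + s$unmeth > 0, 100 * s$meth / (s$meth + s$unmeth), 0)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d", s$chrom, s$pos, s$pos,
                     formatC(pct, format = "f", digits = 6), s$meth, s$unmeth),
             path)
  invisible(path)
}

#' Construct a region set
#'
#' Named annotated intervals (1-based, inclusive) with a feature class.
#'
#' @param chrom,start,end Interval coordinates.
#' @param name Unique region names.
#' @param class One of `"CGI"`, `"gDMR"`, `"hypo_domain"`, `"hyper_domain"`
#'   per region.
#' @param x_chrom Logical flag marking X-chromosome regions; defaults to
#'   `chrom == "chrX"`.
#' @return Data frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, name, class,
                       x_chrom = chrom == "chrX") {
  stopifnot(all(end >= start),
            all(class %in% c("CGI", "gDMR", "hypo_domain", "hyper_domain")))
  if (anyDuplicated(name[class == "gDMR"]))
    stop("gDMR names must be unique")
  structure(data.frame(chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       name = as.character(name), class = as.character(class),
                       x_chrom = as.logical(x_chrom), stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Read regions from a BED-style annotation file
#'
#' BED input is 0-based half-open and is converted to the package's 1-based
#' inclusive coordinates on read. Columns: chrom, start, end, name, class,
#' and optionally an x-chromosome flag (0/1).
#'
#' @param path BED file path.
#' @return A [region_set()].
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 5L) stop("region BED needs chrom, start, end, name, class")
  x <- if (ncol(bed) >= 6L) as.logical(bed[[6L]]) else bed[[1L]] == "chrX"
  region_set(bed[[1L]], bed[[2L]] + 1L, bed[[3L]], bed[[4L]], bed[[5L]], x)
}

#' Write a region set as BED (0-based half-open)
#'
#' @param regions A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%d", regions$chrom,
                     regions$start - 1L, regions$end, regions$name,
                     regions$class, as.integer(regions$x_chrom)),
             path)
  invisible(path)
}

#' Pool site calls of several cells into one pseudo-bulk methylome
#'
#' Per-site methylated and unmethylated counts are summed across cells;
#' sites covered in any cell appear once.
#'
#' @param cells List of [cell_methylome()] objects.
#' @param group Optional group label to select (matched against each cell's
#'   `group`) and to stamp on the result; `NULL` pools all cells.
#' @return A [cell_methylome()] named `pseudobulk:<group>`.
#' @export
pseudobulk <- function(cells, group = NULL) {
  if (!is.null(group))
    cells <- Filter(function(c) identical(c$group, group), cells)
  if (!length(cells)) stop("no cells to pool", if (!is.null(group)) paste0(" in group '", group, "'"))
  sites <- do.call(rbind, lapply(cells, `[[`, "sites"))
  key <- paste(sites$chrom, sites$pos, sep = ":")
  meth <- rowsum(sites$meth, key, reorder = FALSE)
  unmeth <- rowsum(sites$unmeth, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = sites$chrom[first], pos = sites$pos[first],
                    meth = as.integer(meth[, 1L]), unmeth = as.integer(unmeth[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  lab <- if (is.null(group)) "all" else group
  cell_methylome(paste0("pseudobulk:", lab), out, group = lab)
}
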
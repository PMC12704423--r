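# Small deterministic fixtures shared across test files.

# Tile map: one chromosome, `n_tiles` tiles of 100 CpGs spaced 10 bp apart.
toy_tileset <- function(n_tiles = 5L, chrom = "chr1") {
  map <- stats::setNames(list(as.integer(seq_len(n_tiles * 100L) * 10L)), chrom)
  build_tiles(map)
}

# Methylome whose i-th tile carries `meth[i]` methylated and `unmeth[i]`
# unmethylated calls, spread one call per CpG from the tile start.
toy_tile_methylome <- function(tileset, meth, unmeth, cell_id = "cell",
                               group = NA_character_, context = NULL) {
  tiles <- tileset$tiles
  stopifnot(length(meth) == nrow(tiles), length(unmeth) == nrow(tiles))
  rows <- lapply(seq_len(nrow(tiles)), function(i) {
    n <- meth[i] + unmeth[i]
    if (n == 0L) return(NULL)
    # cycle calls over the tile's 100 CpG positions (multi-read sites)
    slot <- ((seq_len(n) - 1L) %% 100L) + 1L
    pos <- as.integer(tiles$start[i] + 10L * (slot - 1L))
    is_meth <- rep(c(1L, 0L), c(meth[i], unmeth[i]))
    m <- rowsum(is_meth, pos)
    u <- rowsum(1L - is_meth, pos)
    data.frame(chrom = tiles$chrom[i], pos = as.integer(rownames(m)),
               meth = as.integer(m[, 1L]), unmeth = as.integer(u[, 1L]),
               stringsAsFactors = FALSE)
  })
  cell_methylome(cell_id, do.call(rbind, rows), group = group, context = context)
}

# Quick small methylome simulation spec for screen/recovery tests.
small_meth_spec <- function(..., seed) {
  args <- utils::modifyList(
    list(n_autosomes = 2L, cpg_per_chromosome = 10000L,
         n_cells_per_group = c(WT = 4L, KO = 4L), coverage_rate = 10000,
         seed = seed),
    list(...))
  do.call(methylome_sim_spec, args)
}
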
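#' Specification for the single-cell methylome simulator
#'
#' Defines a small reference genome (regularly spaced CpGs, 10 per kb), an
#' alternating layout of hyper- and hypomethylated domains, CpG islands
#' (including hypomethylated X-linked ones), germline DMRs with planted
#' knockout effects, per-cell sparse coverage and read-level somatic
#' contamination. All level parameters are fractions in \[0, 1\].
#'
#' @param n_autosomes Number of autosomes (default 5); an X chromosome is
#'   always added.
#' @param cpg_per_chromosome CpGs per chromosome (default 20,000; spacing is
#'   100 bp).
#' @param block_tiles Tiles (100 CpGs each) per domain block; blocks
#'   alternate hyper/hypo starting with hyper (default 5).
#' @param p_hyper,p_hypo True methylation levels of hyper/hypo domains
#'   (defaults 0.90 and 0.05).
#' @param cgis_per_chromosome,cgi_cpgs CpG islands per chromosome and CpGs
#'   per island (defaults 10 and 50); islands alternate between hypo and
#'   hyper blocks, inheriting the domain level, except X-linked islands,
#'   which use `x_cgi_levels`.
#' @param gdmr_list Data frame `name`, `chrom`, `tile` (1-based tile index on
#'   that chromosome), `wt_level`, `ko_delta`; each gDMR spans one 100-CpG
#'   tile. Default: three gDMRs at 0.85 with a planted knockout change of
#'   -0.30.
#' @param global_ko_delta Fraction subtracted from hyper-domain levels in KO
#'   cells (default 0.10; with half the tiles hypermethylated this plants a
#'   5 percentage-point global deficit).
#' @param n_cells_per_group Named integer vector of cells per group (default
#'   `c(WT = 19, KO = 10)`).
#' @param coverage_rate Expected covered CpGs per cell; each CpG is covered
#'   independently with probability `coverage_rate / total CpGs` (default
#'   36,000, i.e. 30% of the default genome).
#' @param read_lambda Read depth per covered site is 1 + a zero-truncation
#'   Poisson: draws from Poisson(`read_lambda`) conditioned on >= 1 (default
#'   1).
#' @param context_params List with `oocyte` and `somatic` named vectors of
#'   expected methylated fractions `c(mCpG=, mCHG=, mCHH=)`.
#' @param n_context_cytosines Cytosines behind each context summary fraction
#'   (default 200,000).
#' @param contamination_fraction Somatic mixing weight per cell in \[0, 1\];
#'   scalar or one value per cell (default 0).
#' @param somatic_cpg_level Global CpG methylation of the somatic profile
#'   (default 0.70, an intermediate unimodal pattern).
#' @param x_cgi_levels Named vector `c(oocyte=, somatic=)` of X-CGI
#'   methylation (defaults 0.02 and 0.40).
#' @param seed Integer seed; identical spec and seed give identical output.
#' @return Validated list of class `methylome_sim_spec`.
#' @export
methylome_sim_spec <- function(n_autosomes = 5L, cpg_per_chromosome = 20000L,
                               block_tiles = 5L, p_hyper = 0.90, p_hypo = 0.05,
                               cgis_per_chromosome = 10L, cgi_cpgs = 50L,
                               gdmr_list = NULL, global_ko_delta = 0.10,
                               n_cells_per_group = c(WT = 19L, KO = 10L),
                               coverage_rate = 36000,
                               read_lambda = 1,
                               context_params = list(
                                 oocyte = c(mCpG = 0.38, mCHG = 0.05, mCHH = 0.06),
                                 somatic = c(mCpG = 0.75, mCHG = 0.01, mCHH = 0.005)),
                               n_context_cytosines = 200000L,
                               contamination_fraction = 0,
                               somatic_cpg_level = 0.70,
                               x_cgi_levels = c(oocyte = 0.02, somatic = 0.40),
                               seed = 1L) {
  chk_frac <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0 | x > 1))
      stop("'", what, "' must be a fraction in [0, 1]")
  }
  if (n_autosomes < 1L) stop("'n_autosomes' must be >= 1")
  if (cpg_per_chromosome < 100L) stop("'cpg_per_chromosome' must be >= 100")
  if (block_tiles < 1L) stop("'block_tiles' must be >= 1")
  chk_frac(p_hyper, "p_hyper"); chk_frac(p_hypo, "p_hypo")
  chk_frac(global_ko_delta, "global_ko_delta")
  chk_frac(contamination_fraction, "contamination_fraction")
  chk_frac(somatic_cpg_level, "somatic_cpg_level")
  chk_frac(x_cgi_levels, "x_cgi_levels")
  chk_frac(unlist(context_params), "context_params")
  if (any(n_cells_per_group < 1L) || is.null(names(n_cells_per_group)))
    stop("'n_cells_per_group' must be a named vector of counts >= 1")
  if (coverage_rate <= 0) stop("'coverage_rate' must be positive")
  if (read_lambda <= 0) stop("'read_lambda' must be positive")
  chroms <- c(paste0("chr", seq_len(n_autosomes)), "chrX")
  tiles_per_chrom <- cpg_per_chromosome %/% 100L
  if (is.null(gdmr_list)) {
    k <- min(3L, n_autosomes)
    gdmr_list <- data.frame(
      name = paste0("gDMR", seq_len(k)),
      chrom = paste0("chr", seq_len(k)),
      tile = rep(3L, k),          # inside the first hyper block
      wt_level = rep(0.85, k),
      ko_delta = rep(-0.30, k), stringsAsFactors = FALSE)
  }
  if (!all(gdmr_list$chrom %in% chroms))
    stop("'gdmr_list' references undeclared chromosomes")
  if (any(gdmr_list$tile < 1L | gdmr_list$tile > tiles_per_chrom))
    stop("'gdmr_list' tile index outside the chromosome")
  chk_frac(gdmr_list$wt_level, "gdmr_list$wt_level")
  if (any(gdmr_list$wt_level + gdmr_list$ko_delta < 0 |
            gdmr_list$wt_level + gdmr_list$ko_delta > 1))
    stop("'gdmr_list' KO level outside [0, 1]")
  structure(list(n_autosomes = as.integer(n_autosomes),
                 cpg_per_chromosome = as.integer(cpg_per_chromosome),
                 block_tiles = as.integer(block_tiles),
                 p_hyper = p_hyper, p_hypo = p_hypo,
                 cgis_per_chromosome = as.integer(cgis_per_chromosome),
                 cgi_cpgs = as.integer(cgi_cpgs),
                 gdmr_list = gdmr_list, global_ko_delta = global_ko_delta,
                 n_cells_per_group = n_cells_per_group,
                 coverage_rate = coverage_rate, read_lambda = read_lambda,
                 context_params = context_params,
                 n_context_cytosines = as.integer(n_context_cytosines),
                 contamination_fraction = contamination_fraction,
                 somatic_cpg_level = somatic_cpg_level,
                 x_cgi_levels = x_cgi_levels,
                 chromosomes = chroms, seed = as.integer(seed)),
            class = "methylome_sim_spec")
}

# Zero-truncated Poisson via inverse CDF.
rtpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
}

# Reference CpG map: regular 100 bp spacing, density 10 CpGs/kb.
sim_cpg_map <- function(spec) {
  pos <- as.integer(100L * seq_len(spec$cpg_per_chromosome) - 50L)
  stats::setNames(rep(list(pos), length(spec$chromosomes)), spec$chromosomes)
}

# Per-site true methylation levels for the oocyte WT/KO and somatic profiles,
# plus the region annotation. Returns list(levels=list(WT,KO,somatic), regions).
sim_site_levels <- function(spec) {
  map <- sim_cpg_map(spec)
  n <- spec$cpg_per_chromosome
  tiles_per_chrom <- n %/% 100L
  block <- spec$block_tiles
  tile_index <- rep(seq_len(tiles_per_chrom), each = 100L)[seq_len(n)]
  tile_index[is.na(tile_index)] <- tiles_per_chrom + 1L  # trailing sites
  hyper_tile <- ((tile_index - 1L) %/% block) %% 2L == 0L
  hyper_tile[tile_index > tiles_per_chrom] <- FALSE
  lv <- list()
  regions <- list()
  for (ch in spec$chromosomes) {
    pos <- map[[ch]]
    wt <- ifelse(hyper_tile, spec$p_hyper, spec$p_hypo)
    ko <- ifelse(hyper_tile, pmax(spec$p_hyper - spec$global_ko_delta, 0),
                 spec$p_hypo)
    som <- rep(spec$somatic_cpg_level, n)
    # CpG islands: alternate between hypo and hyper blocks, centred in a tile
    if (spec$cgis_per_chromosome > 0L) {
      for (i in seq_len(spec$cgis_per_chromosome)) {
        # spread CGIs across the chromosome, alternating target band
        want_hypo <- i %% 2L == 0L
        cand <- which(if (want_hypo) !hyper_tile & tile_index <= tiles_per_chrom
                      else hyper_tile)
        if (!length(cand)) next
        centre <- cand[ceiling(length(cand) * i / (spec$cgis_per_chromosome + 1))]
        first <- max(1L, centre - spec$cgi_cpgs %/% 2L)
        idx <- first:min(n, first + spec$cgi_cpgs - 1L)
        if (ch == "chrX") {
          wt[idx] <- spec$x_cgi_levels[["oocyte"]]
          ko[idx] <- spec$x_cgi_levels[["oocyte"]]
          som[idx] <- spec$x_cgi_levels[["somatic"]]
        }
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = pos[idx[1L]], end = pos[idx[length(idx)]],
          name = sprintf("CGI_%s_%d", ch, i), class = "CGI",
          stringsAsFactors = FALSE)
      }
    }
    # gDMRs override one full tile
    g <- spec$gdmr_list[spec$gdmr_list$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      idx <- which(tile_index == g$tile[j])
      wt[idx] <- g$wt_level[j]
      ko[idx] <- g$wt_level[j] + g$ko_delta[j]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = pos[idx[1L]], end = pos[idx[length(idx)]],
        name = g$name[j], class = "gDMR", stringsAsFactors = FALSE)
    }
    # domain annotation from the layout truth (one flag per tile)
    hyper_by_tile <- hyper_tile[(seq_len(tiles_per_chrom) - 1L) * 100L + 1L]
    r <- rle(hyper_by_tile)
    t_end <- cumsum(r$lengths)
    t_start <- t_end - r$lengths + 1L
    for (j in seq_along(r$values)) {
      cls <- if (r$values[j]) "hyper_domain" else "hypo_domain"
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = pos[(t_start[j] - 1L) * 100L + 1L],
        end = pos[t_end[j] * 100L],
        name = sprintf("%s_%s_%d", cls, ch, j), class = cls,
        stringsAsFactors = FALSE)
    }
    lv[[ch]] <- list(WT = wt, KO = ko, somatic = som)
  }
  reg <- do.call(rbind, regions)
  list(levels = lv,
       regions = region_set(reg$chrom, reg$start, reg$end, reg$name, reg$class),
       hyper_tile_fraction = mean(hyper_tile[tile_index <= tiles_per_chrom]))
}

#' Simulate single-cell oocyte methylomes with planted effects
#'
#' Generates one sparse CpG methylome per cell. Each CpG is covered
#' independently with probability `coverage_rate / total CpGs`; covered sites
#' receive a zero-truncated Poisson read depth; each read is drawn from the
#' somatic profile with probability `contamination_fraction` and from the
#' cell's oocyte profile otherwise, so site-level methylation, context
#' summaries and X-CGI levels shift jointly with contamination. KO cells
#' carry the planted hyper-domain deficit and gDMR changes. Context
#' summaries are binomial draws around the mixed expected fractions.
#'
#' @param spec A [methylome_sim_spec()].
#' @return List with `cells` (list of [cell_methylome()]), `regions` (a
#'   [region_set()] of CGIs, gDMRs and true domains), `tileset` (the
#'   reference [build_tiles()] map) and `truth` (per-cell group and
#'   contamination, planted gDMR deltas, the hyper-tile fraction and the
#'   expected per-group global mean methylation over full tiles).
#' @export
simulate_methylomes <- function(spec) {
  stopifnot(inherits(spec, "methylome_sim_spec"))
  set.seed(spec$seed)
  map <- sim_cpg_map(spec)
  sl <- sim_site_levels(spec)
  n_chrom_sites <- spec$cpg_per_chromosome
  total_sites <- n_chrom_sites * length(spec$chromosomes)
  cov_p <- min(1, spec$coverage_rate / total_sites)
  groups <- rep(names(spec$n_cells_per_group), spec$n_cells_per_group)
  n_cells <- length(groups)
  f_all <- rep(spec$contamination_fraction, length.out = n_cells)
  chrom_vec <- rep(spec$chromosomes, each = n_chrom_sites)
  pos_vec <- rep(map[[1L]], length(spec$chromosomes))
  # first declared group carries the WT profile, any further group the KO profile
  grp_names <- names(spec$n_cells_per_group)
  p_oo <- lapply(stats::setNames(grp_names, grp_names), function(g) {
    which_prof <- if (match(g, grp_names) == 1L) "WT" else "KO"
    unlist(lapply(spec$chromosomes, function(ch) sl$levels[[ch]][[which_prof]]),
           use.names = FALSE)
  })
  p_som <- unlist(lapply(spec$chromosomes, function(ch) sl$levels[[ch]][["somatic"]]),
                  use.names = FALSE)
  ctx_oo <- spec$context_params$oocyte
  ctx_som <- spec$context_params$somatic
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    g <- groups[i]
    f <- f_all[i]
    covered <- which(stats::runif(total_sites) < cov_p)
    reads <- rtpois(length(covered), spec$read_lambda)
    n_som_reads <- stats::rbinom(length(covered), reads, f)
    meth <- stats::rbinom(length(covered), reads - n_som_reads, p_oo[[g]][covered]) +
      stats::rbinom(length(covered), n_som_reads, p_som[covered])
    ctx_mix <- (1 - f) * ctx_oo + f * ctx_som
    ctx_pct <- 100 * stats::rbinom(3L, spec$n_context_cytosines, ctx_mix) /
      spec$n_context_cytosines
    names(ctx_pct) <- names(ctx_oo)
    cells[[i]] <- cell_methylome(
      sprintf("%s_cell%02d", g, sum(groups[seq_len(i)] == g)),
      data.frame(chrom = chrom_vec[covered], pos = pos_vec[covered],
                 meth = meth, unmeth = reads - meth, stringsAsFactors = FALSE),
      group = g, context = ctx_pct)
  }
  tileset <- build_tiles(map)
  # expected per-group global mean % over full tiles (truth for recovery tests)
  full <- seq_len((n_chrom_sites %/% 100L) * 100L)
  expected_global <- vapply(grp_names, function(g) {
    100 * mean(unlist(lapply(spec$chromosomes, function(ch) {
      prof <- if (match(g, grp_names) == 1L) "WT" else "KO"
      sl$levels[[ch]][[prof]][full]
    })))
  }, numeric(1))
  truth <- list(
    cells = data.frame(cell_id = vapply(cells, `[[`, "", "cell_id"),
                       group = groups, contamination_fraction = f_all,
                       stringsAsFactors = FALSE),
    gdmrs = transform(spec$gdmr_list,
                      planted_delta_pct = 100 * ko_delta),
    global_ko_delta = spec$global_ko_delta,
    hyper_tile_fraction = sl$hyper_tile_fraction,
    expected_global_pct = expected_global,
    planted_global_deficit_pct = 100 * spec$global_ko_delta * sl$hyper_tile_fraction)
  list(cells = cells, regions = sl$regions, tileset = tileset, truth = truth)
}
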
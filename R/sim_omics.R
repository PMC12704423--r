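#' Specification for the label-free proteome simulator
#'
#' Raw intensities are `2^x` with `x ~ Normal(baseline + planted shift, sd)`
#' per protein and sample, emulating a log-normal label-free abundance
#' matrix; missing values are injected completely at random.
#'
#' @param n_proteins Number of proteins (default 2,000).
#' @param n_samples_per_group Named integer vector (default
#'   `c(WT = 4L, Hom = 4L)`).
#' @param baseline_log2_mean Per-protein baseline log2 means; scalar is
#'   recycled, `NULL` draws them once from Normal(20, 2) under the seed.
#' @param sd Per-protein log2 standard deviation, scalar recycled
#'   (default 0.3).
#' @param planted_effects Data frame `protein` (index or id), `group`,
#'   `log2_shift`; default none.
#' @param missing_rate Fraction of entries set missing, in \[0, 1)
#'   (default 0).
#' @param seed Integer seed.
#' @return Validated list of class `proteome_sim_spec`.
#' @export
proteome_sim_spec <- function(n_proteins = 2000L,
                              n_samples_per_group = c(WT = 4L, Hom = 4L),
                              baseline_log2_mean = NULL, sd = 0.3,
                              planted_effects = NULL, missing_rate = 0,
                              seed = 1L) {
  if (n_proteins < 1L) stop("'n_proteins' must be >= 1")
  if (is.null(names(n_samples_per_group)) || any(n_samples_per_group < 2L))
    stop("'n_samples_per_group' must be named counts >= 2")
  if (any(sd < 0)) stop("'sd' must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  if (is.null(planted_effects))
    planted_effects <- data.frame(protein = integer(), group = character(),
                                  log2_shift = numeric())
  if (!all(planted_effects$group %in% names(n_samples_per_group)))
    stop("'planted_effects' references unknown groups")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples_per_group = n_samples_per_group,
                 baseline_log2_mean = baseline_log2_mean, sd = sd,
                 planted_effects = planted_effects,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "proteome_sim_spec")
}

#' Simulate a raw label-free proteome abundance matrix
#'
#' @param spec A [proteome_sim_spec()].
#' @return List with `matrix` (a raw-scale [abundance_matrix()]) and `truth`
#'   (data frame of planted per-protein, per-group log2 shifts).
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_sim_spec"))
  set.seed(spec$seed)
  np <- spec$n_proteins
  groups <- rep(names(spec$n_samples_per_group), spec$n_samples_per_group)
  ns <- length(groups)
  baseline <- spec$baseline_log2_mean
  if (is.null(baseline)) baseline <- stats::rnorm(np, 20, 2)
  baseline <- rep_len(baseline, np)
  sds <- rep_len(spec$sd, np)
  proteins <- sprintf("P%04d", seq_len(np))
  shift <- matrix(0, np, ns)
  pe <- spec$planted_effects
  if (nrow(pe)) {
    idx <- if (is.numeric(pe$protein)) as.integer(pe$protein)
           else match(as.character(pe$protein), proteins)
    if (any(is.na(idx) | idx < 1L | idx > np))
      stop("'planted_effects' references unknown proteins")
    for (j in seq_len(nrow(pe)))
      shift[idx[j], groups == pe$group[j]] <- pe$log2_shift[j]
  }
  x <- baseline + shift + matrix(stats::rnorm(np * ns, 0, sds), np, ns)
  raw <- 2^x
  if (spec$missing_rate > 0)
    raw[stats::runif(np * ns) < spec$missing_rate] <- NA_real_
  samples <- paste0(groups, stats::ave(seq_len(ns), groups, FUN = seq_along))
  dimnames(raw) <- list(proteins, samples)
  truth <- if (nrow(pe))
    data.frame(protein = proteins[if (is.numeric(pe$protein)) as.integer(pe$protein)
                                  else match(as.character(pe$protein), proteins)],
               group = pe$group, log2_shift = pe$log2_shift,
               stringsAsFactors = FALSE)
  else data.frame(protein = character(), group = character(),
                  log2_shift = numeric())
  list(matrix = abundance_matrix(raw, stats::setNames(groups, samples)),
       truth = truth)
}

#' Specification for the single-cell transcriptome simulator
#'
#' Gene counts are negative binomial with mean
#' `nb_mean * stage multiplier * 2^planted shift` and gene-wise dispersion;
#' marker modules are elevated in their own stage by `marker_multiplier`.
#'
#' @param n_genes Number of genes (default 2,000).
#' @param nb_mean Per-gene baseline means; scalar recycled, `NULL` draws
#'   log-normal(meanlog log(5), sdlog 1) under the seed.
#' @param nb_dispersion Per-gene NB dispersion (size = 1/dispersion), scalar
#'   recycled (default 0.1).
#' @param n_marker_genes Markers per module (default 20); the first
#'   `n_marker_genes` genes are NSN markers, the next are SN markers
#'   (disjoint by construction).
#' @param marker_multiplier Mean multiplier of a module in its own stage
#'   (default 10).
#' @param n_cells Named integer vector over `stage.genotype` combinations
#'   (default `c(NSN.WT = 4L, SN.WT = 6L, NSN.KO = 4L, SN.KO = 2L)`).
#' @param planted_de Data frame `gene` (index or id), `log2_shift` applied in
#'   KO cells; default none.
#' @param seed Integer seed.
#' @return Validated list of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 2000L, nb_mean = NULL,
                                nb_dispersion = 0.1, n_marker_genes = 20L,
                                marker_multiplier = 10,
                                n_cells = c(NSN.WT = 4L, SN.WT = 6L,
                                            NSN.KO = 4L, SN.KO = 2L),
                                planted_de = NULL, seed = 1L) {
  if (n_genes < 2L * n_marker_genes) stop("'n_genes' too small for the marker modules")
  if (!is.null(nb_mean) && any(nb_mean <= 0)) stop("'nb_mean' must be > 0")
  if (any(nb_dispersion <= 0)) stop("'nb_dispersion' must be > 0")
  if (marker_multiplier <= 0) stop("'marker_multiplier' must be > 0")
  if (is.null(names(n_cells)) || any(n_cells < 0L))
    stop("'n_cells' must be a named vector of non-negative counts")
  if (!all(grepl("^(NSN|SN)\\.", names(n_cells))))
    stop("'n_cells' names must be stage.genotype with stage NSN or SN")
  if (is.null(planted_de))
    planted_de <- data.frame(gene = integer(), log2_shift = numeric())
  structure(list(n_genes = as.integer(n_genes), nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion,
                 n_marker_genes = as.integer(n_marker_genes),
                 marker_multiplier = marker_multiplier, n_cells = n_cells,
                 planted_de = planted_de, seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a single-cell count matrix with stage and genotype structure
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `counts` (genes x cells integer matrix), `cells` (data
#'   frame `cell_id`, `stage`, `genotype`), `nsn_markers`, `sn_markers`
#'   (gene ids) and `truth` (planted KO log2 shifts).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(ng))
  nsn_markers <- genes[seq_len(spec$n_marker_genes)]
  sn_markers <- genes[spec$n_marker_genes + seq_len(spec$n_marker_genes)]
  mu0 <- spec$nb_mean
  if (is.null(mu0)) mu0 <- stats::rlnorm(ng, log(5), 1)
  mu0 <- rep_len(mu0, ng)
  size <- 1 / rep_len(spec$nb_dispersion, ng)
  combos <- names(spec$n_cells)[spec$n_cells > 0L]
  stage <- sub("\\..*$", "", combos)
  genotype <- sub("^[^.]*\\.", "", combos)
  cells <- data.frame(cell_id = character(), stage = character(),
                      genotype = character(), stringsAsFactors = FALSE)
  cols <- list()
  ko_shift <- rep(0, ng)
  pd <- spec$planted_de
  if (nrow(pd)) {
    idx <- if (is.numeric(pd$gene)) as.integer(pd$gene)
           else match(as.character(pd$gene), genes)
    if (any(is.na(idx) | idx < 1L | idx > ng))
      stop("'planted_de' references unknown genes")
    ko_shift[idx] <- pd$log2_shift
  }
  for (k in seq_along(combos)) {
    n <- spec$n_cells[[combos[k]]]
    mu <- mu0
    mu[genes %in% nsn_markers] <- mu[genes %in% nsn_markers] *
      if (stage[k] == "NSN") spec$marker_multiplier else 1
    mu[genes %in% sn_markers] <- mu[genes %in% sn_markers] *
      if (stage[k] == "SN") spec$marker_multiplier else 1
    if (genotype[k] != "WT") mu <- mu * 2^ko_shift
    for (i in seq_len(n)) {
      cols[[length(cols) + 1L]] <- stats::rnbinom(ng, mu = mu, size = size)
      cells <- rbind(cells, data.frame(
        cell_id = sprintf("%s_%s_%02d", stage[k], genotype[k], i),
        stage = stage[k], genotype = genotype[k], stringsAsFactors = FALSE))
    }
  }
  counts <- if (length(cols)) do.call(cbind, cols) else matrix(integer(), ng, 0L)
  dimnames(counts) <- list(genes, cells$cell_id)
  truth <- if (nrow(pd))
    data.frame(gene = genes[if (is.numeric(pd$gene)) as.integer(pd$gene)
                            else match(as.character(pd$gene), genes)],
               log2_shift = pd$log2_shift, stringsAsFactors = FALSE)
  else data.frame(gene = character(), log2_shift = numeric())
  list(counts = counts, cells = cells, nsn_markers = nsn_markers,
       sn_markers = sn_markers, truth = truth)
}
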
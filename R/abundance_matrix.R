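#' Construct an abundance matrix with a group design
#'
#' Container for a label-free proteomics intensity matrix (proteins x samples)
#' together with the sample-to-group assignment. Intensities are raw positive
#' values on input; [log2_transform()] converts in place and records the scale.
#'
#' @param intensities Numeric matrix, proteins in rows, samples in columns,
#'   with row and column names. Missing values allowed (`NA`); present values
#'   must be strictly positive on the raw scale.
#' @param design Named character vector mapping sample id to group label, or a
#'   two-column data frame (sample, group). Every column of `intensities`
#'   must have a group.
#' @param log2 Logical; `TRUE` if `intensities` is already on the log2 scale.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `intensities`, `design` (named character vector) and `log2`.
#' @export
abundance_matrix <- function(intensities, design, log2 = FALSE) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("'intensities' must have protein row names and sample column names")
  if (is.data.frame(design)) {
    if (ncol(design) < 2L) stop("'design' data frame needs sample and group columns")
    design <- stats::setNames(as.character(design[[2L]]), as.character(design[[1L]]))
  }
  missing_design <- setdiff(colnames(intensities), names(design))
  if (length(missing_design))
    stop("samples without a group in the design: ", paste(missing_design, collapse = ", "))
  design <- design[colnames(intensities)]
  if (!log2) {
    bad <- which(!is.na(intensities) & intensities <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-positive intensity for protein '%s', sample '%s'",
                   rownames(intensities)[bad[1L, 1L]], colnames(intensities)[bad[1L, 2L]]))
  }
  structure(list(intensities = intensities, design = design, log2 = log2),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$log2) "log2" else "raw"))
  tab <- table(x$design)
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an abundance matrix and design from TSV files
#'
#' The matrix file has a protein-id first column and one column of raw
#' intensities per sample; the design file has two columns, sample and group.
#'
#' @param matrix_path Path to the intensity TSV.
#' @param design Path to the design TSV, a data frame, or a named character
#'   vector sample -> group.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(matrix_path, design) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- as.character(raw[[1L]])
  if (is.character(design) && length(design) == 1L && file.exists(design))
    design <- utils::read.delim(design, stringsAsFactors = FALSE)
  abundance_matrix(m, design)
}

#' Bundled GV-oocyte proteome example data
#'
#' Raw DIA-NN protein abundances for subcortical maternal complex (SCMC)
#' proteins (`"scmc"`) or selected epigenetic modifier proteins (`"epimod"`)
#' measured in bulk germinal-vesicle oocyte samples from wild-type (WT, 4
#' samples), Nlrp5 heterozygous (Het, 3) and Nlrp5-null (Hom, 4) mice.
#'
#' @param which `"scmc"` or `"epimod"`.
#' @return An [abundance_matrix()] with groups WT, Het, Hom.
#' @export
oocyte_proteome_example <- function(which = c("scmc", "epimod")) {
  which <- match.arg(which)
  file <- switch(which,
                 scmc = "scmc_protein_abundance.tsv",
                 epimod = "epigenetic_modifier_abundance.tsv")
  read_abundance_matrix(
    system.file("extdata", file, package = "oomics", mustWork = TRUE),
    system.file("extdata", "oocyte_proteome_design.tsv", package = "oomics",
                mustWork = TRUE))
}
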
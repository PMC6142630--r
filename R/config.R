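#' Pipeline configuration with published defaults
#'
#' All thresholds and seeds the pipeline uses, in one structured list.
#' Defaults are the published values of the limb single-cell study design this
#' package implements: cells are kept when total mapped reads exceed 250,
#' more than 2000 genes are detected (count > 0) and under 25% of reads map
#' to spike-ins; genes are kept when present in at least 10% of either
#' tissue's cells; a panel gene is "on" in a cell at normalized expression
#' >= 5 that is also >= 5% of the cell's most expressed panel gene;
#' differential expression requires |log2 fold change| >= 2 at BH FDR < 0.01;
#' tSNE runs 2 dimensions, perplexity 30, 3000 iterations, seed 42.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(min_genes_expressed = 100)
#' cfg$combo_min_expr
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # cell QC (strict inequalities, as published)
    min_mapped_reads    = 250,
    min_genes_expressed = 2000,
    max_spike_fraction  = 0.25,
    # gene filter (inclusive fraction, either tissue)
    gene_presence_fraction = 0.10,
    # combination calling (both criteria inclusive >=)
    combo_min_expr     = 5,
    combo_max_fraction = 0.05,
    main_group_min_cells = 5,      # main group iff count > 5, strict
    # differential expression
    de_min_abs_lfc = 2,
    de_max_fdr     = 0.01,
    # covariance selection
    covary_min_rho = 0.3,
    covary_max_fdr = 0.05,
    # HVG + embedding
    n_hvg = 500,
    hvg_trend_span = 0.3,
    tsne = list(dims = 2, perplexity = 30, max_iter = 3000, seed = 42,
                pca = FALSE, theta = 0.5),
    # pseudotime
    pseudotime = list(k_eigs = 10, knn = 10, sigma = "local",
                      n_permutations = 10000),
    # flow gating
    flow_control_quantile = 0.99,
    seed = 42
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  fracs <- c("max_spike_fraction", "gene_presence_fraction",
             "combo_max_fraction", "de_max_fdr", "covary_max_fdr",
             "flow_control_quantile")
  for (f in fracs) {
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) {
      stop(f, " must lie in (0, 1)", call. = FALSE)
    }
  }
  pos <- c("min_mapped_reads", "min_genes_expressed", "combo_min_expr",
           "de_min_abs_lfc", "main_group_min_cells", "n_hvg")
  for (f in pos) {
    if (!(cfg[[f]] > 0)) stop(f, " must be strictly positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param cfg A [pipeline_config()] object.
#' @return `read_config()` returns a `pipeline_config`; `write_config()` its
#'   path, invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
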
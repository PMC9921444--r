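#' Pipeline configuration
#'
#' Assembles the pipeline configuration list with the package defaults.
#' Defaults mirror the reference analysis: tissue k-means with 4 classes,
#' 4096 px tiles at full resolution, a (100, 100, 50) MLP trained 500 epochs
#' per outer iteration for 50 iterations, and dual FDR gates at 0.01 / 0.1.
#'
#' @param tissue_k number of tissue classes for low-resolution segmentation.
#' @param cluster_k number of sample clusters for deep clustering.
#' @param tile_size tile side in pixels at full resolution.
#' @param mlp_hidden integer vector of the three hidden-layer widths.
#' @param epochs MLP training epochs per outer iteration.
#' @param outer_iters outer deep-clustering iterations.
#' @param t1_fdr selection gate: BH-adjusted over-expression q-value must be
#'   below this.
#' @param t2_fdr selection gate: BH-adjusted homogeneity q-value must be
#'   above this.
#' @param min_expr_prop a gene is kept when the proportion of samples with
#'   value > 0 strictly exceeds this.
#' @param neighbor_radius radius (pixels, full resolution) for the
#'   neighboring-nuclei count feature.
#' @param window_radius window radius (low-res pixels) for the per-pixel
#'   robust statistics.
#' @param seed integer seed driving every stochastic stage.
#' @param ... further named entries stored verbatim.
#' @return named list of class `histomorph_config`.
#' @export
pipelineConfig <- function(tissue_k = 4L, cluster_k = 4L, tile_size = 4096L,
                           mlp_hidden = c(100L, 100L, 50L), epochs = 500L,
                           outer_iters = 50L, t1_fdr = 0.01, t2_fdr = 0.1,
                           min_expr_prop = 0.10, neighbor_radius = 50,
                           window_radius = 2L, seed = 1L, ...) {
  stopIfNot(length(mlp_hidden) == 3L, "mlp_hidden must have length 3")
  cfg <- list(tissue_k = as.integer(tissue_k),
              cluster_k = as.integer(cluster_k),
              tile_size = as.integer(tile_size),
              mlp_hidden = as.integer(mlp_hidden),
              epochs = as.integer(epochs),
              outer_iters = as.integer(outer_iters),
              t1_fdr = t1_fdr, t2_fdr = t2_fdr,
              min_expr_prop = min_expr_prop,
              neighbor_radius = neighbor_radius,
              window_radius = as.integer(window_radius),
              seed = as.integer(seed), ...)
  class(cfg) <- "histomorph_config"
  cfg
}

#' Read a YAML or JSON configuration file
#'
#' Entries found in the file override the defaults of [pipelineConfig()];
#' unknown entries are kept verbatim so CLI stages can pass them through.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `histomorph_config` list.
#' @export
readPipelineConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  stopIfNot(is.list(raw), "config must parse to a mapping")
  do.call(pipelineConfig, raw)
}
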
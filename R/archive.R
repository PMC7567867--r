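#' Save a dataset or fitted model archive
#'
#' Serializes datasets, maps and models (with their full hyperparameter
#' provenance: kernel spec, training descriptors, dual coefficients,
#' regularization, prior) to a single-file binary archive via R's
#' native serialization.
#'
#' @param object a \code{density_dataset}, \code{hk_map},
#'   \code{energy_map} or \code{krr_model}
#' @param path output path (conventionally \code{.rds})
#' @return invisibly, \code{path}
#' @export
save_archive <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' Load a dataset or model archive
#'
#' @param path archive path written by \code{\link{save_archive}}
#' @return the stored object
#' @export
load_archive <- function(path) {
  readRDS(path)
}
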
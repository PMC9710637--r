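#' Save a model checkpoint
#'
#' Writes the weight blob (RDS) plus a JSON sidecar (`<path>.json`) carrying
#' the architecture configuration, the ordered class vocabulary and the
#' package version, so a checkpoint is self-describing.
#'
#' @param model an [la_model()].
#' @param path checkpoint file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "la_model"))
  saveRDS(model, path)
  sidecar <- list(
    config = unclass(model$config),
    class_vocabulary = model$vocab,
    classifier_input_width = classifier_input_width(model$config),
    n_parameters = count_parameters(model),
    package_version = as.character(utils::packageVersion("lightattn"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#' @param path path given to [save_checkpoint()].
#' @return the `la_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "la_model")) stop("not a model checkpoint: ", path,
                                         call. = FALSE)
  model
}

#' Write predictions as TSV
#'
#' One row per protein: `id`, `predicted_class`, then one probability column
#' per class in vocabulary order.
#'
#' @param predictions data.frame from [predict.la_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#' @param path TSV path.
#' @return data.frame with `id`, `predicted_class` and probability columns.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
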
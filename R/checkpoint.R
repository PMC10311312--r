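CHECKPOINT_VERSION <- 1L

#' Save a trained model checkpoint
#'
#' Serialises the parameter container together with its configuration echo
#' and a format version, so checkpoints can be validated when reloaded.
#'
#' @param model A `conversion_model`.
#' @param path Output file path (RDS).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "conversion_model"))
  saveRDS(list(version = CHECKPOINT_VERSION, model = model), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint file path.
#' @return The `conversion_model`.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$version) || ck$version > CHECKPOINT_VERSION) {
    stop("unrecognised checkpoint format", call. = FALSE)
  }
  ck$model
}
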
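# Model persistence.
#
# Trained engines are stored as single-file named-array containers holding
# the weight arrays plus the configuration and seed that produced them, so
# any saved model can be audited and re-applied bit-identically.

#' Save a trained super-resolution model
#'
#' @param model an `elm_model` or `cnn_model`.
#' @param path output file (conventionally `.rds`).
#' @export
save_sr_model <- function(model, path) {
  stopifnot(inherits(model, c("elm_model", "cnn_model")))
  obj <- list(engine = if (inherits(model, "elm_model")) "elm" else "cnn",
              version = as.character(utils::packageVersion("lenslessSR")),
              model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trained super-resolution model
#'
#' @param path file written by [save_sr_model()].
#' @return the stored `elm_model` or `cnn_model`.
#' @export
load_sr_model <- function(path) {
  if (!file.exists(path)) stop_io("no such model file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop_io("failed to read model ", path,
                                              ": ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$model) ||
      !inherits(obj$model, c("elm_model", "cnn_model")))
    stop_validation("not a lenslessSR model container: ", path)
  obj$model
}

#' Super-resolve with either engine
#'
#' Convenience dispatcher used by the command-line interface.
#'
#' @param lr low-resolution grayscale matrix.
#' @param model an `elm_model` or `cnn_model` (ignored for
#'   `engine = "none"`).
#' @param engine `"elm"`, `"cnn"`, or `"none"` (plain bicubic
#'   interpolation by `t`).
#' @param t magnification used when `engine = "none"`.
#' @return grayscale matrix of size `dim(lr) * t`.
#' @export
super_resolve <- function(lr, model = NULL, engine = c("elm", "cnn", "none"),
                          t = 4L) {
  engine <- match.arg(engine)
  switch(engine,
         elm = apply_elmsr(lr, model),
         cnn = apply_cnnsr(lr, model),
         none = clamp01(upsample_bicubic(lr, resample_config(t))))
}
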
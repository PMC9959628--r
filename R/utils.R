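`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_file <- function(...) {
  system.file(..., package = "piradscde", mustWork = TRUE)
}

#' Sentinel value marking a CDE as not applicable
#'
#' Distinct from a missing (omitted) value: a rater explicitly records that a
#' variable does not apply (e.g. DCE descriptors when the DCE sequence is
#' absent or inadequate). Missing values are simply absent from storage.
#' @export
NOT_APPLICABLE <- "NOT_APPLICABLE"

stop_piradscde <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "piradscde_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
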
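#' Language-model backends
#'
#' All stages that need a language model talk to a *backend* object: a handler
#' function plus a model identifier and a sampling temperature (0 by default,
#' for deterministic outputs). The handler receives a request list — always
#' containing `type` (`"keywords"`, `"matching"` or `"aggregation"`) and the
#' rendered `prompt`, plus structured context fields — and must return the raw
#' response text. Parsing and validation of that text happen in the pipeline,
#' never in the backend, so deterministic mocks (see [mock_backend()]) exercise
#' the same code paths as a live API adapter would.
#'
#' @param handler `function(request) -> character(1)` returning raw response
#'   text.
#' @param model_id Identifier string recorded with cached calls.
#' @param temperature Sampling temperature; kept at 0 for determinism.
#' @return An object of class `llm_backend`.
#' @export
llm_backend <- function(handler, model_id = "custom", temperature = 0) {
  stopifnot(is.function(handler))
  assert_scalar_number(temperature, "temperature", min = 0)
  structure(list(handler = handler, model_id = model_id,
                 temperature = temperature),
            class = "llm_backend")
}

#' @export
print.llm_backend <- function(x, ...) {
  cat(sprintf("<llm_backend: %s, temperature=%g%s>\n", x$model_id,
              x$temperature,
              if (!is.null(x$cache_dir)) paste0(", cached at ", x$cache_dir) else ""))
  invisible(x)
}

#' Invoke a backend
#'
#' @param backend An [llm_backend()].
#' @param request Request list with at least `type` and `prompt`.
#' @return Raw response text (single string).
#' @export
backend_call <- function(backend, request) {
  if (!inherits(backend, "llm_backend")) {
    abort("`backend` must be an `llm_backend` object.",
          class = "trialmatchr_config_error")
  }
  if (is.null(request$type) || is.null(request$prompt)) {
    abort("Backend requests must carry `type` and `prompt` fields.",
          class = "trialmatchr_config_error")
  }
  if (!is.null(backend$cache_dir)) {
    key <- poly_hash(paste(backend$model_id, backend$temperature,
                           request$type, request$prompt, sep = "\x1f"))
    cache_file <- file.path(backend$cache_dir, paste0(key, ".txt"))
    if (file.exists(cache_file)) {
      return(readChar(cache_file, file.size(cache_file), useBytes = TRUE))
    }
    out <- backend$handler(request)
    writeChar(out, cache_file, eos = NULL, useBytes = TRUE)
    return(out)
  }
  out <- backend$handler(request)
  if (!is.character(out) || length(out) != 1L) {
    abort("Backend handler must return a single string.",
          class = "trialmatchr_backend_error")
  }
  out
}

#' Wrap a backend with an on-disk response cache
#'
#' Responses are cached by a content hash of (model id, temperature, request
#' type, prompt). Re-running a pipeline over completed pairs then makes zero
#' duplicate backend calls, which gives cost control with live APIs and
#' byte-identical reruns with mocks.
#'
#' @param backend An [llm_backend()].
#' @param cache_dir Directory for cached responses (created if needed).
#' @return The backend with caching enabled.
#' @export
cached_backend <- function(backend, cache_dir) {
  if (!inherits(backend, "llm_backend")) {
    abort("`backend` must be an `llm_backend` object.",
          class = "trialmatchr_config_error")
  }
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  backend$cache_dir <- cache_dir
  backend
}
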
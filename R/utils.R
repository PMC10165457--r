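# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a per-stage random seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seeds from one master
#' seed so that inserting a new stage does not scramble the streams of
#' unrelated stages. The substream is a deterministic 31-bit hash of the
#' master seed and the stage name.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h) %% 2147483647)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop2(sprintf("'%s' must be a single non-missing number", name))
  if (x < lower || x > upper)
    stop2(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper))
  invisible(as.numeric(x))
}
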
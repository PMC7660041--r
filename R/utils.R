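#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor fft lm lm.fit mvfft nextn p.adjust pf
#'   predict pt qt rbinom rnorm runif sd setNames spline t.test var
#' @importFrom utils head tail
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a base seed and a string key.
# Keeps results independent of the order in which subjects are processed.
child_seed <- function(seed, key) {
  bytes <- utf8ToInt(paste0(key, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147480009
  as.integer(h)
}

stop_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_param("`", name, "` must be a numeric value of length ", len)
  }
  if (any(x < lower) || any(x > upper)) {
    stop_param("`", name, "` must lie in [", lower, ", ", upper, "], got ",
               paste(signif(x, 4), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < lower) {
    stop_param("`", name, "` must be an integer >= ", lower)
  }
  invisible(as.integer(x))
}

#' Hash of a configuration object
#'
#' Stable content hash used to tag every table a pipeline run writes, so that
#' tables from different configurations are never joined silently.
#'
#' @param x Any R object.
#' @return A character scalar.
#' @export
config_hash <- function(x) {
  rlang::hash(x)
}
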
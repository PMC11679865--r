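#' Numerically stable softmax
#'
#' @param x numeric vector of scores, or a matrix whose rows are scored
#'   independently.
#' @return vector (or matrix) of positive weights; each vector / row sums to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    z <- exp(x - apply(x, 1L, max))
    return(z / rowSums(z))
  }
  z <- exp(x - max(x))
  z / sum(z)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
stop_shape <- function(what, expected, found) {
  stop(sprintf("%s: expected shape %s, found %s", what,
               paste(expected, collapse = " x "),
               paste(found, collapse = " x ")), call. = FALSE)
}

# single integer seed check (R integers are 32-bit)
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
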
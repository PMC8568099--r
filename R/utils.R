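`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sample from a vector without the scalar surprise
#'
#' `sample(x, k)` treats a length-one numeric `x` as `1:x`; simulation code
#' must never do that when `x` is a vector of ids. `resample(x, k)` always
#' samples elements of `x`.
#' @param x vector to sample from
#' @param k number of elements to draw (without replacement)
#' @return `k` elements of `x`
#' @keywords internal
resample <- function(x, k) x[sample.int(length(x), k)]

abort_config <- function(...) stop(sprintf(...), call. = FALSE)

check_proportions <- function(p, what) {
  if (any(p < 0)) abort_config("%s: negative proportion", what)
  if (abs(sum(p) - 1) > 1e-9)
    abort_config("%s: proportions must sum to 1 (got %.12f)", what, sum(p))
  invisible(p)
}

#' Integer seed derived from a base seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @param seed base integer seed
#' @param i stream index (>= 0)
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9176) %% 2147483647L)
}

age_band_labels <- c("16-30", "31-45", "46-65", "66-94")

#' Age band used for schedule matching and demographic keying
#' @param age integer vector of ages (years)
#' @return factor with levels `16-30`, `31-45`, `46-65`, `66-94`
#' @export
age_band <- function(age) {
  cut(age, breaks = c(15, 30, 45, 65, 94), labels = age_band_labels)
}

#' Age group used for reporting exposure-minute summaries
#' @param age integer vector of ages (years)
#' @return factor with levels `<31`, `31-45`, `46-65`, `65+`
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 30, 45, 65, Inf),
      labels = c("<31", "31-45", "46-65", "65+"))
}
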
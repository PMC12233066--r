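#' @useDynLib morphocell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree dist hclust prcomp rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom grDevices contourLines chull
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a global seed
#'
#' One global seed deterministically fans out to stage seeds, so changing
#' only the global seed changes every stochastic stage while two runs with
#' the same global seed are bit-identical. Kept below 2^31 - 1.
#'
#' @param global_seed integer global seed.
#' @param ... one or more integer or character stage keys.
#' @return a single integer seed.
#' @export
derive_seed <- function(global_seed, ...) {
  keys <- list(...)
  h <- as.double(global_seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# column order of the 12 profile features; fixed across the whole package
DESCRIPTORS <- c("area_um2", "perimeter_um", "length_um", "width_um",
                 "lw_ratio", "compactness")

#' Names of the 12 morphological profile features
#'
#' Means first, then standard deviations, each in the descriptor order
#' area, perimeter, length, width, length-to-width ratio, compactness.
#'
#' @return character vector of length 12.
#' @export
profile_feature_names <- function() {
  short <- c("area", "perimeter", "length", "width", "lw_ratio", "compactness")
  c(paste0("mean_", short), paste0("sd_", short))
}
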
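#' @keywords internal
#' @importFrom e1071 svm
"_PACKAGE"

# Deterministic sub-seed derivation: every source of randomness in the package
# flows from one user seed through named substreams, so independent stages
# (subjects, accessories, splits, CV folds) stay reproducible and uncoupled.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, name).
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_raster <- function(x) is.matrix(x) && is.numeric(x) && all(dim(x) >= 2L)

check_raster8 <- function(x, what = "raster") {
  if (length(x) == 0) stop_invalid(what, " is empty")
  if (!is.numeric(x)) stop_invalid(what, " must be numeric")
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 255)
    stop_invalid(what, " has values outside [0, 255]")
  invisible(TRUE)
}
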
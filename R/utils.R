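# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fold angles into [0, 360)
#' @noRd
fold_angle <- function(deg) {
  a <- deg %% 360
  a[a == 360] <- 0
  a
}

vec_norm <- function(v) sqrt(sum(v^2))

# Arc length of an n x 2 polyline matrix.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# Cumulative arc positions (length n) along an n x 2 polyline.
polyline_arcpos <- function(p) {
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

# Straight polyline from a to b with vertex spacing <= step (endpoints kept).
make_polyline <- function(a, b, step = 2) {
  len <- vec_norm(b - a)
  n <- max(2L, as.integer(ceiling(len / step)) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
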
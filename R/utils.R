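.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats plogis qlogis rnorm runif rbinom pnorm qnorm pbinom
#'   binomial glm coef predict integrate uniroot quantile sd var
#' @importFrom utils read.csv write.csv
NULL

# Round to the printed precision of a scoresheet row and return an integer on
# the scaled grid (value * 10^digits), so bin lookups are exact integer
# comparisons rather than floating-point ones.
scale_to_grid <- function(x, digits) {
  as.integer(round(round(x, digits) * 10^digits))
}

# Bin lookup for a numeric scoresheet row. `lower` holds the lower bound of
# every bin except the first (ascending); `points` has one entry per bin.
bin_points <- function(x, lower, points, digits) {
  xi <- scale_to_grid(x, digits)
  li <- as.integer(round(lower * 10^digits))
  idx <- findInterval(xi, li) + 1L
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(xi)
  out[ok] <- points[idx[ok]]
  out
}

enum_points <- function(x, levels) {
  out <- unname(levels[match(x, names(levels))])
  as.integer(out)
}

stop_missing <- function(fields, context) {
  stop(sprintf("missing required field(s) for %s: %s", context,
               paste(fields, collapse = ", ")), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_enum <- function(value, allowed, field) {
  if (is.null(value) || length(value) != 1L || is.na(value) || !value %in% allowed) {
    stop(sprintf("field '%s' must be one of: %s (got %s)", field,
                 paste(allowed, collapse = ", "),
                 if (is.null(value)) "NULL" else deparse(value)), call. = FALSE)
  }
  value
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All stochastic code in the package funnels through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
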
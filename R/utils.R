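# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that library functions with
#' their own `seed` argument never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit signed-integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483587) + 1L
}

## Truncated normal machinery ------------------------------------------------

# Mean of Normal(mean, sd) truncated to [lower, upper] (closed form).
tnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  # Degenerate mass: fall back to the nearest bound.
  out <- mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  bad <- !is.finite(out) | z < 1e-12
  if (any(bad)) {
    mid <- ifelse(mean < lower, lower, ifelse(mean > upper, upper, mean))
    out[bad] <- mid[bad]
  }
  out
}

# Inverse-CDF sampler for the truncated normal; vectorised over all args.
rtnorm <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(pa + u * pmax(pb - pa, 1e-300), mean, sd)
  pmin(pmax(q, lower), upper)
}

# Solve for the location parameter mu such that the average truncated-normal
# mean over per-subject bounds equals `target`. Used so that a configured
# stratum mean is realised exactly in expectation despite the physiological
# bounds on the brain-age gap.
solve_tnorm_location <- function(target, sd, lower, upper) {
  f <- function(mu) mean(tnorm_mean(mu, sd, lower, upper)) - target
  lo <- min(lower) - 10 * sd
  hi <- max(upper) + 10 * sd
  if (f(lo) > 0 || f(hi) < 0) {
    stop("stratum mean ", target, " is unattainable under the bounds [",
         round(min(lower), 2), ", ", round(max(upper), 2), "]")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

## Misc ----------------------------------------------------------------------

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stop_cfg <- function(field, ...) {
  stop("configuration error in `", field, "`: ", ..., call. = FALSE)
}
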
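#' Round half away from zero
#'
#' Percentage rounding used in all printed summaries: round to `digits`
#' decimals with ties going away from zero (unlike [base::round()]'s
#' round-half-even), matching the convention of published assignment-rate
#' tables.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @noRd
pct1 <- function(count, total) round_half_up(100 * count / total, 1)

# Derive a reproducible child seed from a base seed and a label.
# Keeps results below 2^31 - 1 so they are valid R integers.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("deconvbench_config_error", "error")))
}

# Validate a composition vector: non-negative, sums to 1.
check_composition <- function(p, tol = 1e-9, what = "composition") {
  if (any(p < 0)) {
    stop_config(what, " has negative entries")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_config(what, " does not sum to 1 (sum = ", format(sum(p)), ")")
  }
  invisible(p)
}

#' Largest-remainder apportionment of an integer total
#'
#' Distributes `n` items over categories proportionally to `props`, so the
#' result is a vector of non-negative integers summing exactly to `n`.
#' Each category first receives the floor of its exact share; the remaining
#' items go to the categories with the largest fractional remainders
#' (ties broken by category order).
#'
#' @param props non-negative weights (normalized internally)
#' @param n positive integer total
#' @return integer vector, same length and names as `props`, summing to `n`
#' @export
apportion_largest_remainder <- function(props, n) {
  if (n < 0) stop_config("n must be non-negative")
  p <- props / sum(props)
  exact <- p * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  out <- as.integer(base)
  names(out) <- names(props)
  out
}
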
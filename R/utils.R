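#' @keywords internal
#' @noRd
.assert <- function(cond, msg, class = "pni_invalid_argument") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

.assert_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x), sprintf("`%s` must be a single finite number", name))
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  .assert(lo && hi, sprintf("`%s` must lie in %s0, 1%s (got %g)", name,
                            if (open_left) "(" else "[", if (open_right) ")" else "]", x))
}

.assert_count <- function(x, name, min = 1L) {
  .assert(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x),
          sprintf("`%s` must be an integer >= %d (got %s)", name, min, format(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so that seeded operations do not perturb the global random stream.
.with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed), "`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.stop_unattainable <- function(msg) {
  stop(structure(class = c("pni_unattainable_design", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Format a probability as a whole percent for display
#' @noRd
.pct <- function(x) sprintf("%d%%", as.integer(round(100 * x)))
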
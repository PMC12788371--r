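#' @keywords internal
#' @useDynLib copmat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_invalid <- function(msg, class = "copmat_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort_invalid(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package funnel
# through this so that a master seed propagates deterministically.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# derive a child seed from a master seed and a stream label, kept < 2^31
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483587
  as.integer(h + 1)
}
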
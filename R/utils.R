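#' Run code under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so that library calls do not perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage seed from a global seed
#'
#' Fans a single global seed out to per-stage seeds by fixed offsets so that
#' pipeline stages can be re-run independently yet reproducibly. The result
#' always fits in a 32-bit signed integer.
#'
#' @param seed Integer global seed.
#' @param offset Integer stage offset.
#' @return Integer seed.
#' @export
#' @examples
#' derive_seed(1, 2)
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  m <- 2147483629 # large prime below 2^31
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 16807) %% m)
}

assert_matrix2d <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (2D image grid).", name))
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must have identical shape (got %s vs %s).",
                  what, paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

# round-half-away-from-zero to nearest pixel; coordinates here are always
# positive so this is round-half-up, independent of R's banker's rounding
round_px <- function(x) floor(x + 0.5)
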
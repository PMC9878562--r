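# Internal helpers shared across modules.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# Mersenne-Twister + Rejection sampling are pinned so that seeded samples
# are reproducible across platforms and R versions >= 3.6.
with_preserved_seed <- function(seed, code) {
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
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

# Euclidean distances between rows of a (n x d) and rows of b (m x d),
# returned as an n x m matrix. Vectorized; no spatial index -- at the
# population sizes of a chemotaxis chamber (hundreds of cells per frame)
# a dense scan is faster than building a tree each frame.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Row-wise euclidean norm of a matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Normalize rows to unit length; zero rows are left at zero.
normalize_rows <- function(m) {
  nr <- row_norms(m)
  ok <- nr > 0
  m[ok, ] <- m[ok, , drop = FALSE] / nr[ok]
  m
}

stop_format <- function(msg) abort(msg, class = "migratrack_format_error")
stop_validation <- function(msg) abort(msg, class = "migratrack_validation_error")
stop_config <- function(msg) abort(msg, class = "migratrack_config_error")

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
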
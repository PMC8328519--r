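# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a point (length-2 numeric) or an n x 2 matrix to an n x 2 double matrix.
as_point_matrix <- function(p, what = "point") {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("`", what, "` must have two columns (x, y)", call. = FALSE)
    storage.mode(p) <- "double"
    return(p)
  }
  if (!is.numeric(p) || length(p) != 2L) {
    stop("`", what, "` must be a length-2 numeric (x, y) or an n x 2 matrix", call. = FALSE)
  }
  matrix(as.numeric(p), ncol = 2L)
}

check_finite <- function(m, what = "point") {
  if (!all(is.finite(m))) stop("`", what, "` contains non-finite coordinates", call. = FALSE)
  invisible(m)
}

# Deterministic 32-bit substream seed from arbitrary key parts.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; all intermediate
# values stay below 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
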
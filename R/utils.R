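#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats rnorm rlnorm runif qnorm pnorm setNames
NULL

# Internal validation helper: stop with a classed condition so callers/tests
# can distinguish configuration errors from numerical failures.
stop_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scarconcord_config_error")
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_config(msg, ...)
  invisible(TRUE)
}

# Derive a deterministic per-operation sub-stream seed from a single root
# seed, so each generator op draws from its own reproducible stream.
# Offsets are fixed small integers; result kept inside 32-bit integer range.
sub_seed <- function(seed, op) {
  offsets <- c(
    phantom = 101L, intensity = 211L, egm = 307L,
    pace = 401L, landmarks = 503L, lat = 601L
  )
  off <- offsets[[op]]
  if (is.null(off)) stop_config("unknown RNG sub-stream '%s'", op)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

with_sub_seed <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, op))
  force(code)
}

# Blockwise exhaustive nearest-neighbour: for each row of `query` (n x 3),
# the index of the nearest row of `ref` (m x 3), ties broken by lowest index.
# Uses |q - r|^2 = |q|^2 + |r|^2 - 2 q.r computed by matrix product, in
# blocks so memory stays bounded for large n.
nearest_index <- function(query, ref, block = 2048L) {
  query <- as_point_matrix(query)
  ref <- as_point_matrix(ref)
  n <- nrow(query)
  if (n == 0L) return(integer(0))
  r2 <- rowSums(ref^2)
  idx <- integer(n)
  dist <- numeric(n)
  starts <- seq.int(1L, n, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), r2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
  }
  structure(idx, distance = dist)
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_mm", "y_mm", "z_mm"), names(x))
    if (length(cols) == 3L) x <- x[cols] else x <- x[, 1:3]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop_config("points must be n x 3 (got %d columns)", ncol(x))
  dimnames(x) <- NULL
  x
}
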
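#' @keywords internal
"_PACKAGE"

## NULL-default helper used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Derive a per-image RNG seed from a master seed and an image identifier
#'
#' Uses a 32-bit FNV-1a hash of the identifier's UTF-8 bytes folded with the
#' master seed, so that per-image random streams are reproducible and
#' independent of iteration order (parallel-safe).
#'
#' @param master_seed single integer master seed.
#' @param image_id character scalar identifying the image.
#' @return A single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_stream_seed <- function(master_seed, image_id) {
  stop_if_not_scalar_number(master_seed, "master_seed")
  stopifnot(is.character(image_id), length(image_id) == 1L)
  bytes <- utf8ToInt(image_id)
  # FNV-1a in double arithmetic, kept below 2^32 (exact in doubles);
  # the xor only ever touches the low byte because inputs are UTF-8 bytes
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    h_lo <- h %% 2^16
    h_hi <- h %/% 2^16
    h <- (h_lo * 16777619 + ((h_hi * 16777619) %% 2^16) * 2^16) %% 2^32
  }
  as.integer((h + abs(master_seed)) %% (2^31 - 1))
}

## Euclidean nearest-neighbour distances from each row of `from` (n x 2) to
## the closest row of `to` (m x 2), without forming the full n x m matrix.
nearest_dist <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  if (nrow(to) == 0L) return(rep(NA_real_, nrow(from)))
  d2 <- rep(Inf, nrow(from))
  for (k in seq_len(nrow(to))) {
    d2 <- pmin(d2, (from[, 1] - to[k, 1])^2 + (from[, 2] - to[k, 2])^2)
  }
  sqrt(d2)
}
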
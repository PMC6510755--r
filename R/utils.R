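# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals do not
#' perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed; kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Bilinear sampling of a matrix at fractional coordinates
#'
#' Coordinates are 1-based (row, col) in pixel units; samples falling outside
#' the matrix return `fill`.
#' @noRd
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  out <- rep(fill, length(rows))
  if (!any(ok)) return(out)
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(r))
  if (nc == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  dr <- if (nr == 1L) 0L else 1L
  dc <- if (nc == 1L) 0L else 1L
  i00 <- r0 + (c0 - 1L) * nr
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + dr] +
    (1 - fr) * fc * img[i00 + dc * nr] +
    fr * fc * img[i00 + dr + dc * nr]
  out[ok] <- v
  out
}
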
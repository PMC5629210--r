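`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Finite-difference Jacobian of f at x (central differences).
fd_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Bilinear interpolation of image `img` (matrix, row = y, col = x) at
# sub-pixel coordinates. Pixel centers sit at integer coordinates (1-based).
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1L); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x1)] * fx * (1 - fy) +
    img[cbind(y1, x0)] * (1 - fx) * fy +
    img[cbind(y1, x1)] * fx * fy
}
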
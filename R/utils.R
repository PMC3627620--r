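# Internal helpers shared across modules.

# Run expr with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so simulations never perturb the
# session RNG. seed = NULL uses (and advances) the session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Bilinear sampling of a matrix at continuous 1-based (row, col) positions.
# Positions outside the grid return `fill`.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get_px <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- rep(fill, length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v00 <- get_px(r0, c0); v01 <- get_px(r0, c0 + 1)
  v10 <- get_px(r0 + 1, c0); v11 <- get_px(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Shift an image by (dr, dc) pixels (content moves by +dr rows, +dc cols),
# bilinear interpolation, out-of-grid filled with `fill`.
shift_image <- function(img, dr, dc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  vals <- bilinear_sample(img, grid$row - dr, grid$col - dc, fill = fill)
  matrix(vals, nr, nc)
}

# Average a (R*f) x (C*f) matrix into R x C blocks of f x f.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  R <- nrow(m) / f; C <- ncol(m) / f
  stopifnot(R == round(R), C == round(C))
  # aggregate rows then columns with averaging matrices
  Ar <- matrix(0, R, nrow(m))
  Ar[cbind(rep(seq_len(R), each = f), seq_len(nrow(m)))] <- 1 / f
  Ac <- matrix(0, ncol(m), C)
  Ac[cbind(seq_len(ncol(m)), rep(seq_len(C), each = f))] <- 1 / f
  Ar %*% m %*% Ac
}

# Gaussian smoothing of a vector, sigma in samples; reflective edges.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
  stats::filter(xp, k, sides = 2)[half + seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
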
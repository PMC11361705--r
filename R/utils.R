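# internal helpers shared across modules

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Small deterministic string hash (sum of codepoints with prime mixing),
# kept below 2^31 so it can seed R's RNG. Used to give each LFQ sample
# column its own reproducible imputation stream regardless of column order.
string_seed <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647L
  as.integer(h)
}

# 1D Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array along one margin, by shift-and-add
# (zero flux outside the volume is assumed; emitters are validated to lie
# inside, so truncation loss is negligible for interior sources).
blur_along <- function(a, sigma, margin) {
  k <- gauss_kernel(sigma)
  if (length(k) == 1L) return(a)
  r <- (length(k) - 1L) %/% 2L
  d <- dim(a)
  n <- d[margin]
  out <- array(0, d)
  idx_full <- lapply(d, seq_len)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    ia <- idx_full; ia[[margin]] <- src[keep]
    io <- idx_full; io[[margin]] <- which(keep)
    out <- out + {
      tmp <- array(0, d)
      tmp[io[[1]], io[[2]], io[[3]]] <- a[ia[[1]], ia[[2]], ia[[3]]]
      tmp * k[j]
    }
  }
  out
}

blur_3d <- function(a, sigma_z_vox, sigma_xy_vox) {
  a <- blur_along(a, sigma_z_vox, 1L)
  a <- blur_along(a, sigma_xy_vox, 2L)
  blur_along(a, sigma_xy_vox, 3L)
}

# 2D separable Gaussian blur (matrix), same shift-and-add scheme.
blur_2d <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  if (length(k) == 1L) return(m)
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(mm) {  # along rows (first margin)
    n <- nrow(mm)
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      out[which(keep), ] <- out[which(keep), ] + mm[src[keep], ] * k[j]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0
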
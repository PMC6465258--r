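# internal helpers: seeded streams, 3D array shifts, separable smoothing,
# binary erosion

# derive a reproducible child seed (< 2^31) from a master seed and counter
deriveSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

# evaluate f under a local RNG state seeded with `seed`, restoring the caller's
withSeed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

# shift a 3D array by offset d = c(dz, dy, dx); vacated cells get `fill`
shiftArray <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    if (d[k] >= 0) {
      if (d[k] >= dm[k]) return(out)
      dst[[k]] <- (1 + d[k]):dm[k]
      src[[k]] <- 1:(dm[k] - d[k])
    } else {
      if (-d[k] >= dm[k]) return(out)
      dst[[k]] <- 1:(dm[k] + d[k])
      src[[k]] <- (1 - d[k]):dm[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# neighborhood offsets for a given connectivity (26 in 3D, 6 face-only);
# fixed lexicographic (dz, dy, dx) order so conquest tie-breaks are stable
neighborOffsets <- function(connectivity = 26L) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[, c("dz", "dy", "dx")]
  off <- off[order(off$dz, off$dy, off$dx), ]
  keep <- !(off$dz == 0 & off$dy == 0 & off$dx == 0)
  off <- off[keep, ]
  if (connectivity == 6L)
    off <- off[abs(off$dz) + abs(off$dy) + abs(off$dx) == 1L, ]
  as.matrix(off)
}

# separable Gaussian smoothing of a 3D array (reflect-free truncation kernel,
# renormalized at edges via smoothing of a ones-array)
gaussianSmooth3D <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x, axis) {
    out <- array(0, dim(x))
    for (i in seq_along(k)) {
      d <- c(0L, 0L, 0L)
      d[axis] <- i - r - 1L
      out <- out + k[i] * shiftArray(x, d, fill = 0)
    }
    out
  }
  num <- a
  den <- array(1, dim(a))
  for (ax in 1:3) {
    num <- smooth1(num, ax)
    den <- smooth1(den, ax)
  }
  num / den
}

# binary erosion with a Chebyshev ball of radius r (26-neighborhood, applied
# r times); out-of-volume neighbors count as inside the mask
erodeMask <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- neighborOffsets(26L)
  out <- mask
  for (it in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(off)))
      acc <- acc & shiftArray(out, off[i, ], fill = TRUE)
    out <- acc
  }
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical arrays of identical shape.
#' @return `2|a & b| / (|a| + |b|)`.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
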
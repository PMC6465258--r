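# Independent brute-force reference implementations used as oracles.

# Reference GrowCut: literal per-voxel triple loop over the synchronous
# update rule, independent of the vectorised production code. Offsets are
# visited in the same lexicographic (dz, dy, dx) order; an attack must
# strictly exceed the current best to win.
bruteGrowCut <- function(volume, seeds, maxIters, connectivity = 26L) {
  dm <- dim(volume)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[, c("dz", "dy", "dx")]
  off <- off[order(off$dz, off$dy, off$dx), ]
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  if (connectivity == 6L)
    off <- off[abs(off$dz) + abs(off$dy) + abs(off$dx) == 1L, ]
  off <- as.matrix(off)
  maxdiff <- diff(range(volume))
  eps <- 1e-6
  lab <- seeds
  theta <- array(0, dm)
  theta[seeds > 0L] <- 1
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(maxIters)) {
    newLab <- lab; newTheta <- theta
    changed <- FALSE
    for (z in seq_len(dm[1])) for (r in seq_len(dm[2]))
      for (cc in seq_len(dm[3])) {
        best <- theta[z, r, cc]
        for (i in seq_len(nrow(off))) {
          q <- c(z, r, cc) + off[i, ]
          if (any(q < 1L) || any(q > dm)) next
          if (lab[q[1], q[2], q[3]] == 0L) next
          g <- 1 - abs(volume[z, r, cc] - volume[q[1], q[2], q[3]]) / maxdiff
          g <- min(1 - eps, max(eps, g))
          attack <- g * theta[q[1], q[2], q[3]]
          if (attack > best) {
            best <- attack
            newLab[z, r, cc] <- lab[q[1], q[2], q[3]]
            newTheta[z, r, cc] <- attack
          }
        }
      }
    iters <- it
    changed <- any(newLab != lab)
    lab <- newLab; theta <- newTheta
    if (!changed) { converged <- TRUE; break }
  }
  list(lab = lab, theta = theta, iterations = iters, converged = converged)
}

# small, fast phantom configuration used across tests
testPhantomConfig <- function(...) {
  phantomConfig(imageShape = c(3L, 60L, 48L), ...)
}

# exhaustive pairwise AUC (ties one half) — oracle for rocAuc
pairwiseAuc <- function(scores, truth) {
  x <- scores[truth == 1]; y <- scores[truth == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}
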
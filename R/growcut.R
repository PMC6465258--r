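#' 3D GrowCut cellular-automaton segmentation
#'
#' Seeded cellular automaton: every voxel `p` carries a label `l_p` and a
#' strength `theta_p` in `[0, 1]`. Seeds start at strength 1, all other
#' voxels unlabeled at strength 0. On each synchronous sweep a neighbor `q`
#' conquers `p` when `g(|I_p - I_q|) * theta_q > theta_p`, where the attack
#' attenuation is `g(x) = 1 - x / maxdiff` clamped to `[eps, 1 - eps]`
#' (`maxdiff` = observed intensity range of the volume, `eps = 1e-6`); then
#' `l_p <- l_q` and `theta_p <- g * theta_q`. Updates are Jacobi-style
#' (computed from the previous sweep's state), so results do not depend on
#' voxel visit order; among several successful attackers the strongest wins,
#' ties going to the first offset in fixed lexicographic (dz, dy, dx) order.
#' Iteration stops when no label changes or `maxIters` is reached. Seeded
#' voxels can never be conquered because `g < 1` strictly.
#'
#' @param volume 3D numeric array of intensities.
#' @param seeds a `SeedSet` from [autoSeeds], or an integer array of the same
#'   shape (0 none, 1 foreground, 2 background).
#' @param maxIters sweep cap, >= 1.
#' @param connectivity 26 (full 3D neighborhood) or 6 (faces only).
#' @return a [MarrowMask-class]: foreground mask, sweep count, convergence
#'   flag. A warning is emitted if `maxIters` is hit before fixpoint.
#' @export
growCutSegment <- function(volume, seeds, maxIters = 200L,
                           connectivity = 26L) {
  if (inherits(seeds, "SeedSet")) seeds <- seeds$label
  stopifnot(identical(dim(volume), dim(seeds)), maxIters >= 1L,
            connectivity %in% c(6L, 26L))
  if (!any(seeds == 1L))
    stop("need at least one foreground seed")
  if (!any(seeds == 2L) && any(seeds == 0L))
    stop("need at least one background seed")
  maxdiff <- diff(range(volume))
  if (maxdiff == 0) stop("zero intensity range")
  eps <- 1e-6
  off <- neighborOffsets(as.integer(connectivity))
  lab <- seeds
  theta <- array(0, dim(volume))
  theta[seeds > 0L] <- 1
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(maxIters)) {
    best <- theta          # an attack must strictly exceed this to win
    newLab <- lab
    newTheta <- theta
    for (i in seq_len(nrow(off))) {
      d <- off[i, ]
      labQ <- shiftArray(lab, d, fill = 0L)
      thetaQ <- shiftArray(theta, d, fill = 0)
      iQ <- shiftArray(volume, d, fill = Inf)
      g <- 1 - abs(volume - iQ) / maxdiff
      g[!is.finite(g)] <- eps
      g <- pmin(1 - eps, pmax(eps, g))
      attack <- g * thetaQ
      win <- labQ > 0L & attack > best
      if (any(win)) {
        newLab[win] <- labQ[win]
        newTheta[win] <- attack[win]
        best[win] <- attack[win]
      }
    }
    iters <- it
    changed <- any(newLab != lab)
    lab <- newLab
    theta <- newTheta
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GrowCut did not reach a fixpoint within ", maxIters, " sweeps")
  new("MarrowMask", mask = lab == 1L, iterations = iters,
      converged = converged)
}

#' Full preprocessing of one subject
#'
#' Disk normalization (annulus of the most cranial non-degenerated disk)
#' followed by GrowCut segmentation from automatically eroded seeds.
#'
#' @param subject a [SpineSubject-class].
#' @param erosionRadius seed erosion radius (voxels).
#' @param maxIters,connectivity passed to [growCutSegment].
#' @return list with `subject` (disk-normalized) and `mask`
#'   ([MarrowMask-class]).
#' @export
preprocessSubject <- function(subject, erosionRadius = 2L, maxIters = 200L,
                              connectivity = 26L) {
  norm <- normalizeSubject(subject)
  seeds <- autoSeeds(norm, erosionRadius)
  mask <- growCutSegment(voxels(norm), seeds, maxIters = maxIters,
                         connectivity = connectivity)
  list(subject = norm, mask = mask)
}
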
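#' Rigid registration by iterative closest point
#'
#' Point-to-surface ICP: every source vertex is matched to its nearest point
#' on the target surface, a least-squares rigid fit (Kabsch) updates the
#' transform, and the loop stops when the RMS improvement drops below `tol`
#' or after `maxIter` iterations. All source vertices are used, with no
#' trimming or sampling, so the result is deterministic. The caller is
#' responsible for a starting position in which nearest-neighbour
#' correspondences are meaningful; grossly non-overlapping inputs end with a
#' convergence warning carrying the residual, never silently.
#'
#' @param source,target `triMesh` objects; the transform maps source onto target.
#' @param init optional initial `rigidTransform`.
#' @param maxIter iteration cap.
#' @param tol stop when the RMS improves by less than this (mm).
#' @param warnRms warn if the final RMS residual exceeds this (mm).
#' @return a [rigidTransform()] with the final RMS residual.
#' @export
icpRegister <- function(source, target, init = NULL, maxIter = 100L,
                        tol = 1e-6, warnRms = 1) {
  stopifnot(inherits(source, "triMesh"), inherits(target, "triMesh"))
  idx <- buildBVH(target)
  V <- source$vertices
  R <- diag(3); tr <- c(0, 0, 0)
  if (!is.null(init)) { R <- init$rotation; tr <- init$translation }
  prev <- Inf; rms <- Inf
  for (k in seq_len(maxIter)) {
    P <- V %*% t(R) + matrix(tr, nrow(V), 3, byrow = TRUE)
    hit <- closestPoint(idx, P)
    rms <- sqrt(mean(hit$distance^2))
    if (prev - rms < tol) break
    prev <- rms
    ft <- kabsch(V, hit$point)
    R <- ft$R; tr <- ft$t
  }
  if (rms > warnRms)
    warning(sprintf("ICP did not converge to overlap: RMS residual %.4f mm", rms))
  rigidTransform(R, tr, rms = rms)
}

# least-squares rigid fit mapping X onto Y (paired rows)
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}
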
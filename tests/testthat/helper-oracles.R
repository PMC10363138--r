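# Independent oracles: brute-force implementations kept deliberately separate
# from the package code paths they check.

# point-to-mesh distance by scanning every triangle (vectorized region
# classification, Ericson's closest-point-on-triangle)
bruteClosest <- function(mesh, q) {
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]; B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  P <- matrix(as.numeric(q), nrow(F), 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B; d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C; d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  out <- matrix(NA_real_, nrow(F), 3)
  done <- rep(FALSE, nrow(F))
  take <- function(mask, pts) {
    m <- mask & !done
    out[m, ] <<- pts[m, , drop = FALSE]
    done <<- done | m
  }
  take(d1 <= 0 & d2 <= 0, A)
  take(d3 >= 0 & d4 <= d3, B)
  v1 <- d1 / (d1 - d3)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, A + v1 * ab)
  take(d6 >= 0 & d5 <= d6, C)
  w1 <- d2 / (d2 - d6)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, A + w1 * ac)
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + w2 * (C - B))
  den <- va + vb + vc
  take(!done, A + (vb / den) * ab + (vc / den) * ac)
  d <- sqrt(rowSums((out - P)^2))
  list(distance = min(d), face = which.min(d))
}

# Cronbach's alpha through the covariance matrix (a different route than the
# column-variance formula in the package)
bruteAlpha <- function(x) {
  S <- cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# weighted kappa by explicit double loops over the contingency table
bruteKappa <- function(r1, r2, categories, quadratic = FALSE) {
  cN <- length(categories)
  n <- length(r1)
  O <- matrix(0, cN, cN)
  for (i in seq_len(n)) {
    a <- match(r1[i], categories); b <- match(r2[i], categories)
    O[a, b] <- O[a, b] + 1 / n
  }
  num <- 0; den <- 0
  for (a in seq_len(cN)) for (b in seq_len(cN)) {
    w <- abs(a - b) / (cN - 1)
    if (quadratic) w <- w^2
    e <- sum(O[a, ]) * sum(O[, b])
    num <- num + w * O[a, b]
    den <- den + w * e
  }
  1 - num / den
}
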
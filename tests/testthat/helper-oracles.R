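# Independent reference implementations used to cross-check the package's
# algorithms on tiny instances. They restate each definition literally and
# inefficiently, sharing no code with the implementation under test.

# Kennard-Stone by exhaustive recomputation: at every step scan all
# unselected points and recompute every distance from scratch.
oracle_kennard_stone <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  best <- c(NA, NA)
  best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d2(i, j) > best_d) {
        best_d <- d2(i, j)
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand_best <- NA
    cand_d <- -Inf
    for (i in setdiff(seq_len(n), sel)) {
      mind <- min(vapply(sel, function(j) d2(i, j), numeric(1)))
      if (mind > cand_d) {
        cand_d <- mind
        cand_best <- i
      }
    }
    sel <- c(sel, cand_best)
  }
  as.integer(sel)
}

# SPA chain via explicit Gram-Schmidt: at every step orthogonalise every
# remaining column against ALL selected columns from scratch and take the
# largest residual norm.
oracle_spa_chain <- function(X, start, len) {
  X <- as.matrix(X)
  p <- ncol(X)
  chain <- start
  while (length(chain) < len) {
    Q <- qr.Q(qr(X[, chain, drop = FALSE]))
    resid_norm <- rep(-Inf, p)
    for (j in setdiff(seq_len(p), chain)) {
      v <- X[, j]
      r <- v - Q %*% crossprod(Q, v)
      resid_norm[j] <- sum(r^2)
    }
    chain <- c(chain, which.max(resid_norm))
  }
  as.integer(chain)
}

# PCA explained percentages via eigendecomposition of the sample covariance.
oracle_explained_pct <- function(X) {
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  100 * ev / sum(ev)
}

# Exhaustive discrete extremum scan over a curve restricted to a window.
oracle_local_min <- function(wl, v, lo, hi) {
  idx <- which(wl >= lo & wl <= hi)
  best <- NA
  for (i in idx) {
    if (i > 1 && i < length(v) && v[i] < v[i - 1] && v[i] < v[i + 1]) {
      if (is.na(best) || v[i] < v[best]) best <- i
    }
  }
  wl[best]
}
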
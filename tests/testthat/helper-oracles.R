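# Independent brute-force oracles used to validate the package's estimators.

# direct R-loop Gaussian kernel summation (no truncation, no grid tricks)
brute_bias <- function(ledger, pts) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = ledger$d)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    v <- 0
    for (k in seq_along(ledger$time)) {
      q <- (pts[i, ] - ledger$center[k, ]) / ledger$sigma[k, ]
      v <- v + ledger$height[k] * exp(-sum(q^2) / 2)
    }
    out[i] <- v
  }
  out
}

# minimax ("lowest highest point") path value between two nodes of a grid,
# by a Dijkstra-style sweep with 8-connectivity
minimax_saddle <- function(F, from, to) {
  n1 <- nrow(F); n2 <- ncol(F)
  best <- matrix(Inf, n1, n2)
  best[from[1], from[2]] <- F[from[1], from[2]]
  active <- matrix(from, 1, 2)
  while (nrow(active)) {
    nxt <- NULL
    for (r in seq_len(nrow(active))) {
      i <- active[r, 1]; j <- active[r, 2]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
        cand <- max(best[i, j], F[ii, jj])
        if (cand < best[ii, jj]) {
          best[ii, jj] <- cand
          nxt <- rbind(nxt, c(ii, jj))
        }
      }
    }
    active <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else unique(nxt)
  }
  best[to[1], to[2]]
}
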
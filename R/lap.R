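# Linear assignment problem, Jonker-Volgenant style shortest augmenting
# paths with dual potentials, O(n^3). Used by the frame-to-frame linker;
# forbidden assignments are encoded by the caller as a large finite cost.
# Returns match[i] = column assigned to row i.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  J0 <- n + 1L # virtual root column
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j]: row assigned to column j (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(n)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  match <- integer(n)
  match[p[seq_len(n)]] <- seq_len(n)
  match
}
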
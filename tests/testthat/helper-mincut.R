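# Exact discrete min-cut oracles for the anisotropic-TV binary labeling
# energy E(u) = sum (1-u)Cs + u Ct + sum_edges w |u_i - u_j|.
#
# gridMincut: Dinic max-flow on the 6-connected grid graph (exact for this
# submodular energy). enumMincut: full 2^N enumeration, used to validate
# the Dinic oracle on tiny grids.

dinicMaxflow <- function(nnode, edges) {
  m <- nrow(edges)
  from <- integer(2L * m); to <- integer(2L * m); cap <- numeric(2L * m)
  odd <- seq_len(m) * 2L - 1L
  from[odd] <- edges[, 1L]; to[odd] <- edges[, 2L]; cap[odd] <- edges[, 3L]
  from[odd + 1L] <- edges[, 2L]; to[odd + 1L] <- edges[, 1L]
  rev <- integer(2L * m); rev[odd] <- odd + 1L; rev[odd + 1L] <- odd
  adj <- vector("list", nnode)
  sp <- split(seq_len(2L * m), from)
  adj[as.integer(names(sp))] <- sp
  s <- nnode - 1L; t <- nnode
  flow <- 0
  repeat {
    level <- rep(-1L, nnode); level[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ei in adj[[v]])
        if (cap[ei] > 1e-12 && level[to[ei]] < 0L) {
          level[to[ei]] <- level[v] + 1L
          queue <- c(queue, to[ei])
        }
    }
    if (level[t] < 0L) break
    iter <- rep(1L, nnode)
    dfs <- function(v, f) {
      if (v == t) return(f)
      av <- adj[[v]]
      while (iter[v] <= length(av)) {
        ei <- av[iter[v]]
        if (cap[ei] > 1e-12 && level[to[ei]] == level[v] + 1L) {
          d <- dfs(to[ei], min(f, cap[ei]))
          if (d > 1e-12) {
            cap[ei] <<- cap[ei] - d
            cap[rev[ei]] <<- cap[rev[ei]] + d
            return(d)
          }
        }
        iter[v] <<- iter[v] + 1L
      }
      0
    }
    repeat {
      f <- dfs(s, Inf)
      if (f <= 1e-12) break
      flow <- flow + f
    }
  }
  reach <- rep(FALSE, nnode); reach[s] <- TRUE; queue <- s
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (ei in adj[[v]])
      if (cap[ei] > 1e-12 && !reach[to[ei]]) {
        reach[to[ei]] <- TRUE
        queue <- c(queue, to[ei])
      }
  }
  list(value = flow, sourceSide = reach)
}

gridMincut <- function(cs, ct, w) {
  d <- dim(cs); n <- prod(d)
  s <- n + 1L; t <- n + 2L
  edges <- rbind(cbind(rep(s, n), 1:n, as.numeric(cs)),
                 cbind(1:n, rep(t, n), as.numeric(ct)))
  idx <- array(1:n, d)
  for (axis in 1:3) {
    if (d[axis] < 2L) next
    a <- switch(axis, idx[-d[1L], , , drop = FALSE],
                idx[, -d[2L], , drop = FALSE], idx[, , -d[3L], drop = FALSE])
    b <- switch(axis, idx[-1L, , , drop = FALSE],
                idx[, -1L, , drop = FALSE], idx[, , -1L, drop = FALSE])
    # forward-difference weight lives at the head voxel (matches cmfEnergy)
    wv <- switch(axis, w[-d[1L], , , drop = FALSE],
                 w[, -d[2L], , drop = FALSE], w[, , -d[3L], drop = FALSE])
    edges <- rbind(edges,
                   cbind(as.numeric(a), as.numeric(b), as.numeric(wv)),
                   cbind(as.numeric(b), as.numeric(a), as.numeric(wv)))
  }
  res <- dinicMaxflow(t, edges)
  list(energy = res$value,
       u = array(as.numeric(res$sourceSide[1:n]), d))
}

enumMincut <- function(energyFn, d) {
  n <- prod(d)
  best <- Inf; bu <- NULL
  for (k in 0:(2^n - 1)) {
    u <- array(as.integer(intToBits(k))[1:n], d)
    e <- energyFn(u)
    if (e < best) { best <- e; bu <- u }
  }
  list(energy = best, u = bu)
}
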
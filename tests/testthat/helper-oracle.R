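# Brute-force Dijkstra on the 8-connected pixel graph with chamfer weights:
# the independent oracle for the geodesic distance transform. O(V^2) on
# purpose -- no shared code with the package implementation.
dijkstra_oracle <- function(domain, seed, spacing = c(1, 1)) {
  nr <- nrow(domain); nc <- ncol(domain)
  dist <- matrix(Inf, nr, nc)
  dist[seed] <- 0
  done <- !domain
  moves <- expand.grid(di = -1:1, dj = -1:1)
  moves <- moves[!(moves$di == 0 & moves$dj == 0), ]
  w <- sqrt((moves$di * spacing[1])^2 + (moves$dj * spacing[2])^2)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    ui <- (u - 1) %% nr + 1
    uj <- (u - 1) %/% nr + 1
    for (m in seq_len(nrow(moves))) {
      vi <- ui + moves$di[m]; vj <- uj + moves$dj[m]
      if (vi < 1 || vi > nr || vj < 1 || vj > nc) next
      if (!domain[vi, vj]) next
      nd <- dist[ui, uj] + w[m]
      if (nd < dist[vi, vj]) dist[vi, vj] <- nd
    }
  }
  dist
}

# random blob mask with a random seed subset, for oracle-equivalence sweeps
random_domain_seed <- function(nr, nc) {
  dom <- matrix(FALSE, nr, nc)
  for (b in seq_len(sample(2:5, 1))) {
    ci <- sample(nr, 1); cj <- sample(nc, 1); r <- sample(3:8, 1)
    dom <- dom | outer(seq_len(nr), seq_len(nc),
                       function(i, j) (i - ci)^2 + (j - cj)^2 <= r^2)
  }
  px <- which(dom)
  sd_px <- sample(px, max(1, round(0.05 * length(px))))
  seed <- matrix(FALSE, nr, nc)
  seed[sd_px] <- TRUE
  list(domain = dom, seed = seed)
}
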
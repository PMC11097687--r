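# Independent oracles used across tests: pure-R set morphology, brute-force
# nearest-neighbor network construction, and simple deterministic fixtures.

# offsets of a Euclidean disk structuring element with the given radius
disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, ]
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rd <- rs + dr; cd <- cs + dc
  ok_r <- rd >= 1 & rd <= nrow(m); ok_c <- cd >= 1 & cd <= ncol(m)
  out[rd[ok_r], cd[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}

# set dilation: union of the mask shifted by every structuring-element offset
dilate_oracle <- function(m, offsets) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets)))
    out <- out | shift_mask(m, offsets$dr[k], offsets$dc[k])
  out
}

# set erosion: intersection over offsets (zero-padded boundary)
erode_oracle <- function(m, offsets) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets)))
    out <- out & shift_mask(m, -offsets$dr[k], -offsets$dc[k])
  out
}

closing_oracle <- function(m, radius, iterations) {
  off <- disk_offsets(radius)
  for (i in seq_len(iterations)) m <- dilate_oracle(m, off)
  for (i in seq_len(iterations)) m <- erode_oracle(m, off)
  m
}

# brute-force scalar-loop construction of the time-free network
bf_edges <- function(nodes, alpha, df, C = 1, dm = 1) {
  n <- nrow(nodes)
  out <- data.frame(child = integer(0), parent = integer(0), weight = numeric(0))
  for (j in seq_len(n)) {
    w <- rep(Inf, n); cand <- seq_len(n)[-j]
    for (i in cand) {
      l <- sqrt((nodes$row[i] - nodes$row[j])^2 + (nodes$col[i] - nodes$col[j])^2)
      w[i] <- C * l^df * dm * nodes$area[i]^(-alpha)
    }
    best <- order(w, -nodes$area, nodes$id)[1]
    out <- rbind(out, data.frame(child = nodes$id[j], parent = nodes$id[best],
                                 weight = w[best]))
  }
  out
}

# brute-force timed network: candidates strictly earlier in time
bf_time_edges <- function(nodes, times, alpha, df, C = 1, dm = 1) {
  n <- nrow(nodes)
  out <- NULL
  for (j in seq_len(n)) {
    w <- rep(Inf, n)
    for (i in seq_len(n)) {
      if (i == j || times[i] >= times[j]) next
      l <- sqrt((nodes$row[i] - nodes$row[j])^2 + (nodes$col[i] - nodes$col[j])^2)
      w[i] <- C * l^df * (times[j] - times[i]) * dm * nodes$area[i]^(-alpha)
    }
    if (all(is.infinite(w))) next
    best <- order(w, -nodes$area, nodes$id)[1]
    out <- rbind(out, data.frame(child = nodes$id[j], parent = nodes$id[best],
                                 weight = w[best]))
  }
  out
}

# depth-d Sierpinski carpet as a logical matrix (3^d x 3^d)
sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# random node table with distinct positions
random_nodes <- function(n, seed, extent = 1000, alpha = 2.5, xmin = 100) {
  set.seed(seed)
  injury_nodes(data.frame(
    id = seq_len(n),
    row = runif(n, 0, extent), col = runif(n, 0, extent),
    area = xmin * (1 - runif(n))^(-1 / (alpha - 1))))
}
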
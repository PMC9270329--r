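# Geometry fixtures and naive pixel-loop oracles. The oracles are written as
# plain double loops / direct definitions, independent of the package's
# vectorized implementations.

disk_matrix <- function(r, pad = 2L) {
  n <- 2L * r + 2L * pad + 1L
  m <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1L
    }
  }
  m
}

ellipse_matrix <- function(a, b, pad = 2L) {
  n <- 2L * max(a, b) + 2L * pad + 1L
  m <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (((i - ctr) / b)^2 + ((j - ctr) / a)^2 <= 1) m[i, j] <- 1L
    }
  }
  m
}

# connected random blob grown by a pixel random walk
random_blob <- function(n_pixels, dims = c(64L, 64L)) {
  m <- matrix(0L, dims[1], dims[2])
  r <- sample.int(dims[1] - 20L, 1L) + 10L
  c <- sample.int(dims[2] - 20L, 1L) + 10L
  m[r, c] <- 1L
  placed <- 1L
  while (placed < n_pixels) {
    dr <- sample(c(-1L, 0L, 1L), 1L)
    dc <- sample(c(-1L, 0L, 1L), 1L)
    r <- min(max(r + dr, 2L), dims[1] - 1L)
    c <- min(max(c + dc, 2L), dims[2] - 1L)
    if (!m[r, c]) {
      m[r, c] <- 1L
      placed <- placed + 1L
    }
  }
  m
}

oracle_area <- function(labels, values) {
  n <- 0L
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      if (labels[i, j] %in% values) n <- n + 1L
    }
  }
  n
}

oracle_eccentricity <- function(labels, values) {
  rs <- c(); cs <- c()
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      if (labels[i, j] %in% values) {
        rs <- c(rs, i); cs <- c(cs, j)
      }
    }
  }
  mr <- mean(rs); mc <- mean(cs)
  mu20 <- mean((rs - mr)^2); mu02 <- mean((cs - mc)^2)
  mu11 <- mean((rs - mr) * (cs - mc))
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
}

oracle_entropy <- function(pixels, labels, values) {
  counts <- rep(0L, 256L)
  n <- 0L
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      if (labels[i, j] %in% values) {
        counts[pixels[i, j] + 1L] <- counts[pixels[i, j] + 1L] + 1L
        n <- n + 1L
      }
    }
  }
  h <- 0
  for (k in seq_len(256L)) {
    if (counts[k] > 0L) {
      p <- counts[k] / n
      h <- h - p * log2(p)
    }
  }
  h
}

# independent Moore-boundary chain tracer computing the Kulpa perimeter,
# written as a direct position-based walk
oracle_perimeter <- function(m) {
  total <- sum(m == 1L)
  if (total == 1L) return(4 * 0.948)
  inside <- function(r, c) r >= 1 && c >= 1 && r <= nrow(m) &&
    c <= ncol(m) && m[r, c] == 1L
  # neighbours clockwise from east
  nb <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
             c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  start <- NULL
  for (j in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      if (m[i, j] == 1L) { start <- c(i, j); break }
    }
    if (!is.null(start)) break
  }
  back <- c(start[1], start[2] - 1)
  cur <- start
  straight <- 0L; diagonal <- 0L
  first_leave <- NULL
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > 8L * total + 16L) stop("oracle tracer did not terminate")
    kb <- NA
    for (k in 1:8) {
      if (all(back - cur == nb[[k]])) kb <- k
    }
    nxt <- NULL; newback <- back
    for (t in 1:8) {
      k <- ((kb - 1 + t) %% 8) + 1
      cand <- cur + nb[[k]]
      if (inside(cand[1], cand[2])) { nxt <- cand; break }
      newback <- cand
    }
    if (is.null(nxt)) return(4 * 0.948)
    if (all(cur == start)) {
      if (is.null(first_leave)) first_leave <- nxt
      else if (all(nxt == first_leave)) break
    }
    mv <- nxt - cur
    if (mv[1] != 0 && mv[2] != 0) diagonal <- diagonal + 1L
    else straight <- straight + 1L
    back <- newback
    cur <- nxt
  }
  0.948 * straight + 1.340 * diagonal
}

oracle_circularity <- function(m) {
  a <- sum(m == 1L)
  p <- oracle_perimeter(m)
  4 * pi * a / p^2
}
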
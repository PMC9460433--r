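# Independent exhaustive greedy re-implementation of the region-merging
# criterion, used as the oracle for the optimized merge engine. Segments are
# identified by their minimum row-major pixel id; every iteration recomputes
# all pairwise fusion costs from scratch and merges the global minimum-cost
# adjacent pair while its cost is below scale^2 (ties: smallest (a, b) pair;
# the merged segment keeps the smaller id).

oracle_stats <- function(pix, nr, nc, layers) {
  r <- (pix - 1) %/% nc + 1
  c <- (pix - 1) %% nc + 1
  vals <- lapply(layers, function(m) m[cbind(r, c)])
  list(
    n = length(pix),
    l = oracle_perimeter(pix, nr, nc),
    bbox = c(min(r), max(r), min(c), max(c)),
    sum = vapply(vals, sum, numeric(1)),
    sumsq = vapply(vals, function(v) sum(v^2), numeric(1))
  )
}

oracle_perimeter <- function(pix, nr, nc) {
  r <- (pix - 1) %/% nc + 1
  c <- (pix - 1) %% nc + 1
  inset <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- rep(FALSE, length(rr))
    out[ok] <- ((rr[ok] - 1) * nc + cc[ok]) %in% pix
    out
  }
  sum(!inset(r - 1, c)) + sum(!inset(r + 1, c)) +
    sum(!inset(r, c - 1)) + sum(!inset(r, c + 1))
}

# shared unit edges between two pixel sets
oracle_shared <- function(pa, pb, nr, nc) {
  r <- (pa - 1) %/% nc + 1
  c <- (pa - 1) %% nc + 1
  cnt <- 0
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    rr <- r + d[1]; cc <- c + d[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cnt <- cnt + sum(((rr[ok] - 1) * nc + cc[ok]) %in% pb)
  }
  cnt
}

oracle_segment <- function(layers, w, scale) {
  if (is.matrix(layers)) layers <- list(layers)
  nr <- nrow(layers[[1]]); nc <- ncol(layers[[1]])
  npix <- nr * nc
  seg_of <- seq_len(npix)        # pixel (row-major id) -> segment id
  thr <- scale^2
  repeat {
    ids <- sort(unique(seg_of))
    pixsets <- split(seq_len(npix), seg_of)
    stats <- lapply(pixsets, oracle_stats, nr = nr, nc = nc, layers = layers)
    best <- NULL
    for (ai in seq_along(ids)) {
      for (bi in seq_along(ids)) {
        if (bi <= ai) next
        a <- ids[ai]; b <- ids[bi]
        sh <- oracle_shared(pixsets[[as.character(a)]],
                            pixsets[[as.character(b)]], nr, nc)
        if (sh == 0) next
        cost <- fusion_cost(stats[[as.character(a)]],
                            stats[[as.character(b)]], w, shared_edges = sh)
        if (is.null(best) || cost < best$cost) {
          best <- list(cost = cost, a = a, b = b)
        }
      }
    }
    if (is.null(best) || !(best$cost < thr)) break
    seg_of[seg_of == best$b] <- best$a
  }
  # canonical relabel: 1..K in row-major first-appearance order
  lab <- match(seg_of, unique(seg_of))
  matrix(lab, nr, nc, byrow = TRUE)
}

canonical_labels <- function(m) {
  v <- as.vector(t(m))  # row-major
  matrix(match(v, unique(v[!is.na(v)])), nrow(m), ncol(m), byrow = TRUE)
}

# 4-connectivity check of every segment in a label matrix
segments_connected <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  for (id in unique(lab[!is.na(lab)])) {
    cells <- which(lab == id)
    seen <- logical(length(cells))
    names(seen) <- cells
    queue <- cells[1]
    seen[1] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nr + 1; c <- (cur - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        lin <- (cc - 1) * nr + rr
        j <- match(lin, cells)
        if (!is.na(j) && !seen[j]) {
          seen[j] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}

# single-pixel segment stats for fusion_cost unit tests
pixel_stats <- function(row, col, values) {
  list(n = 1, l = 4, bbox = c(row, row, col, col),
       sum = values, sumsq = values^2)
}
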
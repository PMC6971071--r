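# Brute-force oracles: deliberately naive (loops, flood fill, exhaustive
# enumeration) so they stay independent of the package's vectorized and
# compiled implementations.

rand_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# 8-connected labeling by queue-based flood fill.
brute_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      rc <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- rc[1L] + dr; cc <- rc[2L] + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

brute_filter_particles <- function(mask, min_area) {
  lab <- brute_label(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
}

brute_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- 0L
  at <- function(r, c) {
    if (r < 1L || r > nr || c < 1L || c > nc) FALSE else mask[r, c]
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    edges <- edges + (!at(r - 1L, c)) + (!at(r + 1L, c)) +
      (!at(r, c - 1L)) + (!at(r, c + 1L))
  }
  edges
}

brute_detached <- function(mask, min_size) {
  lab <- brute_label(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) <= 1L) return(0L)
  sum(sizes[-which.max(sizes)] >= min_size)
}

# Count degree-1 pixels of a skeleton by direct neighbor enumeration.
brute_endpoints <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  n <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    deg <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc])
        deg <- deg + 1L
    }
    if (deg == 1L) n <- n + 1L
  }
  n
}

brute_max_invasion_length <- function(mask_t, centroid_ref, area_ref) {
  best <- -Inf
  for (r in seq_len(nrow(mask_t))) for (c in seq_len(ncol(mask_t))) {
    if (!mask_t[r, c]) next
    d <- sqrt((r - centroid_ref[1L])^2 + (c - centroid_ref[2L])^2)
    if (d > best) best <- d
  }
  max(0, best - sqrt(area_ref / pi))
}

brute_moving_average <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - (w - 1L) %/% 2L)
    hi <- min(n, i + w %/% 2L)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# A filled disk mask with the pixel-center-in-circle convention.
disk_mask <- function(size, radius, center = (size + 1) / 2) {
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  sqrt((row - center)^2 + (col - center)^2) <= radius
}

# A micrograph whose segmentation has exactly the requested subareas,
# for closed-form index checks.
micrograph_with_areas <- function(area_core, area_intermediate, area_edge,
                                  size = 20L) {
  total <- area_core + area_intermediate + area_edge
  stopifnot(total <= size * size)
  vals <- c(rep(40, area_core), rep(100, area_intermediate),
            rep(150, area_edge), rep(240, size * size - total))
  micrograph(matrix(vals, size, size))
}

default_thresholds <- function() threshold_set(200, 110, 70)
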
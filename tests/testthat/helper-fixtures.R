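# Shared fixtures and independent oracles, built in code.

# Rectangular frame mask with optional interior content.
frame_mask <- function(h, w) {
  m <- matrix(0L, h, w)
  m[c(1L, h), ] <- 1L
  m[, c(1L, w)] <- 1L
  m
}

# Frame + single full-height vertical boundary at column `col`.
vsplit_mask <- function(h, w, col) {
  m <- frame_mask(h, w)
  m[, col] <- 1L
  m
}

# Random blobby mask used for thinning/labeling property tests: a frame
# plus random thick lines and rectangles.
random_structure_mask <- function(h, w, seed) {
  set.seed(seed)
  m <- frame_mask(h, w)
  for (i in seq_len(sample(1:3, 1))) {
    if (runif(1) < 0.5) {
      col <- sample(3:(w - 2), 1)
      m[, col:min(w, col + sample(0:2, 1))] <- 1L
    } else {
      row <- sample(3:(h - 2), 1)
      m[row:min(h, row + sample(0:2, 1)), ] <- 1L
    }
  }
  for (i in seq_len(sample(0:2, 1))) {
    r <- sample(2:(h - 3), 1); c <- sample(2:(w - 3), 1)
    m[r:(r + sample(1:2, 1)), c:(c + sample(1:2, 1))] <- 1L
  }
  m
}

# Brute-force distance oracle: for each pixel of the image and each
# region label, scan every labeled pixel. Shares only arithmetic
# primitives with the implementation under test.
brute_distance_maps <- function(labeled, st, sw) {
  h <- nrow(labeled); w <- ncol(labeled)
  n <- max(labeled)
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  st2 <- st^2; sw2 <- sw^2
  lapply(seq_len(n), function(i) {
    px <- which(labeled == i, arr.ind = TRUE)
    M <- st2 * outer(rr, px[, 1], "-")^2 + sw2 * outer(cc, px[, 2], "-")^2
    j <- max.col(-M, ties.method = "first")
    matrix(sqrt(M[cbind(seq_along(j), j)]), h, w)
  })
}

# Independent breadth-first distance (step count) between two pixels of
# `passable`, written from scratch with a plain queue; NA if unreachable.
bfs_steps_oracle <- function(passable, a, b) {
  h <- nrow(passable); w <- ncol(passable)
  dist <- matrix(NA_integer_, h, w)
  dist[a[1], a[2]] <- 0L
  queue <- matrix(a, 1, 2)
  head <- 1L
  while (head <= nrow(queue)) {
    p <- queue[head, ]; head <- head + 1L
    if (p[1] == b[1] && p[2] == b[2]) return(dist[b[1], b[2]])
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      q <- p + d
      if (q[1] < 1L || q[1] > h || q[2] < 1L || q[2] > w) next
      if (passable[q[1], q[2]] == 1L && is.na(dist[q[1], q[2]])) {
        dist[q[1], q[2]] <- dist[p[1], p[2]] + 1L
        queue <- rbind(queue, q)
      }
    }
  }
  dist[b[1], b[2]]
}

# Map the generator's regions onto pipeline labels via the per-region
# interior seed points; fails if any seed lands on a boundary pixel.
match_regions <- function(labeled, truth) {
  vapply(seq_len(nrow(truth$seeds)), function(k) {
    px <- data_to_pixel(truth$seeds[k, ], truth$cal)
    labeled[px[1], px[2]]
  }, 0L)
}

example_record_path <- function() {
  system.file("extdata", "phdat_example.json", package = "phasedig",
              mustWork = TRUE)
}

# Small valid probability table for record-construction tests.
toy_table <- function(nrows = 2) {
  data.frame(temperature = seq_len(nrows) - 1,
             composition = rep(50, nrows),
             "L1" = rep(0.5, nrows),
             "La" = rep(0.5, nrows),
             check.names = FALSE)
}

toy_record <- function(tab = toy_table(), state = "complete",
                       method = "A", type = "anionic", ...) {
  phdat_record(tab, smiles = "CCCCCCCCCCCCOS(=O)(=O)[O-].[Na+]",
               state = state, name = "toy surfactant",
               source = "unit-test fixture", figure = "1",
               method = method, type = type, ...)
}
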
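# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so expected values frozen in the tests stay valid.

# area-uniform samples of a sphere surface
sphere_points <- function(n, center = c(0, 0, 0), radius = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  sweep(v * radius, 2, center, "+")
}

# deterministic near-uniform sphere sampling (Fibonacci lattice)
fib_sphere <- function(n, center = c(0, 0, 0), radius = 1) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  sweep(cbind(rho * cos(phi), z, rho * sin(phi)) * radius, 2, center, "+")
}

# axis-aligned planar patch in the y = const plane
plane_points <- function(n, y = 0, extent = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(runif(n, 0, extent), y, runif(n, 0, extent))
}

# Monte-Carlo sphere intersection fraction: uniform samples inside the
# smaller sphere, fraction also inside the larger one. Independent of the
# closed-form implementation.
mc_overlap_fraction <- function(c1, r1, c2, r2, n = 1e6, chunk = 1e6,
                                seed = 1) {
  if (r2 < r1) {  # sample inside the smaller sphere
    tmp <- c1; c1 <- c2; c2 <- tmp
    tmp <- r1; r1 <- r2; r2 <- tmp
  }
  set.seed(seed)
  hits <- 0
  left <- n
  while (left > 0) {
    m <- min(chunk, left)
    dir <- matrix(rnorm(3 * m), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- r1 * runif(m)^(1 / 3)
    pts <- sweep(dir * rad, 2, c1, "+")
    hits <- hits + sum(rowSums(sweep(pts, 2, c2, "-")^2) < r2^2)
    left <- left - m
  }
  hits / n
}

# brute-force average ranks (sort-based, no use of base::rank)
brute_ranks <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  pos <- seq_along(x)
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}

# tiny ASCII PLY with faces, written in code (text only)
write_face_ply <- function(path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 2",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "10 0 0", "0 10 0", "0 0 10",
    "3 0 1 2", "3 0 1 3"), path)
  path
}

default_test_bunch <- function(n = 20, seed = 7, ...) {
  generate_bunch(synthetic_bunch_spec(n_berries = n, seed = seed, ...))
}
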
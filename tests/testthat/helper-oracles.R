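# Independent brute-force oracles for the morphology operators. These share
# no code with the package internals: dilation/erosion enumerate ball
# offsets and shift whole arrays; connectivity analyses go through igraph.

oracle_ball_offsets <- function(r) {
  s <- ceiling(r)
  g <- expand.grid(dz = -s:s, dy = -s:s, dx = -s:s)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2 + 1e-7, ])
}

# translate a logical array by integer offset o, zero-filling
oracle_shift <- function(m, o) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- vector("list", 3)
  dst <- vector("list", 3)
  for (a in 1:3) {
    s1 <- max(1L, 1L - o[a])
    s2 <- min(d[a], d[a] - o[a])
    if (s1 > s2) return(out)
    src[[a]] <- s1:s2
    dst[[a]] <- (s1 + o[a]):(s2 + o[a])
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

oracle_dilate <- function(m, r) {
  offs <- oracle_ball_offsets(r)
  acc <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) {
    acc <- acc | oracle_shift(m, offs[i, ])
  }
  acc
}

# erosion = complement of dilation of the complement (ball is symmetric)
oracle_erode <- function(m, r) !oracle_dilate(!m, r)

oracle_pad <- function(m, p) {
  d <- dim(m)
  out <- array(FALSE, d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- m
  out
}

# closing on Z^3: pad so neither dilation nor erosion sees the grid edge
oracle_close <- function(m, r) {
  p <- as.integer(ceiling(r)) + 1L
  cl <- oracle_erode(oracle_dilate(oracle_pad(m, p), r), r)
  d <- dim(m)
  cl[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# forward neighbor offsets for building undirected adjacency once per pair
.oracle_forward_offsets <- function(connectivity) {
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  # keep one representative of each +/- pair
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, ])
}

# igraph-based connected components of TRUE voxels; returns membership array
# (0 = background) with component ids in order of smallest linear index
oracle_label_components <- function(m, connectivity = 26) {
  d <- dim(m)
  sel <- which(m)
  if (length(sel) == 0L) return(array(0L, d))
  id <- integer(prod(d))
  id[sel] <- seq_along(sel)
  offs <- .oracle_forward_offsets(connectivity)
  idx <- seq_len(prod(d))
  k <- (idx - 1L) %/% (d[1] * d[2])
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  i <- (idx - 1L) %% d[1]
  edges <- integer(0)
  for (t in seq_len(nrow(offs))) {
    o <- offs[t, ]
    ok <- i + o[1] >= 0 & i + o[1] < d[1] &
      j + o[2] >= 0 & j + o[2] < d[2] &
      k + o[3] >= 0 & k + o[3] < d[3]
    nb <- idx + o[1] + d[1] * o[2] + d[1] * d[2] * o[3]
    pair <- rep(FALSE, length(idx))
    pair[ok] <- m[idx[ok]] & m[nb[ok]]
    if (any(pair)) {
      edges <- c(edges, rbind(id[idx[pair]], id[nb[pair]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(sel), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in scan order
  first <- match(unique(memb), memb)
  renum <- integer(max(memb))
  renum[memb[sort(first)]] <- seq_along(first)
  out <- integer(prod(d))
  out[sel] <- renum[memb]
  array(out, d)
}

# fill background components not touching the border (6-connected background)
oracle_fill_holes <- function(m) {
  lab <- oracle_label_components(!m, connectivity = 6)
  d <- dim(m)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  reachable <- unique(lab[border & !m])
  out <- m
  out[!m & !(lab %in% reachable)] <- TRUE
  out
}

oracle_fill_pores <- function(m, r) oracle_fill_holes(oracle_close(m, r))

# exact squared EDT by direct minimization (tiny inputs only)
oracle_edt_sq <- function(site, spacing = c(1, 1, 1)) {
  d <- dim(site)
  sel <- which(site, arr.ind = TRUE)
  out <- array(Inf, d)
  if (nrow(sel) == 0L) return(out)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    dz <- (i - sel[, 1]) * spacing[1]
    dy <- (j - sel[, 2]) * spacing[2]
    dx <- (k - sel[, 3]) * spacing[3]
    out[i, j, k] <- min(dz^2 + dy^2 + dx^2)
  }
  out
}

# seeded Bernoulli test mask
random_mask <- function(shape, p, seed) {
  withr::with_seed(seed, array(stats::runif(prod(shape)) < p, dim = shape))
}

# axis-aligned solid cube of edge n centered in a volume padded by `pad`
solid_cube <- function(n, pad) {
  arr <- array(FALSE, dim = rep(n + 2 * pad, 3))
  arr[pad + seq_len(n), pad + seq_len(n), pad + seq_len(n)] <- TRUE
  arr
}

# small hollow-shell phantom spec used across tests
small_shell_spec <- function(..., shape = c(72, 72, 72),
                             outer_radii = c(27, 24, 21),
                             cortical_thickness = 10, noise_sigma = 0,
                             seed = 7L) {
  phantom_spec(shape = shape, outer_radii = outer_radii,
               cortical_thickness = cortical_thickness,
               noise_sigma = noise_sigma, seed = seed, ...)
}
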
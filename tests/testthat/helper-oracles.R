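# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (no Rcpp, no regression helpers).

# Brute-force flood-fill labelling of a 3D logical array, plain R.
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  labels <- array(0L, d)
  nxt <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z] || labels[x, y, z] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(x, y, z))
    labels[x, y, z] <- nxt
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        w <- v + c(offs$dx[i], offs$dy[i], offs$dz[i])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0) {
          labels[w[1], w[2], w[3]] <- nxt
          stack[[length(stack) + 1]] <- w
        }
      }
    }
  }
  labels
}

# Digitized ball of radius r voxels, centered in a (2r+3)^3 array.
digitized_ball <- function(r) {
  n <- 2 * r + 3
  ctr <- (n + 1) / 2
  x <- seq_len(n)
  dist2 <- outer(outer((x - ctr)^2, (x - ctr)^2, `+`), (x - ctr)^2, `+`)
  array(dist2 <= r^2, c(n, n, n))
}

# Brute-force perimeter count: loop over voxels, test 6 face neighbours.
brute_perimeter <- function(mask) {
  d <- dim(mask)
  count <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    nb <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
               c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    for (w in nb) {
      if (any(w < 1) || any(w > d) || !mask[w[1], w[2], w[3]]) {
        count <- count + 1
        break
      }
    }
  }
  count
}

# tau(q) from brute-force moment sums of an explicit cascade measure at one
# deep level: tau = log2(sum mu^q) / (-k).
brute_tau <- function(w, q) {
  k <- log2(length(w))
  log2(sum(w[w > 0]^q)) / (-k)
}

# Shared phantom fixtures, built once per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fragment_phantom_128 <- function(seed = 1) {
  cached(paste0("frag128_", seed), function() {
    generate_phantom(phantom_spec(c(128, 128, 128), "fragment_pack",
                                  seed = seed))
  })
}

tube_phantom_128 <- function() {
  cached("tube128", function() {
    generate_phantom(phantom_spec(c(128, 128, 128), "tube_array",
                                  tube_axis = 3))
  })
}

fragment_phantom_64 <- function(seed = 1) {
  cached(paste0("frag64_", seed), function() {
    generate_phantom(phantom_spec(c(64, 64, 64), "fragment_pack", seed = seed))
  })
}
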
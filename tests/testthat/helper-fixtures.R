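# shared fixtures, built in code at test time

# small deterministic cube: dims (nr, nc, nb), values a smooth function of
# indices so interleave mistakes are detectable
tiny_cube <- function(nr = 2L, nc = 2L, nb = 3L,
                      wl = seq(450, 800, length.out = nb)) {
  a <- array(0, dim = c(nr, nc, nb))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) for (b in seq_len(nb))
    a[r, cc, b] <- r + 10 * cc + 100 * b + 0.001 * r * b
  hypercube(a, wl)
}

# reduced-axis generator config for fast search tests
small_config <- function(n_bands = 40L, seed = 1L, ...) {
  generator_config(wavelengths_nm = seq(450, 800, length.out = n_bands),
                   seed = seed, ...)
}

# independent brute-force connected-component centroid (double loops, no
# shared code with top_region_centroid)
brute_centroid <- function(r2, wl, delta = 0.01, connected = TRUE) {
  mx <- max(r2, na.rm = TRUE)
  B <- nrow(r2)
  inset <- matrix(FALSE, B, B)
  for (i in seq_len(B)) for (j in seq_len(B))
    if (is.finite(r2[i, j]) && r2[i, j] >= mx - delta) inset[i, j] <- TRUE
  if (connected) {
    best <- NULL; bestval <- -Inf
    for (i in seq_len(B)) for (j in seq_len(B))
      if (is.finite(r2[i, j]) && r2[i, j] >= mx - 1e-9 &&
          (wl[i] - wl[j]) > bestval) {
        best <- c(i, j); bestval <- wl[i] - wl[j]
      }
    comp <- matrix(FALSE, B, B)
    comp[best[1L], best[2L]] <- TRUE
    repeat {
      changed <- FALSE
      for (i in seq_len(B)) for (j in seq_len(B)) {
        if (comp[i, j] || !inset[i, j]) next
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= B && jj >= 1 && jj <= B && comp[ii, jj]) {
            comp[i, j] <- TRUE; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    inset <- comp
  }
  # column-major accumulation, matching the summation order of which()
  m00 <- 0L; m10 <- 0; m01 <- 0
  for (j in seq_len(B)) for (i in seq_len(B)) if (inset[i, j]) {
    m00 <- m00 + 1L; m10 <- m10 + wl[i]; m01 <- m01 + wl[j]
  }
  list(m00 = m00, m10 = m10, m01 = m01, cx = m10 / m00, cy = m01 / m00)
}
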
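# Independent brute-force oracles used across the test files.  These are kept
# deliberately naive (double loops, direct formulas) so they share no code
# with the implementation they check.

# O(N^2) total energy with explicit minimum image and the 4*V1 LJ convention
brute_energy <- function(pos, box, p) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- pos[i, 1] - pos[j, 1]
      dy <- pos[i, 2] - pos[j, 2]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      r <- sqrt(dx^2 + dy^2)
      if (r < p$r_c) {
        s100 <- (p$sigma / r)^100
        lj <- 4 * p$V1 * (s100^2 - s100)
        yuk <- p$V2 * exp(-r / p$lambda) / (r / p$lambda)
        e <- e + lj + yuk
      }
    }
  }
  e
}

# naive per-particle neighbour counts within a cutoff (periodic minimum image)
brute_neighbor_counts <- function(pos, box, cutoff) {
  n <- nrow(pos)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- pos[i, 1] - pos[j, 1]
      dy <- pos[i, 2] - pos[j, 2]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      if (dx^2 + dy^2 < cutoff^2) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

# miniature geometry used throughout: N = 40 charges, core 10 nm, grafting
# density matched to the experimental brush
mini_geom <- function() miniature_brush_params()

# a tiny valid cell state at miniature scale
mini_state <- function(L = 4, N3 = 50, R_W_mult = 8) {
  g <- mini_geom()
  cell_state(g, R_W_mult * (g$R_PS + g$L_C), L, N3)
}
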
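# Shared fixtures and independent oracles.

# Event-driven brute-force latch oracle: per unit, walk the rate sequence
# with explicit if/else state updates (independent of the vectorized
# latch rule used by the implementation).
oracle_latch_path <- function(w, Tu, Td, r_seq, start_up = FALSE) {
  states <- matrix(NA, length(r_seq), length(w))
  up <- rep(start_up, length(w))
  for (s in seq_along(r_seq)) {
    for (i in seq_along(w)) {
      h <- w[i] * r_seq[s]
      if (!up[i]) {
        if (h >= Tu) up[i] <- TRUE
      } else {
        if (h <= Td) up[i] <- FALSE
      }
    }
    states[s, ] <- up
  }
  states
}

# Exhaustive enumeration oracle for stable autapse rates: every latch
# configuration (2^Nd of them) is checked for self-consistency at its
# implied rate.
enumerate_stable_rates <- function(w, Tu, Td, beta = 1) {
  nd <- length(w)
  stable <- numeric(0)
  for (mask in 0:(2^nd - 1)) {
    up <- as.logical(bitwAnd(mask, 2^(seq_len(nd) - 1)))
    r <- beta * sum(up)
    ok_up <- all(w[up] * r > Td)
    ok_down <- all(w[!up] * r < Tu)
    if (ok_up && ok_down) stable <- c(stable, r)
  }
  sort(unique(stable))
}

# Feedback-vs-rate curve from a parametric band trace: feedback at the
# first time the rate crosses each grid value.
band_curve <- function(trace, r_grid) {
  vapply(r_grid, function(x) {
    i <- which(trace$rate >= x)[1]
    if (is.na(i)) NA_real_ else trace$feedback[i]
  }, numeric(1))
}

# Largest pointwise gap between two band curves, allowing each comparison
# point to slide by up to `window` rate units (tolerates step-edge
# misalignment between traces).
band_gap <- function(tr1, tr2, r_grid, window = 1) {
  b1 <- band_curve(tr1, r_grid)
  step <- r_grid[2] - r_grid[1]
  k <- round(window / step)
  b2 <- band_curve(tr2, r_grid)
  n <- length(r_grid)
  worst <- 0
  for (i in seq_len(n)) {
    if (is.na(b1[i])) next
    lo <- max(1, i - k)
    hi <- min(n, i + k)
    cand <- abs(b1[i] - b2[lo:hi])
    cand <- cand[!is.na(cand)]
    if (length(cand)) worst <- max(worst, min(cand))
  }
  worst
}
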
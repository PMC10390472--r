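# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (brute force) and separate from the package
# code paths they check.

# single straight fiber phantom, horizontal at height y_um
single_fiber_phantom <- function(sigma_nm = 31.85, pixel_size = 0.01,
                                 field = c(3, 1.5), y_um = NULL) {
  if (is.null(y_um)) y_um <- field[2] / 2
  fiber_network_phantom(
    field_um = field, pixel_size = pixel_size,
    fibers = data.frame(x0 = 0.15 * field[1], y0 = y_um,
                        x1 = 0.85 * field[1], y1 = y_um),
    sigma_nm = sigma_nm)
}

# O(n^2) textbook DBSCAN membership oracle: returns logical vector, TRUE for
# cluster members (core or border), FALSE for noise
naive_dbscan_members <- function(x, y, eps, min_pts) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- d2 <= eps^2           # includes self
  core <- rowSums(nb) >= min_pts
  member <- core
  for (i in which(!core)) member[i] <- any(nb[i, ] & core)
  member
}

# independent per-line run scanner: off-runs strictly between on pixels
naive_line_gaps <- function(v) {
  gaps <- integer(0)
  run <- 0L; seen_on <- FALSE
  for (p in v) {
    if (p) {
      if (seen_on && run > 0L) gaps <- c(gaps, run)
      run <- 0L; seen_on <- TRUE
    } else if (seen_on) {
      run <- run + 1L
    }
  }
  gaps
}

naive_count_gaps <- function(mask, px) {
  g <- c(unlist(lapply(seq_len(nrow(mask)), function(i) naive_line_gaps(mask[i, ]))),
         unlist(lapply(seq_len(ncol(mask)), function(j) naive_line_gaps(mask[, j]))))
  g * px
}

# brute-force 1D search of the exponential negative log-likelihood
naive_exp_mle <- function(gaps) {
  nll <- function(l) -sum(stats::dexp(gaps, l, log = TRUE))
  stats::optimize(nll, c(1e-4, 10 / mean(gaps)))$minimum
}

# Thompson-style precision recomputed independently for expectation checks
expected_precision <- function(s, N, a, b) {
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}
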
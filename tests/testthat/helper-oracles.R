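# Independent oracles shared by the module tests and the acceptance
# suite: a literal re-count implementation of the window rule and a
# dense grid-search maximiser of the two-locus F2 likelihood.

# independent re-count oracle for the sliding-window caller
recount_oracle <- function(ad1, ad2, window, step, ratio, min_inf) {
  nsnp <- nrow(ad1)
  w <- min(window, nsnp)
  starts <- seq(1, nsnp - w + 1, by = step)
  out <- matrix(NA_integer_, length(starts), ncol(ad1))
  for (j in seq_len(ncol(ad1))) {
    for (k in seq_along(starts)) {
      idx <- starts[k]:(starts[k] + w - 1)
      s1 <- s2 <- inf <- 0
      for (i in idx) {
        h1 <- ad1[i, j] > 0; h2 <- ad2[i, j] > 0
        if (h1 || h2) inf <- inf + 1
        if (h1) s1 <- s1 + 1
        if (h2) s2 <- s2 + 1
      }
      if (inf < min_inf) next
      a <- s1 >= ratio * s2
      b <- s2 >= ratio * s1
      out[k, j] <- if (a && b) NA_integer_ else if (a) 1L else
        if (b) 3L else 2L
    }
  }
  out
}

# dense grid-search ML oracle for the two-locus F2 likelihood:
# coarse pass at 1e-3, then a fine pass (2e-5) around the optimum so
# the oracle's own resolution is well below the comparison tolerance
grid_ml_r <- function(n9) {
  coarse <- seq(0.001, 0.499, by = 0.001)
  r0 <- coarse[which.max(recfrac_loglik(n9, coarse))]
  fine <- seq(max(1e-5, r0 - 2e-3), min(0.49999, r0 + 2e-3), by = 2e-5)
  fine[which.max(recfrac_loglik(n9, fine))]
}

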
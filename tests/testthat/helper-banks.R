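# Calibration blocks used throughout: two, three and four items with spread
# difficulties and discriminations.
block_two <- function()
  item_bank(list(irt_item(1.6, -1), irt_item(1.6, 1)))

block_three <- function()
  item_bank(list(irt_item(1, -1.5), irt_item(2, 0.5), irt_item(2.5, 2)))

block_four <- function()
  item_bank(list(irt_item(1.5, -1.5), irt_item(1, -0.25), irt_item(1, 0.25),
                 irt_item(1.5, 1.5)))

# operational-uncertainty model for an m-item stylized test
normal_um <- function(m, a_op = 1)
  uncertainty_model("normal", make_operational_test(m, a_op))

# Exhaustive-search oracle for 2PL D-optimal allocation on a coarse grid:
# enumerates every 0/1 assignment of cells to items and returns the best
# attainable sum of block log-determinants (rank-deficient blocks excluded
# by the same relative-noise rule the optimizer uses).
brute_force_best <- function(bank, grid, um = uncertainty_model("known")) {
  elems <- optcalib:::.elemental_grid(bank, grid, um)
  mass <- grid$htot * grid$step
  n <- length(bank)
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), grid$J)))
  best <- -Inf
  for (r in seq_len(nrow(combos))) {
    a <- combos[r, ]
    val <- 0
    for (i in seq_len(n)) {
      m <- matrix(elems[[i]] %*% (mass * (a == i)), 2, 2)
      d <- det(m)
      if (d <= 1e-10 * m[1, 1] * m[2, 2]) { val <- -Inf; break }
      val <- val + log(d)
    }
    if (val > best) best <- val
  }
  best
}

# random symmetric PSD 2x2 matrix (for efficiency identities)
rand_psd2 <- function() {
  A <- matrix(stats::rnorm(4), 2, 2)
  crossprod(A) + diag(2) * 0.1
}
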
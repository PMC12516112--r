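test_that("grid construction is exact and carries unit normal mass", {
  g <- build_grid()
  expect_equal(g$J, 1200L)
  expect_equal(g$midpoints[1], -6 + 0.005)
  expect_lt(abs(sum(dnorm(g$midpoints) * g$step) - 1), 1e-6)
  expect_error(build_grid(step = -0.1), "positive")
  expect_error(build_grid(0, 1, 0.3), "divide")
})

test_that("the random design splits every cell equally", {
  g <- build_grid(step = 0.1)
  d <- random_design(3, g)
  expect_true(all(d$weights == 1 / 3))
  expect_equal(rowSums(d$weights), rep(1, g$J))
  # per-item subdensity integrates to 1/n
  expect_equal(sum(d$weights[, 1] * g$htot * g$step), 1 / 3,
               tolerance = 1e-6)
  # n = 1 random design is the full allocation
  d1 <- random_design(1, g)
  expect_true(all(d1$weights == 1))
})

test_that("a single calibration item receives the whole axis", {
  d <- optimize_design(item_bank(list(irt_item(1.2, 0))),
                       build_grid(step = 0.1))
  iv <- extract_intervals(d)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$lower, iv$upper, iv$item), c(-6, 6, 1))
})

test_that("exchange matches exhaustive search on coarse grids", {
  # all 0/1 assignments enumerated; the exchange result must attain the max
  cases <- list(
    list(bank = block_two(), grid = build_grid(step = 2),
         um = uncertainty_model("known")),
    list(bank = block_two(), grid = build_grid(step = 2),
         um = normal_um(6)),
    list(bank = block_three(), grid = build_grid(step = 1.5),
         um = uncertainty_model("known"))
  )
  for (cs in cases) {
    best <- brute_force_best(cs$bank, cs$grid, cs$um)
    d <- optimize_design(cs$bank, cs$grid, cs$um)
    expect_equal(attr(d, "criterion_value"), best, tolerance = 1e-9)
  }
})

test_that("the criterion never decreases across exchange sweeps", {
  for (um in list(uncertainty_model("known"), normal_um(6))) {
    d <- optimize_design(block_three(), build_grid(step = 0.02), um)
    path <- attr(d, "criterion_path")
    expect_true(all(diff(path) >= -1e-9 * (1 + abs(path[-length(path)]))))
    expect_true(attr(d, "converged"))
  }
})

test_that("identical items give a label-symmetric optimum", {
  twin <- item_bank(list(irt_item(1.5, 0), irt_item(1.5, 0)))
  g <- build_grid(step = 0.1)
  d <- optimize_design(twin, g)
  M <- assemble_from_grid(twin, d, g, uncertainty_model("known"))
  # swapping the two columns must leave the criterion unchanged
  dsw <- structure(list(grid = g, weights = d$weights[, 2:1]),
                   class = "calib_design")
  Msw <- assemble_from_grid(twin, dsw, g, uncertainty_model("known"))
  expect_equal(sum(log(block_dets(M))), sum(log(block_dets(Msw))),
               tolerance = 1e-10)
})

test_that("the two-item optimal design is symmetric and alternating", {
  # a1 = a2, b1 = -b2: mirroring the axis and relabeling items is a symmetry
  d <- optimize_design(block_two(), build_grid(step = 0.01))
  iv <- extract_intervals(d)
  expect_equal(nrow(iv), 4L)
  expect_equal(iv$item, c(1, 2, 1, 2))
  expect_equal(iv$lower[-1], -rev(iv$upper[-4]), tolerance = 1e-9)
})

test_that("interval extraction round-trips and rejects fractional designs", {
  g <- build_grid(step = 0.05)
  d <- optimize_design(block_three(), g, normal_um(30))
  iv <- extract_intervals(d)
  expect_equal(iv$lower[1], -6)
  expect_equal(iv$upper[nrow(iv)], 6)
  expect_true(all(iv$upper > iv$lower))
  expect_true(all(diff(iv$item) != 0))
  d2 <- intervals_to_design(iv, g)
  expect_equal(d2$weights, d$weights)
  expect_error(extract_intervals(random_design(2, g)), "0/1")
})

test_that("cells with zero population mass still extend the intervals", {
  trunc_norm <- function(t) dnorm(t) * (abs(t) < 3)
  g <- build_grid(step = 0.5, density = trunc_norm)
  d <- optimize_design(block_two(), g)
  iv <- extract_intervals(d)
  expect_equal(iv$lower[1], -6)
  expect_equal(iv$upper[nrow(iv)], 6)
  expect_lt(nrow(iv), 8)  # tails merged into coherent intervals
})

test_that("sensitivity is maximized by the assigned item at the optimum", {
  bank <- block_two()
  g <- build_grid(step = 0.01)
  um <- uncertainty_model("known")
  d <- optimize_design(bank, g, um)
  M <- assemble_from_grid(bank, d, g, um)
  assign <- max.col(d$weights)
  # check interior midpoints away from interval boundaries
  for (t in c(-2, -0.4, 0.4, 2)) {
    j <- which.min(abs(g$midpoints - t))
    s <- vapply(1:2, function(i) sensitivity(d, i, g$midpoints[j], M,
                                             criterion_d(), um, bank),
                numeric(1))
    expect_equal(which.max(s), assign[j])
  }
})

test_that("D-sensitivity scales inversely with the information matrix", {
  bank <- block_two()
  g <- build_grid(step = 0.05)
  d <- optimize_design(bank, g)
  M <- assemble_from_grid(bank, d, g)
  Mk <- block_info(lapply(M$blocks, function(b) 3 * b))
  s1 <- sensitivity(d, 1, 0.5, M, criterion_d(), uncertainty_model("known"),
                    bank)
  s3 <- sensitivity(d, 1, 0.5, Mk, criterion_d(), uncertainty_model("known"),
                    bank)
  expect_equal(s3, s1 / 3, tolerance = 1e-12)
})

test_that("acknowledged uncertainty widens the middle intervals", {
  g <- build_grid(step = 0.01)
  d_inf <- optimize_design(block_two(), g)
  d_m6 <- optimize_design(block_two(), g, normal_um(6))
  mid_width <- function(d) {
    iv <- extract_intervals(d)
    sum((iv$upper - iv$lower)[abs((iv$upper + iv$lower) / 2) < 1])
  }
  expect_gt(mid_width(d_m6), mid_width(d_inf))
})

test_that("L-optimal designs run through the generic exchange path", {
  bank <- block_two()
  g <- build_grid(step = 0.1)
  d <- optimize_design(bank, g, criterion = criterion_c(c(0, 1)))
  expect_true(all(d$weights %in% c(0, 1)))
  path <- attr(d, "criterion_path")
  expect_true(all(diff(path) >= -1e-9 * (1 + abs(path[-length(path)]))))
  # the b-targeted design concentrates mass near each item's difficulty
  M <- assemble_from_grid(bank, d, g)
  Mr <- assemble_from_grid(bank, random_design(2, g), g)
  eff <- relative_efficiency(M, Mr, criterion_c(c(0, 1)))
  expect_gt(eff$overall, 1)
})

test_that("interval CSV export writes 4-decimal endpoints", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- optimize_design(block_two(), build_grid(step = 0.05))
  write_intervals(d, f)
  iv <- utils::read.csv(f)
  expect_named(iv, c("lower", "upper", "item"))
  expect_equal(iv$lower[1], -6)
})
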
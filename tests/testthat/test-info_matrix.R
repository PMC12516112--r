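test_that("ptilde respects symmetry and degenerate limits", {
  it <- irt_item(1.4, 0.6)
  # normal prior centered at b: p(b+x) + p(b-x) = 1 forces 1/2
  expect_equal(ptilde(it, ability_prior("normal", 0.6, 0.8)), 0.5,
               tolerance = 1e-12)
  # vanishing variance recovers the point probability
  expect_equal(ptilde(it, ability_prior("normal", -0.4, 1e-12)),
               prob(it, -0.4), tolerance = 1e-9)
  expect_equal(ptilde(it, ability_prior("point", mean = -0.4)),
               prob(it, -0.4))
})

test_that("ptilde quadrature matches a large Monte-Carlo oracle", {
  it <- irt_item(1.5, 1)
  v <- normal_posterior(0, make_operational_test(30, 1))$variance
  pr <- ability_prior("normal", 0, v)
  set.seed(31)
  draws <- rnorm(1e6, 0, sqrt(v))
  mc <- prob(it, draws)
  se <- stats::sd(mc) / 1000
  expect_lt(abs(ptilde(it, pr) - mean(mc)), 3 * se)
})

test_that("psi vector reduces correctly at a point prior and keeps signs", {
  it <- irt_item(1.2, -0.5)
  th <- 0.3
  p <- prob(it, th)
  expect_equal(psi_vector(it, ability_prior("point", mean = th)),
               p * (1 - p) * c(th + 0.5, -1.2), tolerance = 1e-12)
  # difficulty component is -a E[p(1-p)] < 0 for any normal prior
  expect_lt(psi_vector(it, ability_prior("normal", -0.5, 0.7))[2], 0)
})

test_that("psi vector matches an adaptive-quadrature oracle", {
  it <- irt_item(1, -1)
  pr <- ability_prior("normal", 0, 0.25)
  oracle1 <- integrate(function(t) {
    p <- prob(it, t); (t + 1) * p * (1 - p) * dnorm(t, 0, 0.5)
  }, -10, 10, rel.tol = 1e-12)$value
  oracle2 <- integrate(function(t) {
    p <- prob(it, t); -1 * p * (1 - p) * dnorm(t, 0, 0.5)
  }, -10, 10, rel.tol = 1e-12)$value
  expect_equal(psi_vector(it, pr), c(oracle1, oracle2), tolerance = 1e-8)
})

test_that("uncertainty-adjusted elemental info is a rank-1 outer product", {
  it <- irt_item(1.6, 1)
  pr <- normal_posterior(0.5, make_operational_test(12, 1))
  E <- elemental_info_uncertain(it, pr)
  psi <- psi_vector(it, pr)
  pt <- ptilde(it, pr)
  expect_equal(E[1, 1], psi[1]^2 / (pt * (1 - pt)), tolerance = 1e-12)
  expect_equal(E[1, 2], E[2, 1])
  expect_equal(E[1, 2], psi[1] * psi[2] / (pt * (1 - pt)), tolerance = 1e-12)
  expect_equal(det(E), 0, tolerance = 1e-15)
  # point prior reproduces the known-ability elemental matrix
  expect_equal(elemental_info_uncertain(it, ability_prior("point", mean = 0.5)),
               elemental_info_known(it, 0.5), tolerance = 1e-12)
})

test_that("known elemental info at theta = b isolates the difficulty entry", {
  E <- elemental_info_known(irt_item(1, -1), -1)
  expect_equal(E, 0.25 * matrix(c(0, 0, 0, 1), 2, 2))
  expect_gte(sum(diag(elemental_info_known(irt_item(2, 1), -3))), 0)
})

test_that("full allocation under known abilities reproduces the reference
           standardized information matrices", {
  # integrate() oracle agrees to 4 decimals: (.2158, -.1253, .1779) and
  # (.1175, .1123, .3146)
  bank <- item_bank(list(irt_item(1, -1), irt_item(1.5, 1)))
  d <- random_design(1, build_grid())
  for (k in 1:2) {
    one <- item_bank(list(bank[[k]]))
    M <- assemble_from_grid(one, d, uncertainty = uncertainty_model("known"))
    got <- round(M$blocks[[1]], 4)
    want <- if (k == 1) matrix(c(.2158, -.1253, -.1253, .1779), 2, 2)
            else matrix(c(.1175, .1123, .1123, .3146), 2, 2)
    expect_equal(got, want)
  }
})

test_that("assembly is linear in the allocation", {
  bank <- block_two()
  grid <- build_grid(step = 0.05)
  um <- normal_um(12)
  full <- random_design(1, grid)
  M1 <- assemble_from_grid(item_bank(list(bank[[1]])), full, grid, um)
  half <- random_design(2, grid)
  M2 <- assemble_from_grid(bank, half, grid, um)
  expect_equal(M2$blocks[[1]], M1$blocks[[1]] / 2, tolerance = 1e-12)
  # complementary interval designs sum to the full allocation per item
  iv_a <- data.frame(lower = c(-6, 0), upper = c(0, 6), item = c(1, 2))
  iv_b <- data.frame(lower = c(-6, 0), upper = c(0, 6), item = c(2, 1))
  Ma <- assemble_from_grid(bank, intervals_to_design(iv_a, grid), grid, um)
  Mb <- assemble_from_grid(bank, intervals_to_design(iv_b, grid), grid, um)
  Mf2 <- assemble_from_grid(item_bank(list(bank[[2]])), full, grid, um)
  expect_equal(Ma$blocks[[1]] + Mb$blocks[[1]], M1$blocks[[1]],
               tolerance = 1e-12)
  expect_equal(Ma$blocks[[2]] + Mb$blocks[[2]], Mf2$blocks[[1]],
               tolerance = 1e-12)
})

test_that("ability uncertainty can only lower the diagonal information", {
  um <- normal_um(30)
  grid <- build_grid(step = 0.02)
  d <- random_design(1, grid)
  for (it in unclass(block_three())) {
    one <- item_bank(list(it))
    Mk <- assemble_from_grid(one, d, grid, uncertainty_model("known"))
    Mu <- assemble_from_grid(one, d, grid, um)
    expect_lte(Mu$blocks[[1]][1, 1], Mk$blocks[[1]][1, 1] + 1e-12)
    expect_lte(Mu$blocks[[1]][2, 2], Mk$blocks[[1]][2, 2] + 1e-12)
  }
})

test_that("the normal uncertainty model converges to known abilities", {
  grid <- build_grid(step = 0.05)
  d <- random_design(1, grid)
  bank <- item_bank(list(irt_item(1.6, -1)))
  Mk <- assemble_from_grid(bank, d, grid, uncertainty_model("known"))
  Mu <- assemble_from_grid(bank, d, grid, normal_um(10000))
  expect_lt(max(abs(Mu$blocks[[1]] - Mk$blocks[[1]])), 1e-3)
})

test_that("quadrature and draw-based elemental info agree within MC error", {
  it <- irt_item(1.5, 1)
  mu <- 0.3; v <- 0.2
  set.seed(41)
  draws <- rnorm(1e5, mu, sqrt(v))
  Eq <- elemental_info_uncertain(it, ability_prior("normal", mu, v))
  Ed <- elemental_info_uncertain(it, ability_prior("draws", draws = draws))
  # batch the draws to get an MC s.e. per entry
  batches <- lapply(split(draws, rep(1:10, each = 1e4)), function(b)
    elemental_info_uncertain(it, ability_prior("draws", draws = b)))
  for (idx in list(c(1, 1), c(1, 2), c(2, 2))) {
    bs <- vapply(batches, function(B) B[idx[1], idx[2]], numeric(1))
    se <- stats::sd(bs) / sqrt(10)
    expect_lt(abs(Eq[idx[1], idx[2]] - Ed[idx[1], idx[2]]), 3 * se + 1e-6)
  }
})

test_that("sample-based assembly approaches the known-ability grid limit", {
  bank <- item_bank(list(irt_item(1, -1)))
  N <- 2001
  th <- seq(-6, 6, length.out = N)
  draws <- lapply(th, function(t) ability_prior("draws", draws = t))
  grid <- build_grid(step = 0.05)
  d <- random_design(1, grid)
  Ms <- assemble_from_sample(bank, d, th, draws)
  Mk <- assemble_from_grid(bank, d, grid, uncertainty_model("known"))
  expect_lt(max(abs(Ms$blocks[[1]] / Mk$blocks[[1]] - 1)), 0.02)
  # input order is irrelevant: estimates are sorted internally
  perm <- sample(N)
  Mp <- assemble_from_sample(bank, d, th[perm], draws[perm])
  expect_equal(Mp$blocks[[1]], Ms$blocks[[1]], tolerance = 1e-12)
})

test_that("draw count barely changes the assembled information", {
  bank <- item_bank(list(irt_item(1, -1)))
  grid <- build_grid(step = 0.1)
  d <- random_design(1, grid)
  set.seed(51)
  N <- 200
  th <- sort(rnorm(N))
  make_sets <- function(S) lapply(th, function(t)
    ability_prior("draws", draws = rnorm(S, t, 0.3)))
  M100 <- assemble_from_sample(bank, d, th, make_sets(100))
  M1000 <- assemble_from_sample(bank, d, th, make_sets(1000))
  expect_lt(max(abs(M100$blocks[[1]] - M1000$blocks[[1]])), 0.05)
})

test_that("block info JSON serialization round-trips", {
  M <- block_info(list(matrix(c(.2, -.1, -.1, .3), 2, 2),
                       matrix(c(.4, .05, .05, .1), 2, 2)))
  f <- withr::local_tempfile(fileext = ".json")
  write_block_info(M, f)
  M2 <- read_block_info(f)
  expect_equal(M2$blocks, M$blocks)
  expect_equal(M2$items, M$items)
})
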
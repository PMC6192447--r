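test_that("BRS scoring reverses even items and averages", {
  expect_equal(score_brs(c(5, 1, 5, 1, 5, 1)), 5.0)
  expect_equal(score_brs(c(3, 3, 3, 3, 3, 3)), 3.0)
  expect_equal(score_brs(c(4, 2, 5, 1, 3, 2)), 25 / 6)
  # matrix input
  M <- rbind(c(5, 1, 5, 1, 5, 1), c(1, 5, 1, 5, 1, 5))
  expect_equal(score_brs(M), c(5, 1))
  # double reversal restores the raw responses
  x <- c(4, 2, 5, 1, 3, 2)
  rev2 <- x; rev2[c(2, 4, 6)] <- 6 - (6 - rev2[c(2, 4, 6)])
  expect_identical(rev2, x)
  expect_error(score_brs(1:5), "6 items")
  expect_error(score_brs(c(0, 1, 2, 3, 4, 5)), "1..5")
})

test_that("BRS missing-item proration follows the half-scale rule", {
  expect_equal(score_brs(c(5, NA, 5, NA, 5, NA)), 5)       # 3 of 6 present
  expect_true(is.na(score_brs(c(5, NA, NA, NA, 5, NA))))   # 2 of 6 present
})

test_that("CISS subscale sums and proration", {
  expect_equal(unname(score_ciss(rep(1, 48))), c(16, 16, 16))
  expect_equal(unname(score_ciss(rep(5, 48))), c(80, 80, 80))
  x <- c(rep(3, 16), rep(1, 32))
  expect_equal(unname(score_ciss(x)), c(48, 16, 16))
  # custom map moves the high block
  map <- setNames(rep(c("AoC", "EoC", "ToC"), each = 16), sprintf("item%02d", 1:48))
  expect_equal(unname(score_ciss(x, map)), c(16, 16, 48))
  # proration: half of ToC items missing
  y <- c(rep(4, 8), rep(NA, 8), rep(1, 32))
  expect_equal(unname(score_ciss(y)), c(64, 16, 16))
  y2 <- c(rep(4, 7), rep(NA, 9), rep(1, 32))
  expect_true(is.na(score_ciss(y2)[["ToC"]]))
  expect_error(score_ciss(rep(1, 47)), "48 items")
  expect_error(score_ciss(rep(1, 48), map = rep("ToC", 48)), "16 items")
})

test_that("adjusted Pearson correlation matches a normal-equations oracle", {
  set.seed(60)
  n <- 50
  age <- runif(n, 18, 90); sex <- rbinom(n, 1, 0.5)
  x <- 0.03 * age + 0.5 * sex + rnorm(n)
  y <- -0.02 * age + 0.8 * sex + 0.4 * x + rnorm(n)
  covars <- cbind(age = age, sex = sex)
  ap <- adjusted_pearson(x, y, covars)
  # explicit normal-equations two-stage residualization
  Z <- cbind(1, age, sex)
  bx <- solve(t(Z) %*% Z, t(Z) %*% x); rx <- x - Z %*% bx
  by <- solve(t(Z) %*% Z, t(Z) %*% y); ry <- y - Z %*% by
  r_o <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  expect_equal(ap$r, drop(r_o), tolerance = 1e-10)
  expect_equal(ap$se, sqrt((1 - r_o^2) / (n - 2 - 2)), tolerance = 1e-10)
  # symmetry and no-covariate reduction to plain Pearson
  expect_equal(adjusted_pearson(y, x, covars)$r, ap$r)
  expect_equal(adjusted_pearson(x, y)$r, cor(x, y))
  expect_equal(adjusted_pearson(x, x)$r, 1)
  expect_equal(adjusted_pearson(x, -x)$r, -1)
  expect_error(adjusted_pearson(x, rep(1, n)), "zero residual")
})

test_that("item simulation keying: BRS recovers the latent order", {
  set.seed(1)
  lat <- data.frame(id = 1:500, resilience = rnorm(500))
  items0 <- simulate_items(lat, "BRS", item_noise = 1e-8, seed = 1)
  sc <- score_brs(items0[, -1])
  # zero-noise items are a monotone (step) transform of the latent score
  expect_true(all(diff(sc[order(lat$resilience)]) >= 0))
  expect_gt(cor(sc, lat$resilience, method = "spearman"), 0.93)
  # latent far above the top threshold: odd items 5, even items 1, score 5
  lat2 <- data.frame(id = 1:11, resilience = c(rnorm(10), 100))
  it2 <- simulate_items(lat2, "BRS", item_noise = 1e-8, seed = 2)
  expect_equal(unlist(it2[11, 1 + c(1, 3, 5)], use.names = FALSE), rep(5L, 3))
  expect_equal(unlist(it2[11, 1 + c(2, 4, 6)], use.names = FALSE), rep(1L, 3))
  expect_equal(score_brs(it2[11, -1]), 5.0)
})

test_that("default item noise yields BRS alpha in the instrument's published band", {
  lat <- data.frame(id = 1:1000, resilience = rnorm(1000))
  items <- simulate_items(lat, "BRS", seed = 3)
  keyed <- as.matrix(items[, -1])
  keyed[, c(2, 4, 6)] <- 6 - keyed[, c(2, 4, 6)]
  a <- cronbach_alpha(keyed)
  expect_gt(a, 0.80)
  expect_lt(a, 0.91)
  # scored traits track the latent scores closely
  expect_gt(cor(score_brs(items[, -1]), lat$resilience, method = "spearman"), 0.9)
})

test_that("CISS items are emitted in three blocks driven by the right latents", {
  set.seed(4)
  lat <- data.frame(id = 1:800, ToC = rnorm(800), EoC = rnorm(800), AoC = rnorm(800))
  items <- simulate_items(lat, "CISS", seed = 5)
  expect_equal(ncol(items), 49L)
  sc <- score_ciss(items[, -1])
  for (tr in c("ToC", "EoC", "AoC")) {
    expect_gt(cor(sc[[tr]], lat[[tr]], method = "spearman"), 0.9)
    others <- setdiff(c("ToC", "EoC", "AoC"), tr)
    for (o in others) expect_lt(abs(cor(sc[[tr]], lat[[o]])), 0.15)
  }
  expect_error(simulate_items(lat, "GRIT"), "arg")
})
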
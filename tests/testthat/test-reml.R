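make_block_matrix <- function(groups) {
  M <- outer(groups, groups, "==") * 1
  dimnames(M) <- list(seq_along(groups), seq_along(groups))
  M
}

test_that("with no random components the residual equals the OLS estimate", {
  set.seed(90)
  n <- 80
  X <- cbind(age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  y <- 1 + 0.02 * X[, 1] + rnorm(n)
  fit <- reml_fit(y, X, list())
  ols <- lm(y ~ X)
  expect_equal(unname(fit$vcs[["residual"]]), sum(ols$residuals^2) / (n - 3),
               tolerance = 1e-12)
  expect_error(reml_fit(y, cbind(X, X[, 1]), list()), "singular")
})

test_that("an identity component is flagged as unidentifiable against the residual", {
  set.seed(91)
  n <- 60
  y <- rnorm(n)
  I_mat <- diag(n); dimnames(I_mat) <- list(1:n, 1:n)
  expect_warning(reml_fit(y, NULL, list(Z = I_mat), ids = as.character(1:n)),
                 "identifiable")
})

test_that("balanced full-sib REML reproduces the one-way ANOVA closed form to 1e-6", {
  set.seed(92)
  ns <- 500; k <- 2; n <- ns * k
  fam <- rep(seq_len(ns), each = k)
  y <- rnorm(ns, sd = sqrt(0.35))[fam] + rnorm(n, sd = sqrt(0.65))
  S <- make_block_matrix(fam)
  fit <- reml_fit(y, NULL, list(S = S), ids = as.character(1:n), tol = 1e-10)
  msb <- sum((tapply(y, fam, mean) - mean(y))^2 * k) / (ns - 1)
  msw <- sum((y - ave(y, fam))^2) / (n - ns)
  expect_equal(unname(fit$vcs[["S"]]), (msb - msw) / k, tolerance = 1e-6)
  expect_equal(unname(fit$vcs[["residual"]]), msw, tolerance = 1e-6)
})

test_that("AI-REML matches a dense grid search of the restricted likelihood", {
  set.seed(93)
  worst <- 0
  for (case in 1:4) {
    n <- 60
    sib <- make_block_matrix(rep(1:(n / 2), each = 2))
    grp <- make_block_matrix(rep(1:(n / 5), each = 5))
    truef <- list(c(0.5, 0.3), c(0.2, 0.5), c(0.6, 0), c(0, 0.4))[[case]]
    y <- sqrt(truef[1]) * rnorm(n / 2)[rep(1:(n / 2), each = 2)] +
      sqrt(truef[2]) * rnorm(n / 5)[rep(1:(n / 5), each = 5)] +
      sqrt(max(1 - sum(truef), 0.05)) * rnorm(n)
    X <- cbind(rnorm(n))
    fit <- reml_fit(y, X, list(A = sib, B = grp), ids = as.character(1:n), tol = 1e-9)
    gr <- grid_reml_oracle(y, X, list(sib, grp), step = 0.01)
    expect_gte(fit$logL, gr$logL - 1e-4)   # REML at least as good as any grid point
    d <- max(abs(fit$fractions[1:2] - gr$fractions))
    worst <- max(worst, d)
    expect_lte(d, 0.011)
  }
  # single-component instances
  for (case in 1:2) {
    n <- 50
    sib <- make_block_matrix(rep(1:(n / 2), each = 2))
    y <- sqrt(0.4) * rnorm(n / 2)[rep(1:(n / 2), each = 2)] + sqrt(0.6) * rnorm(n)
    fit <- reml_fit(y, NULL, list(A = sib), ids = as.character(1:n), tol = 1e-9)
    gr <- grid_reml_oracle(y, NULL, list(sib), step = 0.01)
    expect_gte(fit$logL, gr$logL - 1e-4)
    expect_lte(abs(fit$fractions[[1]] - gr$fractions[1]), 0.011)
  }
})

test_that("restricted likelihood is monotone over nested models", {
  ch <- small_cohort()
  sp <- variance_spec(h2_g = 0.2, e2_c = 0.2)
  ph <- simulate_phenotypes(ch$ped, ch$geno, sp, seed = 12)
  y <- setNames(ph$trait, ph$id)
  X <- cbind(age = ph$age, sex = ph$sex)
  mats <- list(G = ch$G, S = ch$Sm, C = ch$Cm)
  f3 <- reml_fit(y, X, mats)
  f2 <- reml_fit(y, X, mats[c("G", "C")])
  f1 <- reml_fit(y, X, mats["C"])
  f0 <- reml_fit(y, X, list())
  expect_gte(f3$logL, f2$logL - 1e-3)
  expect_gte(f2$logL, f1$logL - 1e-3)
  expect_gte(f1$logL, f0$logL - 1e-3)
  # fraction invariants
  for (f in list(f3, f2, f1)) {
    expect_true(all(f$fractions >= 0))
    expect_lte(sum(f$fractions), 1 + 1e-6)
    expect_equal(unname(f$fractions[["residual"]]),
                 1 - sum(f$fractions[setdiff(names(f$fractions), "residual")]),
                 tolerance = 1e-8)
  }
})

test_that("REML estimates are invariant to a simultaneous permutation of individuals", {
  set.seed(94)
  n <- 120
  fam <- rep(1:(n / 3), each = 3)
  S <- make_block_matrix(fam)
  y <- rnorm(n / 3, sd = 0.6)[fam] + rnorm(n, sd = 0.8)
  X <- cbind(runif(n))
  f1 <- reml_fit(y, X, list(S = S), ids = as.character(1:n), tol = 1e-8)
  p <- sample(n)
  Sp <- S[p, p]; dimnames(Sp) <- list(as.character(1:n), as.character(1:n))
  f2 <- reml_fit(y[p], X[p, , drop = FALSE], list(S = Sp),
                 ids = as.character(1:n), tol = 1e-8)
  expect_equal(f2$fractions, f1$fractions, tolerance = 1e-6)
  expect_equal(f2$logL, f1$logL, tolerance = 1e-6)
})

test_that("matrix/trait misalignment raises an alignment error", {
  ch <- small_cohort()
  y <- rnorm(10)
  names(y) <- paste0("zz", 1:10)
  expect_error(reml_fit(y, NULL, list(G = ch$G)), "missing individuals")
})

test_that("boundary LRT: statistic, mixture p-value, nesting checks", {
  f_full <- structure(list(logL = -100, components = c("G", "S")), class = "reml_fit")
  f_red <- structure(list(logL = -100, components = "G"), class = "reml_fit")
  l0 <- lrt_component(f_full, f_red)
  expect_equal(l0$statistic, 0)
  expect_equal(l0$p, 0.5)
  f_red2 <- structure(list(logL = -101.92, components = "G"), class = "reml_fit")
  l1 <- lrt_component(f_full, f_red2)
  expect_equal(l1$statistic, 3.84)
  expect_equal(l1$p, 0.5 * pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(l1$p, 0.025, tolerance = 1e-3)
  # higher reduced logL than full -> statistic clipped at 0
  f_red3 <- structure(list(logL = -99.9, components = "G"), class = "reml_fit")
  expect_equal(lrt_component(f_full, f_red3)$statistic, 0)
  expect_error(lrt_component(f_full, structure(list(logL = 0, components = "Z"),
                                               class = "reml_fit")), "nested")
  expect_error(lrt_component(f_full, structure(list(logL = 0, components = character(0)),
                                               class = "reml_fit")), "exactly one")
})

test_that("backward selection trace shrinks strictly and respects alpha", {
  ch <- small_cohort()
  sp <- variance_spec(e2_c = 0.35)
  ph <- simulate_phenotypes(ch$ped, ch$geno, sp, seed = 13)
  y <- setNames(ph$trait, ph$id)
  X <- cbind(age = ph$age, sex = ph$sex)
  mats <- list(G = ch$G, K = ch$K, F = ch$Fm, S = ch$Sm, C = ch$Cm)
  sel <- backward_select(y, X, mats)
  expect_lte(length(sel$trace), 5L)
  sizes <- vapply(sel$trace, function(r) length(r$components), 0L)
  expect_true(all(diff(sizes) < 0))
  # every retained component significant in the final round
  last <- sel$trace[[length(sel$trace)]]
  if (length(sel$components)) expect_true(all(last$p[sel$components] < 0.05))
  # the strong couple effect must survive
  expect_true("C" %in% sel$components)
})

test_that("report table formats fractions with significance stars", {
  expect_equal(nrow(report_table(list())), 0L)
  f <- structure(list(fractions = c(G = 0.14, residual = 0.86),
                      se = c(G = 0.03, residual = 0.05),
                      components = "G", n_used = 100L, logL = -1),
                 class = "reml_fit")
  tab <- report_table(list(m1 = f), p_values = list(m1 = c(G = 0.01)))
  expect_equal(tab$G[1], "0.14 (0.03)*")
  expect_equal(tab$residual[1], "0.86 (0.05)")
  expect_true(is.na(tab$K[1]))
})
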
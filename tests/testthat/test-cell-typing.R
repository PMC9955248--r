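test_that("population distribution counts cell states", {
  tis <- build_tissue(toy2, 3, 3, r = 1, seed = 1)
  tis$X[] <- 1L                       # all cells in state (1,1) -> s = 4
  G <- population_distribution(tis)
  expect_equal(G, c(0, 0, 0, 1))
  tis$X[1:4, ] <- 0L                  # 4 cells at s = 1, 5 at s = 4
  expect_equal(population_distribution(tis), c(4 / 9, 0, 0, 5 / 9))
  expect_equal(sum(population_distribution(tis)), 1)
})

test_that("constrained LS recovers exact mixtures with zero error", {
  basis <- c(list(g0 = model6$g0), model6$pinned_r1)
  G <- 0.3 * basis$g1 + 0.7 * basis$g2
  fit <- fit_mixture_ls(G, basis)
  expect_equal(unname(fit$weights), c(0, 0.3, 0.7), tolerance = 1e-9)
  expect_lt(fit$epsilon, 1e-12)

  fit0 <- fit_mixture_ls(model6$g0, basis)
  expect_equal(unname(fit0$weights["g0"]), 1, tolerance = 1e-9)
  expect_lt(fit0$epsilon, 1e-12)

  expect_error(fit_mixture_ls(G, list()), "at least one")
})

test_that("constrained LS matches a 0.01-step grid search on the simplex", {
  basis2 <- model6$pinned_r1
  basis3 <- c(list(g0 = model6$g0), model6$pinned_r1)
  B2 <- do.call(cbind, basis2)
  B3 <- do.call(cbind, basis3)
  set.seed(31)
  for (rep in 1:5) {
    G <- random_simplex(64)
    # 2-component grid
    c1 <- seq(0, 1, by = 0.01)
    obj2 <- vapply(c1, function(a)
      sqrt(sum((G - B2 %*% c(a, 1 - a))^2)), numeric(1))
    fit2 <- fit_mixture_ls(G, basis2)
    expect_lte(fit2$objective, min(obj2) + 1e-10)
    # 3-component grid
    grid <- expand.grid(a = c1, b = c1)
    grid <- grid[grid$a + grid$b <= 1 + 1e-12, ]
    obj3 <- apply(grid, 1, function(ab)
      sqrt(sum((G - B3 %*% c(ab[1], ab[2], 1 - ab[1] - ab[2]))^2)))
    fit3 <- fit_mixture_ls(G, basis3)
    expect_lte(fit3$objective, min(obj3) + 1e-10)
    # simplex constraints hold exactly
    for (fit in list(fit2, fit3)) {
      expect_true(all(fit$weights >= 0 & fit$weights <= 1))
      expect_lt(abs(sum(fit$weights) - 1), 1e-12)
    }
  }
})

test_that("spectral weights equal LS weights on orthogonal exact mixtures", {
  basis <- model6$pinned_r1
  G <- 0.5 * basis$g1 + 0.5 * basis$g2
  sw <- spectral_weights(G, basis)
  expect_equal(unname(sw$weights), c(0.5, 0.5), tolerance = 1e-9)

  pure <- spectral_weights(basis$g2, basis)
  expect_equal(unname(pure$weights), c(0, 1), tolerance = 1e-9)

  set.seed(41)
  for (rep in 1:10) {
    a <- runif(1)
    G <- a * basis$g1 + (1 - a) * basis$g2
    sw <- spectral_weights(G, basis)$weights
    lw <- fit_mixture_ls(G, basis)$weights
    expect_lt(max(abs(sw - lw)), 1e-6)
  }
  # four-component basis as well
  basis4 <- model6$pinned_r2
  a4 <- random_simplex(4)
  G4 <- as.numeric(do.call(cbind, basis4) %*% a4)
  expect_equal(unname(spectral_weights(G4, basis4)$weights), a4,
               tolerance = 1e-9)

  expect_error(spectral_weights(G, list(model6$g0, basis$g1)),
               "not orthogonal")
})

test_that("magnetization is the cell-type fraction difference c2 - c1", {
  expect_equal(magnetization(c(g1 = 0, g2 = 1)), 1)
  expect_equal(magnetization(c(g1 = 1, g2 = 0)), -1)
  expect_equal(magnetization(c(g0 = 0, g1 = 0.5, g2 = 0.5)), 0)
  fit <- fit_mixture_ls(model6$pinned_r1$g2,
                        c(list(g0 = model6$g0), model6$pinned_r1))
  expect_equal(magnetization(fit), 1, tolerance = 1e-9)
  expect_error(magnetization(c(g1 = 0.2, g2 = 0.3, g3 = 0.25, g4 = 0.25)),
               "r = 1")
})

test_that("NNMF factorizes population histories into non-negative types", {
  basis <- model6$pinned_r1
  # rank-1: identical columns recover the single component
  G1 <- matrix(rep(basis$g1, 20), ncol = 20)
  r1 <- nnmf_decompose(G1, 1, seed = 5)
  expect_lt(max(abs(r1$Omega[, 1] - basis$g1)), 1e-6)

  # rank-2 mixtures of disjoint-support components, recovered up to permutation
  set.seed(6)
  mix <- vapply(1:40, function(i) {
    a <- runif(1, 0.05, 0.95)
    a * basis$g1 + (1 - a) * basis$g2
  }, numeric(64))
  r2 <- nnmf_decompose(mix, 2, seed = 7)
  expect_true(all(r2$Omega >= 0) && all(r2$E >= 0))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- sapply(list(basis$g1, basis$g2), function(g)
    max(cosine(r2$Omega[, 1], g), cosine(r2$Omega[, 2], g)))
  expect_true(all(sims >= 0.99))

  expect_error(nnmf_decompose(mix, 50, seed = 1), "min")
})
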
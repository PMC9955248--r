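test_that("RBN generation is reproducible, validated, and respects the bias", {
  a <- generate_rbn(6, 2, 0.5, seed = 11)
  b <- generate_rbn(6, 2, 0.5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_rbn(6, 2, 0.5, seed = 12)))

  all1 <- generate_rbn(6, 2, 1.0, seed = 5)
  expect_true(all(unlist(all1$truth_tables) == 1L))

  expect_error(generate_rbn(4, 5, 0.5, seed = 1), "1 <= k <= n")

  # over many seeds, table entries are Bernoulli(p = 0.5)
  ones <- vapply(seq_len(1000), function(s)
    sum(unlist(generate_rbn(6, 2, 0.5, seed = 1000 + s)$truth_tables)),
    numeric(1))
  m <- 1000 * 6 * 4
  frac <- sum(ones) / m
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / m))

  # each node has distinct inputs in range
  expect_true(all(vapply(a$inputs, function(j)
    length(unique(j)) == 2L && all(j >= 1 & j <= 6), logical(1))))
})

test_that("critical connectivity follows k_c = 1/(2p(1-p))", {
  expect_equal(critical_connectivity(0.5), 2.0)
  expect_equal(critical_connectivity(0.1), 1 / 0.18)
  expect_equal(critical_connectivity(0.3), critical_connectivity(0.7))
  expect_error(critical_connectivity(0), "undefined")
  expect_error(critical_connectivity(1), "undefined")
})

test_that("state encoding is the big-endian bijection on S = {1..2^n}", {
  expect_identical(encode_state(c(0, 0)), 1L)
  expect_identical(encode_state(c(1, 0)), 3L)
  for (n in c(3L, 6L, 10L)) {
    for (s in seq_len(2^n)) {
      expect_identical(encode_state(decode_state(s, n)), s)
    }
  }
})

test_that("synchronous update evaluates truth tables from the old state", {
  expect_identical(synchronous_update(toy2, c(1L, 0L)), c(0L, 1L))
  expect_identical(synchronous_update(toy2, c(1L, 1L)), c(1L, 1L))
  expect_identical(synchronous_update(toy2, c(0L, 0L)), c(0L, 0L))
  expect_identical(synchronous_update(toy2, c(0L, 1L)), c(0L, 1L))
})

test_that("perturbed step replaces the whole vector at rate 1-(1-q)^n", {
  set.seed(1)
  # q = 0: always the deterministic update
  for (i in 1:20) {
    x <- sample(0:1, 2, replace = TRUE)
    expect_identical(as.integer(perturbed_step(toy2, x, 0)),
                     synchronous_update(toy2, x))
  }
  # q = 1: event probability 1 and gamma = all ones
  for (i in 1:20)
    expect_identical(as.integer(perturbed_step(toy2, c(0L, 0L), 1)), c(1L, 1L))

  # empirical event frequency for q = 0.1, n = 6
  net <- model6$net
  steps <- 1e5
  x <- rep(0L, 6)
  hits <- 0L
  for (t in seq_len(steps)) {
    x <- perturbed_step(net, x, 0.1)
    hits <- hits + attr(x, "perturbed")
  }
  p_event <- 1 - 0.9^6
  expect_lt(abs(hits / steps - p_event), 3 * sqrt(p_event * (1 - p_event) / steps))
})

test_that("transition matrix matches the enumerated chain on the toy network", {
  # q = 0: P = D, exactly one 1 per row
  P0 <- transition_matrix(toy2, 0)
  expect_true(all(rowSums(P0 == 1) == 1))
  expect_equal(rowSums(P0), rep(1, 4))

  # q = 0.5: rho = 0.75, gamma uniform; P = 0.25 D + 0.1875 * ones
  # D by direct truth-table evaluation of the 4 states
  D <- matrix(0, 4, 4)
  for (s in 1:4) {
    x <- c((s - 1) %/% 2, (s - 1) %% 2)
    xn <- c(x[1] & x[2], x[1] | x[2])
    D[s, 1 + 2 * xn[1] + xn[2]] <- 1
  }
  expect_equal(transition_matrix(toy2, 0.5), 0.25 * D + 0.1875, tolerance = 1e-14)

  # rows sum to 1 for random networks
  for (s in 1:5) {
    P <- transition_matrix(generate_rbn(5, 2, 0.5, seed = s), 0.2)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }

  expect_error(transition_matrix(generate_rbn(13, 2, 0.5, seed = 1), 0.1),
               "dense")
})

test_that("stationary distribution is the left fixed vector", {
  # uniform chain -> uniform stationary
  N <- 8
  expect_equal(stationary_distribution(matrix(1 / N, N, N)), rep(1 / N, N))

  # pure-perturbation chain (rho = 1): pi = product-Bernoulli(q) mass
  q <- 0.3
  gam <- c((1 - q)^2, (1 - q) * q, q * (1 - q), q^2)
  P <- matrix(gam, 4, 4, byrow = TRUE)
  expect_equal(stationary_distribution(P), gam, tolerance = 1e-12)

  # fixed-point residual for the model chain
  P6 <- transition_matrix(model6$net, 0.1)
  pi6 <- stationary_distribution(P6)
  expect_lt(max(abs(as.numeric(pi6 %*% P6) - pi6)), 1e-12)
  expect_true(all(pi6 > 0))  # ergodic for q in (0,1)
})

test_that("Monte Carlo histogram estimates the exact stationary vector", {
  g <- estimate_steady_state_mc(model6$net, 0.1, steps = 3e5, burn_in = 1000,
                                seed = 7)
  expect_equal(sum(g), 1)
  exact <- stationary_distribution(transition_matrix(model6$net, 0.1))
  expect_lt(tv_distance(g, exact), 0.05)

  # reproducibility
  g2 <- estimate_steady_state_mc(model6$net, 0.1, steps = 1e4, seed = 3)
  g3 <- estimate_steady_state_mc(model6$net, 0.1, steps = 1e4, seed = 3)
  expect_identical(g2, g3)

  # q = 0 from a fixed point: support is that attractor only
  h <- estimate_steady_state_mc(toy2, 0, steps = 500, x0 = c(1L, 1L))
  expect_equal(h[4], 1)
  expect_equal(sum(h[-4]), 0)
})
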
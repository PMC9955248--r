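test_that("the periodic lattice has 4 distinct symmetric neighbors per cell", {
  tis <- build_tissue(model6$net, 3, 3, r = 1, seed = 1)
  expect_error(build_tissue(model6$net, 2, 3, r = 1), ">= 3")
  L <- 9L
  for (i in seq_len(L)) {
    expect_length(unique(tis$nbr[i, ]), 4L)
    expect_false(i %in% tis$nbr[i, ])
    for (j in tis$nbr[i, ]) expect_true(i %in% tis$nbr[j, ])
  }
  # unordered bond count on a periodic square lattice is 2 L
  bonds <- unique(t(apply(cbind(rep(seq_len(L), 4), as.vector(tis$nbr)), 1, sort)))
  expect_identical(nrow(bonds), 2L * L)

  # pinned init sets the CK layer
  tp <- build_tissue(model6$net, 4, 4, r = 1, init = "pinned", w = 2, seed = 1)
  expect_true(all(tp$X[, 1] == 1L))
})

test_that("the Hamiltonian counts each bond once and all field terms", {
  tis <- build_tissue(model6$net, 3, 3, r = 1, seed = 1)
  tis$X[, 1] <- 1L
  p <- ising_params(J = 1, h0 = 0, h = 0, T = 1)
  expect_equal(hamiltonian(tis, p), -18)          # 18 bonds, all aligned
  tis2 <- tis
  tis2$X[5, 1] <- 0L
  expect_equal(hamiltonian(tis2, p), -10)         # 4 bonds flip sign
  pf <- ising_params(J = 0, h0 = 0, h = 1, psi = 1, T = 1)
  expect_equal(hamiltonian(tis, pf), -9)          # field term over 9 cells
  ph <- ising_params(J = 0, h0 = 1, h = 0, T = 1)
  expect_error(hamiltonian(tis, ph), "f_bar")
})

test_that("f_bar is the spin of the BN-predicted CK update", {
  tis <- build_tissue(toy2, 3, 3, r = 1, seed = 1)
  tis$X[1, ] <- c(1L, 1L)   # AND(1,1) = 1
  tis$X[2, ] <- c(1L, 0L)   # AND(1,0) = 0
  fb <- compute_f_bar(tis)
  expect_equal(fb[1, 1], 1)
  expect_equal(fb[2, 1], -1)
})

test_that("Metropolis acceptance follows min(1, exp(-dE/T))", {
  net <- model6$net
  # dE < 0 proposals are always accepted: one full sweep aligns all spins
  tis <- build_tissue(net, 8, 8, r = 1, init = "pinned", w = 1, seed = 1)
  p <- ising_params(J = 0, h0 = 0, h = 1, psi = 1, T = 0.5, n_mc = 64L)
  set.seed(1)
  up <- metropolis_sweep(tis, p)$tissue
  expect_true(all(up$X[, 1] == 1L))

  # dE = 2T is accepted with probability exp(-2)
  tis2 <- build_tissue(net, 32, 32, r = 1, init = "pinned", w = 2, seed = 1)
  p2 <- ising_params(J = 0, h0 = 0, h = 1, psi = 1, T = 1, n_mc = 1024L)
  set.seed(8)
  down <- metropolis_sweep(tis2, p2)$tissue
  frac <- mean(down$X[, 1] == 0L)
  pacc <- exp(-2)
  expect_lt(abs(frac - pacc), 3 * sqrt(pacc * (1 - pacc) / 1024))
})

test_that("accumulated dE matches the Hamiltonian difference", {
  tis <- build_tissue(model6$net, 4, 5, r = 2, seed = 3)
  p <- ising_params(J = 0.7, h0 = 0.9, h = 0.3, psi = c(1, -1), T = 1.2,
                    n_mc = 20L)
  fb <- compute_f_bar(tis)
  set.seed(5)
  H0 <- hamiltonian(tis, p, fb)
  res <- metropolis_sweep(tis, p, fb)
  H1 <- hamiltonian(res$tissue, p, fb)
  expect_lt(abs((H1 - H0) - res$dE), 1e-9)
})

test_that("flipping every CK spin leaves the h = h0 = 0 energy invariant", {
  tis <- build_tissue(model6$net, 4, 4, r = 1, seed = 6)
  p <- ising_params(J = 1, h0 = 0, h = 0, T = 1)
  H0 <- hamiltonian(tis, p)
  tis$X[, 1] <- 1L - tis$X[, 1]
  expect_equal(hamiltonian(tis, p), H0)
})

test_that("mc_step and the fast run loop are the same Markov chain", {
  tis <- build_tissue(model6$net, 4, 4, r = 2, seed = 10)
  p <- ising_params(J = 1, h0 = 0.5, h = 0, T = 1.3, n_mc = 5L)
  set.seed(77)
  t1 <- mc_step(tis, p, q = 0.1)
  set.seed(77)
  t2 <- run_tissue(tis, p, q = 0.1, steps = 1)$tissue
  expect_identical(t1$X, t2$X)
  # and over several chained steps
  set.seed(78)
  ta <- tis
  for (i in 1:5) ta <- mc_step(ta, p, q = 0.1)
  set.seed(78)
  tb <- run_tissue(tis, p, q = 0.1, steps = 5)$tissue
  expect_identical(ta$X, tb$X)
})

test_that("identical seeds give identical tissue trajectories", {
  tis <- build_tissue(model6$net, 5, 5, r = 1, seed = 2)
  p <- ising_params(J = 1, h0 = 0.3, h = 0, T = 2, n_mc = 10L)
  set.seed(42); r1 <- run_tissue(tis, p, q = 0.05, steps = 200)
  set.seed(42); r2 <- run_tissue(tis, p, q = 0.05, steps = 200)
  expect_identical(r1$tissue$X, r2$tissue$X)
  expect_identical(r1$M_spin, r2$M_spin)
})

test_that("sampled states obey the Boltzmann distribution on a 3x3 lattice", {
  # exact enumeration of the 512-state 3x3 Ising model (independent oracle)
  Lx <- 3; Ly <- 3; L <- 9; Tt <- 2.5
  nbr_right <- (0:8) %/% 3 * 3 + ((0:8) %% 3 + 1) %% 3 + 1
  nbr_down <- ((0:8) %/% 3 + 1) %% 3 * 3 + (0:8) %% 3 + 1
  conf_E <- conf_M <- numeric(512)
  for (c0 in 0:511) {
    s <- 2 * as.integer(intToBits(c0)[1:9]) - 1
    conf_E[c0 + 1] <- -sum(s * s[nbr_right] + s * s[nbr_down])
    conf_M[c0 + 1] <- sum(s)
  }
  wts <- exp(-conf_E / Tt); wts <- wts / sum(wts)
  m_levels <- seq(-9, 9, by = 2)
  pM_exact <- vapply(m_levels, function(m) sum(wts[conf_M == m]), numeric(1))

  tis <- build_tissue(model6$net, 3, 3, r = 1, seed = 1)
  p <- ising_params(J = 1, h0 = 0, h = 0, T = Tt, n_mc = 9L)
  set.seed(13)
  res <- run_tissue(tis, p, q = 0.1, steps = 4e4)
  emp <- res$M_spin[-(1:2000)] * 9
  pM_emp <- vapply(m_levels, function(m) mean(abs(emp - m) < 1e-9), numeric(1))
  expect_lt(0.5 * sum(abs(pM_emp - pM_exact)), 0.05)
})

test_that("h0-dominated tissues reproduce the uncoupled hybrid cell chain", {
  # J = 0, h >> 0 limit: with every cell proposed once per sweep, the CK
  # follows f_bar deterministically; each cell is then an independent chain
  # whose CK updates first and whose other genes read the new CK value.
  net <- model6$net
  q <- 0.1
  n <- 6; N <- 64
  # exact stationary distribution of that per-cell chain (oracle)
  rho <- 1 - (1 - q)^n
  P <- matrix(0, N, N)
  for (s in seq_len(N)) {
    x <- decode_state(s, n)
    ck <- synchronous_update(net, x)[1]
    xmid <- x; xmid[1] <- ck
    xo <- synchronous_update(net, xmid)[-1]
    det_t <- encode_state(c(ck, xo))
    for (g in 0:(2^5 - 1)) {
      bits <- as.integer(intToBits(g)[5:1])
      mass <- prod(ifelse(bits == 1, q, 1 - q))
      P[s, encode_state(c(ck, bits))] <- P[s, encode_state(c(ck, bits))] + rho * mass
    }
    P[s, det_t] <- P[s, det_t] + (1 - rho)
  }
  pi_exact <- stationary_distribution(P)

  tis <- build_tissue(net, 10, 10, r = 1, seed = 21)
  p <- ising_params(J = 0, h0 = 50, h = 0, T = 1, n_mc = 100L)
  set.seed(22)
  res <- run_tissue(tis, p, q = q, steps = 3000, record_G_every = 1L)
  G_avg <- rowMeans(res$G_hist[, -(1:500)])
  expect_lt(0.5 * sum(abs(G_avg - pi_exact)), 0.05)
})

test_that("annealing h0 down at subcritical T ends in a differentiated tissue", {
  basis <- c(list(g0 = model6$g0), model6$pinned_r1)
  tis <- build_tissue(model6$net, 6, 6, r = 1, seed = 30)
  p <- ising_params(J = 1, h0 = 3, h = 0, T = 1, n_mc = 36L)
  set.seed(30)
  an <- anneal_sweep(tis, p, q = 0.1, vary = "h0", values = c(3, 1.5, 0),
                     t_eq = 400, t_sample = 400, basis = basis)
  expect_identical(nrow(an$summary), 3L)
  wsums <- rowSums(an$summary[, c("g0", "g1", "g2")])
  expect_lt(max(abs(wsums - 1)), 1e-9)
  expect_lt(max(an$summary$epsilon), 1e-2)
  # at h0 = 0 and T < Tc the tissue sits in one pinned cell type
  wfin <- an$summary[3, c("g1", "g2")]
  expect_gt(max(wfin), 0.6)
  expect_gt(abs(an$summary$M_spin[3]), 0.9)

  # a length-1 schedule is a plain equilibrate-and-sample run
  an1 <- anneal_sweep(tis, p, q = 0.1, vary = "T", values = 1,
                      t_eq = 10, t_sample = 10, basis = basis)
  expect_identical(nrow(an1$summary), 1L)
})
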
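#' Construct a Boolean network
#'
#' A Boolean network over `n` binary genes.  Gene `i` reads the ordered input
#' set `inputs[[i]]` (indices into `1:n`) and updates synchronously through
#' its truth table: the input tuple `(x[j1], ..., x[jk])` is read as a
#' big-endian binary number, and entry `1 + sum(x[jl] * 2^(k-l))` of
#' `truth_tables[[i]]` is the new value of gene `i`.
#'
#' @param inputs list of integer vectors; `inputs[[i]]` are the regulators of
#'   gene `i`, in order.
#' @param truth_tables list of 0/1 vectors; `truth_tables[[i]]` has exactly
#'   `2^length(inputs[[i]])` entries.
#' @param p truth-table bias used to generate the network, if any.
#' @param seed generation seed, if any (kept for provenance; not used here).
#' @return an object of class `boolean_network` with fields `n`, `k`
#'   (uniform in-degree, `NA` if mixed), `p`, `inputs`, `truth_tables`,
#'   `seed`.
#' @export
boolean_network <- function(inputs, truth_tables, p = NA_real_, seed = NULL) {
  n <- length(inputs)
  if (n < 1L) stop("a Boolean network needs at least one gene")
  if (length(truth_tables) != n)
    stop("`inputs` and `truth_tables` must have one entry per gene")
  inputs <- lapply(inputs, function(j) as.integer(j))
  truth_tables <- lapply(truth_tables, function(f) as.integer(f))
  for (i in seq_len(n)) {
    ki <- length(inputs[[i]])
    if (ki < 1L) stop(sprintf("gene %d has no inputs", i))
    if (anyNA(inputs[[i]]) || any(inputs[[i]] < 1L) || any(inputs[[i]] > n))
      stop(sprintf("gene %d: input index out of range 1..%d", i, n))
    if (length(truth_tables[[i]]) != 2^ki)
      stop(sprintf("gene %d: truth table must have %d entries, got %d",
                   i, 2^ki, length(truth_tables[[i]])))
    if (!all(truth_tables[[i]] %in% c(0L, 1L)))
      stop(sprintf("gene %d: truth table entries must be 0 or 1", i))
  }
  ks <- lengths(inputs)
  structure(
    list(n = n, k = if (length(unique(ks)) == 1L) ks[[1L]] else NA_integer_,
         p = p, inputs = inputs, truth_tables = truth_tables,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: n = %d genes, in-degree k = %s, bias p = %s\n",
              x$n, ifelse(is.na(x$k), "mixed", x$k),
              ifelse(is.na(x$p), "unknown", format(x$p))))
  if (!is.null(x$seed)) cat(sprintf("  generated from seed %d\n", x$seed))
  invisible(x)
}

#' Generate a random Boolean network (RBN)
#'
#' Kauffman-ensemble RBN: every gene has `k` distinct regulators drawn
#' uniformly without replacement, and every truth-table entry is 1
#' independently with probability `p`.  The same `(n, k, p, seed)` reproduces
#' the identical network.
#'
#' @param n number of genes.
#' @param k in-degree (1 <= k <= n).
#' @param p truth-table bias in `[0, 1]`.
#' @param seed integer seed.
#' @return a [boolean_network()].
#' @export
generate_rbn <- function(n, k, p, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must satisfy 1 <= k <= n")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  local_seed(seed, {
    inputs <- lapply(seq_len(n), function(i) sample.int(n, k))
    tts <- lapply(seq_len(n), function(i) rbinom(2^k, 1L, p))
    boolean_network(inputs, tts, p = p, seed = seed)
  })
}

#' Critical connectivity of the RBN ensemble
#'
#' The order/chaos boundary of random Boolean networks lies at
#' `k_c = 1 / (2 p (1 - p))`.
#'
#' @param p truth-table bias, strictly inside `(0, 1)`.
#' @return the critical in-degree (a real number).
#' @export
critical_connectivity <- function(p) {
  if (any(p <= 0 | p >= 1))
    stop("critical connectivity is undefined at p = 0 or p = 1 (division by zero)")
  1 / (2 * p * (1 - p))
}

#' Encode / decode decimal network states
#'
#' States are indexed `s = 1 + sum_i x_i 2^(n-i)` with gene 1 the most
#' significant bit, so `S = {1, ..., 2^n}` and pinning gene 1 to 0/1 splits
#' `S` into its first and second half.
#'
#' @param x 0/1 vector of gene values.
#' @return `encode_state`: the decimal index in `1..2^n`.
#' @export
encode_state <- function(x) {
  n <- length(x)
  as.integer(1 + sum(x * 2^(n - seq_len(n))))
}

#' @rdname encode_state
#' @param s decimal state index in `1..2^n`.
#' @param n number of genes.
#' @return `decode_state`: the 0/1 gene vector of length `n`.
#' @export
decode_state <- function(s, n) {
  if (s < 1 || s > 2^n) stop("`s` out of range 1..2^n")
  v <- s - 1L
  as.integer(bitwAnd(bitwShiftR(v, n - seq_len(n)), 1L))
}

# All 2^n states as a (2^n) x n 0/1 matrix, row s = decode_state(s, n).
state_matrix <- function(n) {
  s <- 0:(2^n - 1)
  m <- matrix(0L, length(s), n)
  for (i in seq_len(n)) m[, i] <- bitwAnd(bitwShiftR(s, n - i), 1L)
  m
}

tt_index <- function(xj) {
  k <- length(xj)
  1L + as.integer(sum(xj * 2^(k - seq_len(k))))
}

#' Synchronous deterministic update
#'
#' One fully synchronous step: every gene reads its inputs from the old state
#' and takes the value of its truth table.
#'
#' @param net a [boolean_network()].
#' @param x 0/1 state vector of length `net$n`.
#' @return the updated 0/1 state vector.
#' @export
synchronous_update <- function(net, x) {
  if (length(x) != net$n || !all(x %in% c(0L, 1L)))
    stop("`x` must be a 0/1 vector of length n")
  vapply(seq_len(net$n), function(i) {
    net$truth_tables[[i]][tt_index(x[net$inputs[[i]]])]
  }, integer(1))
}

#' One noisy (perturbed) update step
#'
#' With probability `1 - (1-q)^n` the whole gene vector is replaced by a
#' random binary vector with i.i.d. Bernoulli(`q`) entries (gene-expression
#' noise); otherwise the deterministic synchronous update is applied.  The
#' returned state carries a logical attribute `"perturbed"` recording which
#' branch fired, so perturbation-event counts are auditable.
#'
#' @inheritParams synchronous_update
#' @param q per-gene activation probability of the perturbation vector.
#' @return the new 0/1 state vector, with attribute `"perturbed"`.
#' @export
perturbed_step <- function(net, x, q) {
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
  rho <- 1 - (1 - q)^net$n
  if (rho > 0 && runif(1) < rho) {
    out <- as.integer(runif(net$n) < q)
    attr(out, "perturbed") <- TRUE
  } else {
    out <- synchronous_update(net, x)
    attr(out, "perturbed") <- FALSE
  }
  out
}

# Deterministic next-state map over decimal states (1-based), optionally with
# the first r genes pinned to the bits of X_w (w in 1..2^r).  Vectorized over
# the full state space; used by the exact chain and the fast simulators.
det_state_map <- function(net, r = 0L, w = 0L) {
  n <- net$n
  if (n > 20L) stop("state-space enumeration limited to n <= 20")
  X <- state_matrix(n)
  pin_bits <- if (r > 0L && w > 0L) pin_values(r, w) else NULL
  snew <- rep(0, nrow(X))
  for (i in seq_len(n)) {
    if (i <= r && w > 0L) {
      bit <- rep(pin_bits[i], nrow(X))
    } else {
      Ji <- net$inputs[[i]]
      k <- length(Ji)
      idx <- rep(1L, nrow(X))
      for (l in seq_len(k)) idx <- idx + X[, Ji[l]] * 2L^(k - l)
      bit <- net$truth_tables[[i]][idx]
    }
    snew <- snew * 2 + bit
  }
  as.integer(snew) + 1L
}

# Product-Bernoulli(q) mass of each decimal state; pinned CK bits (when
# w > 0) carry an indicator on matching X_w instead.
gamma_mass <- function(n, q, r = 0L, w = 0L) {
  X <- state_matrix(n)
  pin_bits <- if (r > 0L && w > 0L) pin_values(r, w) else NULL
  g <- rep(1, nrow(X))
  for (i in seq_len(n)) {
    b <- X[, i]
    if (i <= r && w > 0L) g <- g * (b == pin_bits[i])
    else g <- g * (b * q + (1 - b) * (1 - q))
  }
  g
}

#' Exact transition matrix of the noisy Boolean chain
#'
#' Builds the row-stochastic matrix `P = (1-rho) D + rho 1 gamma^T` over the
#' decimal state space, where `rho = 1 - (1-q)^n`, `D` is the 0/1
#' deterministic-update matrix and `gamma` is the product-Bernoulli(`q`) mass
#' of the target state.  With `r > 0` and `w in 1..2^r` the first `r` genes
#' are pinned to `X_w`: the deterministic part holds them fixed and the
#' perturbation vector covers the free genes only, so every row of `P` targets
#' the `X_w` block.
#'
#' @inheritParams perturbed_step
#' @param r control-kernel size (0 for the unpinned chain).
#' @param w pin index in `1..2^r` (ignored when `r = 0`).
#' @return a dense `2^n` x `2^n` row-stochastic matrix.
#' @export
transition_matrix <- function(net, q, r = 0L, w = 0L) {
  n <- net$n
  if (n > 12L)
    stop(sprintf(paste0("transition_matrix: 2^%d states cannot be held as a ",
                        "dense chain; use estimate_steady_state_mc()"), n))
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
  N <- 2L^n
  dmap <- det_state_map(net, r, w)
  rho <- 1 - (1 - q)^n
  g <- gamma_mass(n, q, r, w)
  P <- matrix(rho * g, N, N, byrow = TRUE)
  ij <- cbind(seq_len(N), dmap)
  P[ij] <- P[ij] + (1 - rho)
  P
}

#' Stationary distribution of an ergodic chain
#'
#' Power iteration for the unique left fixed vector `pi P = pi`, `pi >= 0`,
#' `sum(pi) = 1`.
#'
#' @param P row-stochastic matrix.
#' @param tol convergence tolerance on `max |pi P - pi|`.
#' @param max_iter iteration cap.
#' @return the stationary probability vector.
#' @export
stationary_distribution <- function(P, tol = 1e-12, max_iter = 1e6) {
  N <- nrow(P)
  if (ncol(P) != N) stop("`P` must be square")
  if (max(abs(rowSums(P) - 1)) > 1e-9) stop("`P` must be row-stochastic")
  pi0 <- rep(1 / N, N)
  for (it in seq_len(max_iter)) {
    pi1 <- as.numeric(pi0 %*% P)
    if (max(abs(pi1 - pi0)) <= tol) return(pi1 / sum(pi1))
    pi0 <- pi1
  }
  stop(sprintf("power iteration did not converge: residual %.3e after %d iterations",
               max(abs(as.numeric(pi0 %*% P) - pi0)), as.integer(max_iter)))
}

#' Monte Carlo estimate of the steady-state distribution
#'
#' Simulates the noisy chain on decimal states (via a precomputed
#' deterministic next-state map) and returns the normalized visit histogram
#' after discarding `burn_in` steps.
#'
#' @inheritParams transition_matrix
#' @param steps number of recorded steps.
#' @param burn_in steps discarded before recording.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param x0 initial 0/1 state (default: all zeros).
#' @return a probability vector over `1..2^n` summing exactly to 1.
#' @export
estimate_steady_state_mc <- function(net, q, steps, burn_in = 0L, seed = NULL,
                                     x0 = NULL) {
  if (steps <= 0) stop("`steps` must be positive")
  dmap <- det_state_map(net)
  s0 <- if (is.null(x0)) 0L else encode_state(x0) - 1L
  h <- local_seed(seed,
    cpp_bn_chain(dmap - 1L, net$n, 0L, -1L, q, as.integer(steps),
                 as.integer(burn_in), s0))
  h / sum(h)
}
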
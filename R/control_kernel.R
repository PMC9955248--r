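#' Pin values of a control kernel
#'
#' The control kernel (CK) is, by convention, the first `r` genes.  Pin index
#' `w` in `1..2^r` decodes `w - 1` as an `r`-bit big-endian string: `X_1` is
#' all zeros, `X_{2^r}` all ones.
#'
#' @param r control-kernel size.
#' @param w pin index in `1..2^r` (`w = 0` means unpinned and returns NULL).
#' @return integer 0/1 vector of length `r`, or NULL for `w = 0`.
#' @export
pin_values <- function(r, w) {
  r <- as.integer(r); w <- as.integer(w)
  if (r < 1L) stop("`r` must be >= 1")
  if (w == 0L) return(NULL)
  if (w < 0L || w > 2L^r) stop(sprintf("`w` must lie in {0, 1, ..., %d}", 2L^r))
  v <- w - 1L
  as.integer(bitwAnd(bitwShiftR(v, r - seq_len(r)), 1L))
}

#' Pin a control kernel
#'
#' Returns the pinned dynamics: CK genes held at `X_w` every step while the
#' remaining genes follow the synchronous update; `w = 0` leaves the network
#' unpinned.  Perturbation noise, when enabled, applies to non-CK genes only
#' while pinned (pins are absolute).
#'
#' @param net a [boolean_network()].
#' @param r control-kernel size (`1 <= r <= n`).
#' @param w pin index in `{0} U {1..2^r}`.
#' @return an object of class `pinned_bn`.
#' @export
pin <- function(net, r, w) {
  r <- as.integer(r); w <- as.integer(w)
  if (r < 1L || r > net$n) stop("`r` must satisfy 1 <= r <= n")
  if (w < 0L || w > 2L^r) stop(sprintf("`w` must lie in {0, 1, ..., %d}", 2L^r))
  structure(list(net = net, r = r, w = w), class = "pinned_bn")
}

#' @export
print.pinned_bn <- function(x, ...) {
  if (x$w == 0L) {
    cat(sprintf("Unpinned dynamics (w = 0) of an n = %d network\n", x$net$n))
  } else {
    cat(sprintf("Pinned dynamics: CK = genes 1..%d held at X_%d = (%s)\n",
                x$r, x$w, paste(pin_values(x$r, x$w), collapse = ",")))
  }
  invisible(x)
}

#' One step of pinned dynamics
#'
#' @param pnet a [pin()]ned network.
#' @param x current 0/1 state.
#' @param q perturbation parameter (0 disables noise).
#' @return the new 0/1 state.
#' @export
pinned_step <- function(pnet, x, q = 0) {
  net <- pnet$net
  if (pnet$w == 0L) {
    out <- if (q > 0) perturbed_step(net, x, q) else synchronous_update(net, x)
    return(out)
  }
  rho <- 1 - (1 - q)^net$n
  if (rho > 0 && runif(1) < rho) {
    out <- as.integer(runif(net$n) < q)
  } else {
    out <- synchronous_update(net, x)
  }
  out[seq_len(pnet$r)] <- pin_values(pnet$r, pnet$w)
  out
}

#' Steady-state distributions of all pin states of a control kernel
#'
#' For each `w` in `1..2^r`, the pinned chain's stationary distribution
#' `g_w^{(r)}`, computed exactly from the pinned transition matrix (default)
#' or by Monte Carlo.  Each `g_w` is supported inside the block of the state
#' space whose first `r` bits equal `X_w`, so the `2^r` distributions are
#' pairwise orthogonal.
#'
#' @inheritParams pin
#' @param q perturbation parameter in `(0, 1)`.
#' @param method `"exact"` (transition-matrix oracle) or `"mc"`.
#' @param steps,burn_in,seed Monte Carlo settings (method `"mc"`).
#' @return a named list `g1 ... g{2^r}` of probability vectors over `1..2^n`.
#' @export
pinned_steady_states <- function(net, r, q, method = c("exact", "mc"),
                                 steps = 1e5, burn_in = 1000L, seed = NULL) {
  method <- match.arg(method)
  r <- as.integer(r)
  if (r < 1L || r > net$n) stop("`r` must satisfy 1 <= r <= n")
  ws <- seq_len(2L^r)
  out <- lapply(ws, function(w) {
    if (method == "exact") {
      stationary_distribution(transition_matrix(net, q, r, w))
    } else {
      dmap <- det_state_map(net, r, w)
      h <- local_seed(if (is.null(seed)) NULL else seed + w,
        cpp_bn_chain(dmap - 1L, net$n, r, w - 1L, q, as.integer(steps),
                     as.integer(burn_in), 0L))
      h / sum(h)
    }
  })
  names(out) <- paste0("g", ws)
  out
}

#' Maximum pairwise overlap of a set of distributions
#'
#' Returns `max_{i != j} sum_s g_i(s) g_j(s)`; exactly 0 certifies that the
#' distributions have pairwise disjoint supports (the orthogonality condition
#' of partitioned pinned steady states).
#'
#' @param g_list list of at least two probability vectors of equal length.
#' @return the maximum pairwise scalar product.
#' @export
verify_partition <- function(g_list) {
  if (length(g_list) < 2L) stop("need at least two distributions")
  mx <- -Inf
  for (i in seq_along(g_list)) {
    for (j in seq_along(g_list)) {
      if (i < j) mx <- max(mx, sum(g_list[[i]] * g_list[[j]]))
    }
  }
  mx
}

#' Define a dynamic (stochastic) control-kernel process
#'
#' A discrete-time Markov chain `eta_t` over pin states; at each step the CK
#' is held at `X_{eta_t}` (state 0 = unpinned).
#'
#' @param states integer vector, subset of `{0} U {1..2^r}`.
#' @param transition_probs row-stochastic matrix over `states`.
#' @return an object of class `dynamic_ck`.
#' @export
dynamic_ck_process <- function(states, transition_probs) {
  states <- as.integer(states)
  P <- as.matrix(transition_probs)
  if (nrow(P) != length(states) || ncol(P) != length(states))
    stop("`transition_probs` must be square over `states`")
  if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12)
    stop("`transition_probs` rows must be non-negative and sum to 1")
  structure(list(states = states, transition_probs = P), class = "dynamic_ck")
}

#' Simulate dynamic control-kernel pinning
#'
#' Runs the cell under `eta_t`-driven pinning and returns the visit histogram
#' of the cell states together with the realized occupancy of `eta`.  When the
#' pin process switches slowly relative to the network's mixing time, the
#' histogram is a mixture of the pinned steady states with weights close to
#' the occupancy fractions.
#'
#' @inheritParams pinned_steady_states
#' @param proc a [dynamic_ck_process()].
#' @param steps recorded steps.
#' @param burn_in steps discarded before recording.
#' @param seed integer seed.
#' @return list with `g` (probability vector over `1..2^n`) and
#'   `eta_occupancy` (named occupancy fractions of the pin states).
#' @export
simulate_dynamic_ck <- function(net, r, proc, q, steps, burn_in = 0L,
                                seed = NULL) {
  stopifnot(inherits(proc, "dynamic_ck"))
  r <- as.integer(r)
  if (any(proc$states < 0L) || any(proc$states > 2L^r))
    stop(sprintf("process states must lie in {0, 1, ..., %d}", 2L^r))
  dmaps <- vapply(proc$states, function(w) det_state_map(net, r, w) - 1L,
                  integer(2L^net$n))
  pp <- ifelse(proc$states == 0L, -1L, proc$states - 1L)
  res <- local_seed(seed,
    cpp_dynamic_ck_chain(dmaps, as.integer(pp), net$n, r, q,
                         proc$transition_probs, as.integer(steps),
                         as.integer(burn_in), 0L, 0L))
  names(res$eta_occupancy) <- paste0("w", proc$states)
  res$g <- res$g / sum(res$g)
  res
}
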
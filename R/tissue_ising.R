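#' Ising interaction parameters
#'
#' Parameters of the multilayer Ising Hamiltonian over the control-kernel
#' layers of a tissue: pairwise coupling `J` between the four lattice
#' neighbors (paracrine signaling), local field `h0` toward each cell's own
#' BN-predicted CK update (the cell's tendency to follow its original
#' dynamics), and external/autocrine field `h` along the layer field `psi`.
#' `T` is the population-level intrinsic noise (temperature) and `n_mc` the
#' number of cells attempted per layer per MC step.
#'
#' @param J pairwise coupling (uniform, >= 0).
#' @param h0 local original-dynamics field strength.
#' @param h external field strength.
#' @param psi per-layer external field direction in `{-1, +1}` (recycled).
#' @param T temperature (> 0).
#' @param n_mc cells attempted per layer per MC step.
#' @return an object of class `ising_params`.
#' @export
ising_params <- function(J = 1, h0 = 0, h = 0, psi = 1, T = 1, n_mc = 10L) {
  if (T <= 0) stop("`T` must be positive")
  if (J < 0) stop("`J` must be non-negative")
  if (!all(psi %in% c(-1, 1))) stop("`psi` entries must be -1 or +1")
  structure(list(J = J, h0 = h0, h = h, psi = psi, T = T,
                 n_mc = as.integer(n_mc)), class = "ising_params")
}

# Four nearest neighbors (up, down, left, right) of every cell on an
# Lx x Ly periodic lattice; cells are numbered row-major.
tissue_neighbors <- function(Lx, Ly) {
  L <- Lx * Ly
  i <- seq_len(L) - 1L
  col <- i %% Lx
  row <- i %/% Lx
  idx <- function(r, c) r * Lx + c + 1L
  cbind(up    = idx((row - 1L) %% Ly, col),
        down  = idx((row + 1L) %% Ly, col),
        left  = idx(row, (col - 1L) %% Lx),
        right = idx(row, (col + 1L) %% Lx))
}

#' Build a tissue of coupled Boolean networks
#'
#' `Lx * Ly` isogenic cells on a 2D periodic lattice, each holding a full BN
#' state; the first `r` genes double as the Ising spin layers.
#'
#' @param net the shared [boolean_network()].
#' @param Lx,Ly lattice dimensions (both >= 3; smaller wraps would duplicate
#'   neighbors).
#' @param r control-kernel size.
#' @param init `"random"` (all genes uniform) or `"pinned"` (CK layer set to
#'   `X_w`, other genes random).
#' @param w pin index for `init = "pinned"`.
#' @param seed integer seed for the initial states.
#' @return an object of class `bn_tissue` with fields `net`, `Lx`, `Ly`, `r`,
#'   `X` (`L x n` 0/1 matrix of cell states) and `nbr` (`L x 4` neighbor
#'   indices).
#' @export
build_tissue <- function(net, Lx, Ly, r, init = c("random", "pinned"),
                         w = NULL, seed = NULL) {
  init <- match.arg(init)
  Lx <- as.integer(Lx); Ly <- as.integer(Ly); r <- as.integer(r)
  if (Lx < 3L || Ly < 3L)
    stop("`Lx` and `Ly` must be >= 3 (periodic wrap-around would duplicate neighbors)")
  if (r < 1L || r > net$n) stop("`r` must satisfy 1 <= r <= n")
  L <- Lx * Ly
  X <- local_seed(seed, {
    X <- matrix(as.integer(runif(L * net$n) < 0.5), L, net$n)
    if (init == "pinned") {
      if (is.null(w)) stop("`w` is required for init = \"pinned\"")
      X[, seq_len(r)] <- matrix(pin_values(r, w), L, r, byrow = TRUE)
    }
    X
  })
  structure(list(net = net, Lx = Lx, Ly = Ly, r = r, X = X,
                 nbr = tissue_neighbors(Lx, Ly)),
            class = "bn_tissue")
}

#' @export
print.bn_tissue <- function(x, ...) {
  cat(sprintf("Tissue: %d x %d cells (periodic), n = %d genes, CK size r = %d\n",
              x$Lx, x$Ly, x$net$n, x$r))
  invisible(x)
}

# Decimal-encoded (1-based) states of all cells.
cell_states <- function(tissue) {
  n <- tissue$net$n
  as.integer(tissue$X %*% 2^(n - seq_len(n))) + 1L
}

#' BN-predicted control-kernel spins
#'
#' For every cell and CK layer, the spin `2 f_m(y_m) - 1` the CK gene would
#' take under the synchronous update of the cell's current full state.  This
#' field is recomputed once per MC step and held fixed during the Metropolis
#' sweep.
#'
#' @param tissue a [build_tissue()] object.
#' @return an `L x r` matrix of -1/+1 values.
#' @export
compute_f_bar <- function(tissue) {
  net <- tissue$net
  X <- tissue$X
  out <- matrix(0, nrow(X), tissue$r)
  for (m in seq_len(tissue$r)) {
    Ji <- net$inputs[[m]]
    k <- length(Ji)
    idx <- rep(1L, nrow(X))
    for (l in seq_len(k)) idx <- idx + X[, Ji[l]] * 2L^(k - l)
    out[, m] <- 2 * net$truth_tables[[m]][idx] - 1
  }
  out
}

#' Multilayer Ising energy of a tissue
#'
#' `H_r = sum_m [ -J sum_bonds s_i s_j - h0 sum_i s_i fbar_i - h psi_m sum_i s_i ]`
#' with `s = 2x - 1` and every unordered lattice bond counted once.
#'
#' @inheritParams compute_f_bar
#' @param params an [ising_params()].
#' @param f_bar `L x r` matrix from [compute_f_bar()]; required when
#'   `h0 != 0`.
#' @return the total energy (a scalar).
#' @export
hamiltonian <- function(tissue, params, f_bar = NULL) {
  r <- tissue$r
  if (params$h0 != 0 && is.null(f_bar))
    stop("`f_bar` is required when h0 != 0")
  psi <- rep_len(params$psi, r)
  S <- 2 * tissue$X[, seq_len(r), drop = FALSE] - 1
  right <- tissue$nbr[, "right"]
  down <- tissue$nbr[, "down"]
  H <- 0
  for (m in seq_len(r)) {
    s <- S[, m]
    H <- H - params$J * sum(s * s[right] + s * s[down]) -
      params$h * psi[m] * sum(s)
    if (params$h0 != 0) H <- H - params$h0 * sum(s * f_bar[, m])
  }
  H
}

#' One Metropolis sweep over the control-kernel layers
#'
#' For each layer independently, `n_mc` distinct cells are drawn uniformly and
#' single-spin flips are proposed sequentially, accepted with probability
#' `min(1, exp(-dE/T))` where `dE` uses the current (partially updated)
#' configuration.
#'
#' @inheritParams hamiltonian
#' @return list with the updated `tissue` and `dE`, the summed energy change
#'   of the accepted flips.
#' @export
metropolis_sweep <- function(tissue, params, f_bar = NULL) {
  r <- tissue$r
  if (is.null(f_bar)) {
    if (params$h0 != 0) stop("`f_bar` is required when h0 != 0")
    f_bar <- matrix(0, nrow(tissue$X), r)
  }
  res <- cpp_metropolis_sweep(tissue$X[, seq_len(r), drop = FALSE],
                              tissue$nbr, r, params$J, params$h0, params$h,
                              rep_len(params$psi, r), params$T, params$n_mc,
                              f_bar)
  tissue$X[, seq_len(r)] <- res$spins
  list(tissue = tissue, dE = res$dE)
}

#' One hybrid MC step of the tissue
#'
#' Order per step: (1) compute `f_bar` from the current states; (2) Metropolis
#' sweep of the CK layers; (3) synchronous perturbed update of the non-CK
#' genes of every cell (the replacement vector fires per cell with probability
#' `1-(1-q)^n` and overwrites non-CK genes only; the CK genes carry the spin
#' values).
#'
#' @inheritParams hamiltonian
#' @param q perturbation parameter of the per-cell gene noise.
#' @return the updated tissue.
#' @export
mc_step <- function(tissue, params, q) {
  net <- tissue$net
  n <- net$n
  r <- tissue$r
  fb <- if (params$h0 != 0) compute_f_bar(tissue) else NULL
  tissue <- metropolis_sweep(tissue, params, fb)$tissue
  rho <- 1 - (1 - q)^n
  free <- if (r < n) seq.int(r + 1L, n) else integer(0)
  Xold <- tissue$X
  for (i in seq_len(nrow(Xold))) {
    if (rho > 0 && runif(1) < rho) {
      tissue$X[i, free] <- as.integer(runif(n - r) < q)
    } else {
      x <- Xold[i, ]
      for (g in free) {
        tissue$X[i, g] <- net$truth_tables[[g]][tt_index(x[net$inputs[[g]]])]
      }
    }
  }
  tissue
}

# Precompute the decimal-state tables used by the C++ run loop: the non-CK
# bits of the synchronous update of every full state, and the +/-1 spin each
# CK gene would take.
tissue_tables <- function(net, r) {
  n <- net$n
  if (n > 16L) stop("tissue simulation limited to n <= 16 genes")
  dmap0 <- det_state_map(net) - 1L
  nfree <- n - r
  othmap <- as.integer(dmap0 %% 2L^nfree)
  fmap <- matrix(0, 2L^n, r)
  for (m in seq_len(r)) {
    fmap[, m] <- 2 * bitwAnd(bitwShiftR(dmap0, n - m), 1L) - 1
  }
  list(othmap = othmap, fmap = fmap)
}

# Projection basis ghat[, w] = g_w / <g_w, g_w> from a list of pinned
# steady-state distributions.
spectral_basis <- function(basis) {
  B <- do.call(cbind, basis)
  sweep(B, 2, colSums(B^2), "/")
}

#' Run a tissue simulation
#'
#' Fast loop over [mc_step()]s with optional per-step cell-type magnetization
#' (spectral weights on an orthogonal pinned basis), optional
#' temperature-magnetization feedback, and optional recording of the
#' population distribution.
#'
#' @inheritParams mc_step
#' @param steps number of MC steps.
#' @param basis optional list of the `2^r` pinned steady-state distributions
#'   (from [pinned_steady_states()]); enables the `M_type` trace (r = 1).
#' @param feedback optional [feedback_controller()]; couples `dT/dt = |M| -
#'   alpha T` to the run (requires `basis` and r = 1) and overrides
#'   `params$T` with the controller temperature.
#' @param record_G_every record the population distribution, tissue-mean gene
#'   state and step index every this many steps (0 = never).
#' @return list with the final `tissue`, per-step traces `M_spin` (CK layer-1
#'   mean spin), `M_type` and `T_trace` (when enabled), `T_final`, and the
#'   recorded `G_hist` (states x records), `mean_state`, `steps_recorded`.
#' @export
run_tissue <- function(tissue, params, q, steps, basis = NULL,
                       feedback = NULL, record_G_every = 0L) {
  net <- tissue$net
  r <- tissue$r
  selftune <- !is.null(feedback)
  if (selftune && (is.null(basis) || r != 1L))
    stop("feedback requires r = 1 and a pinned `basis`")
  tabs <- tissue_tables(net, r)
  ghat <- if (!is.null(basis)) spectral_basis(basis) else
    matrix(0, 2L^net$n, 0L)
  T0 <- if (selftune) feedback$T else params$T
  res <- cpp_run_tissue(cell_states(tissue) - 1L, tissue$nbr, net$n, r,
                        tabs$othmap, tabs$fmap, params$J, params$h0,
                        params$h, rep_len(params$psi, r), T0, q,
                        params$n_mc, as.integer(steps),
                        selftune,
                        if (selftune) feedback$alpha else 0,
                        if (selftune) feedback$dtau else 0,
                        if (selftune) feedback$T_min else 0,
                        ghat, !is.null(basis), as.integer(record_G_every))
  n <- net$n
  Xn <- matrix(0L, nrow(tissue$X), n)
  for (i in seq_len(n)) Xn[, i] <- bitwAnd(bitwShiftR(res$s, n - i), 1L)
  tissue$X <- Xn
  list(tissue = tissue,
       M_spin = res$M_spin,
       M_type = if (!is.null(basis) || selftune) res$M_type else NULL,
       T_trace = if (selftune) res$T_trace else NULL,
       T_final = res$T_final,
       G_hist = if (record_G_every > 0) res$G_hist else NULL,
       mean_state = if (record_G_every > 0) res$mean_state else NULL,
       steps_recorded = if (record_G_every > 0) res$steps_recorded else NULL,
       n_perturbations = res$n_perturbations)
}

#' Annealing sweep over a control parameter
#'
#' For each value of the schedule (over `h0` or `T`): `t_eq` equilibration
#' steps, then `t_sample` sampled steps recording the population distribution
#' and its constrained-least-squares mixture fit against `basis`.  The final
#' state of each value seeds the next, as in a physical annealing run.
#'
#' @inheritParams run_tissue
#' @param vary `"h0"` or `"T"`.
#' @param values ordered schedule of parameter values.
#' @param t_eq,t_sample equilibration and sampling steps per value.
#' @param basis named list of basis distributions for the mixture fit,
#'   typically `c(list(g0 = ...), pinned_steady_states(...))`.
#' @return list with `summary` (one row per schedule value: mean weights,
#'   mean relative error `epsilon`, mean layer-1 spin magnetization),
#'   `weights` (per-value `t_sample x K` matrices) and the final `tissue`.
#' @export
anneal_sweep <- function(tissue, params, q, vary = c("h0", "T"), values,
                         t_eq, t_sample, basis) {
  vary <- match.arg(vary)
  if (length(values) < 1L) stop("`values` must be non-empty")
  K <- length(basis)
  rows <- vector("list", length(values))
  wlist <- vector("list", length(values))
  for (v in seq_along(values)) {
    params[[vary]] <- values[[v]]
    if (t_eq > 0) tissue <- run_tissue(tissue, params, q, t_eq)$tissue
    res <- run_tissue(tissue, params, q, t_sample, record_G_every = 1L)
    tissue <- res$tissue
    Wmat <- matrix(0, t_sample, K)
    eps <- numeric(t_sample)
    for (t in seq_len(t_sample)) {
      fit <- fit_mixture_ls(res$G_hist[, t], basis)
      Wmat[t, ] <- fit$weights
      eps[t] <- fit$epsilon
    }
    colnames(Wmat) <- names(basis)
    wlist[[v]] <- Wmat
    rows[[v]] <- data.frame(value = values[[v]],
                            t(colMeans(Wmat)),
                            epsilon = mean(eps),
                            M_spin = mean(res$M_spin))
  }
  summary <- do.call(rbind, rows)
  names(summary)[1] <- vary
  list(summary = summary, weights = wlist, tissue = tissue)
}
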
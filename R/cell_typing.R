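#' Instantaneous population distribution of a tissue
#'
#' The fraction of the `L` cells in each decimal-encoded state.
#'
#' @param tissue a [build_tissue()] object.
#' @return a probability vector over `1..2^n` summing exactly to 1.
#' @export
population_distribution <- function(tissue) {
  N <- 2L^tissue$net$n
  tabulate(cell_states(tissue), nbins = N) / nrow(tissue$X)
}

#' Simplex-constrained least-squares mixture fit
#'
#' Finds weights minimizing `||G - sum_k c_k basis_k||_2` subject to
#' `0 <= c_k <= 1` and `sum c_k = 1`, by exact active-set enumeration over the
#' faces of the simplex (each face's equality-constrained solution is obtained
#' from its KKT system; the best feasible one is the global optimum).  The
#' relative error is `epsilon = ||G - G_fit|| / N` with `N` the number of
#' states.
#'
#' @param G a probability vector (the population distribution).
#' @param basis named list of basis distributions (each summing to 1),
#'   e.g. `c(list(g0 = g0), pinned_steady_states(...))`.
#' @return an object of class `mixture_fit`: list with `weights` (named,
#'   summing to 1), `epsilon`, `fitted`, and `objective` (`||G - G_fit||_2`).
#' @export
fit_mixture_ls <- function(G, basis) {
  if (length(basis) < 1L) stop("`basis` must contain at least one distribution")
  K <- length(basis)
  if (K > 12L) stop("active-set enumeration limited to 12 basis components")
  B <- do.call(cbind, basis)
  if (nrow(B) != length(G)) stop("basis and `G` dimensions disagree")
  BtB <- crossprod(B)
  BtG <- crossprod(B, G)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^K - 2)) {
    free <- which(bitwAnd(bitwShiftR(mask, seq_len(K) - 1L), 1L) == 0L)
    kf <- length(free)
    A <- rbind(cbind(2 * BtB[free, free, drop = FALSE], 1), c(rep(1, kf), 0))
    rhs <- c(2 * BtG[free], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    cf <- sol[seq_len(kf)]
    if (any(cf < -1e-10) || any(cf > 1 + 1e-10)) next
    cw <- numeric(K)
    cw[free] <- pmin(pmax(cf, 0), 1)
    cw <- cw / sum(cw)
    obj <- sqrt(sum((G - as.numeric(B %*% cw))^2))
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- cw
    }
  }
  if (is.null(best)) stop("mixture fit failed: no feasible face (degenerate basis?)")
  names(best) <- names(basis)
  structure(list(weights = best,
                 epsilon = best_obj / length(G),
                 objective = best_obj,
                 fitted = as.numeric(B %*% best)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Mixture fit: weights\n")
  print(round(x$weights, 4))
  cat(sprintf("relative error epsilon = %.3e\n", x$epsilon))
  invisible(x)
}

#' Spectral decomposition weights on an orthogonal pinned basis
#'
#' Projects `G` on the dual basis `ghat_w = g_w / <g_w, g_w>`, so that an
#' exact mixture `G = sum_w a_w g_w` of the pairwise-orthogonal pinned
#' distributions returns exactly `a_w`.  Intended for the `h0 = 0` regime
#' where every cell sits in a pinned block and the unpinned fraction
#' vanishes.  Raw projections are clipped to `[0, 1]` and renormalized for
#' reporting; the raw values are retained.
#'
#' @param G a probability vector.
#' @param basis list of pairwise-orthogonal pinned steady-state
#'   distributions.
#' @return list with `weights` (clipped, renormalized, named) and `raw`
#'   (unnormalized projections).
#' @export
spectral_weights <- function(G, basis) {
  if (verify_partition(basis) > 1e-10)
    stop("`basis` is not orthogonal (max pairwise inner product > 1e-10)")
  ghat <- spectral_basis(basis)
  raw <- as.numeric(crossprod(ghat, G))
  w <- pmin(pmax(raw, 0), 1)
  if (sum(w) > 0) w <- w / sum(w)
  names(w) <- names(raw) <- names(basis)
  list(weights = w, raw = raw)
}

#' Tissue magnetization from an r = 1 mixture
#'
#' The order parameter `M_t = c2 - c1`, the difference of the two cell-type
#' fractions of a CK of size 1: `-1` and `+1` are homogeneous populations of
#' types g1 and g2, 0 a perfectly balanced (pluripotent-like) mixture.
#'
#' @param fit a `mixture_fit`, or a named weight vector containing `g1` and
#'   `g2` entries.
#' @return `M_t` in `[-1, 1]`.
#' @export
magnetization <- function(fit) {
  w <- if (inherits(fit, "mixture_fit")) fit$weights else fit
  if (!all(c("g1", "g2") %in% names(w)))
    stop("magnetization is defined for r = 1 fits with components g1 and g2")
  if (sum(!(names(w) %in% c("g0", "g1", "g2"))) > 0)
    stop("magnetization is defined for r = 1 fits with components g1 and g2")
  unname(w["g2"] - w["g1"])
}

#' Non-negative matrix factorization of a population history
#'
#' Lee-Seung multiplicative updates for the Frobenius objective
#' `||G - Omega E||_F`: decomposes the non-negative states x time history
#' into `K` non-negative components (columns of `Omega`, each normalized to
#' sum 1, interpretable as steady-state distributions of cell types) and
#' their time-varying weights `E`.
#'
#' @param G_history non-negative `N x T` matrix (one population distribution
#'   per column).
#' @param K decomposition rank.
#' @param seed integer seed for the random initialization.
#' @param max_iter,tol iteration cap and relative-improvement tolerance.
#' @return an object of class `nnmf_result`: list with `Omega` (`N x K`,
#'   columns sum to 1), `E` (`K x T`), `K` and the final `loss`.
#' @export
nnmf_decompose <- function(G_history, K, seed = NULL, max_iter = 2000L,
                           tol = 1e-10) {
  G_history <- as.matrix(G_history)
  if (any(G_history < 0)) stop("`G_history` must be non-negative")
  N <- nrow(G_history); Tn <- ncol(G_history)
  K <- as.integer(K)
  if (K < 1L || K > min(N, Tn))
    stop("`K` must satisfy 1 <= K <= min(dim(G_history))")
  eps <- .Machine$double.eps
  local_seed(seed, {
    W <- matrix(runif(N * K, 0.1, 1), N, K)
    H <- matrix(runif(K * Tn, 0.1, 1), K, Tn)
    loss_old <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, G_history)) / (crossprod(W) %*% H + eps)
      W <- W * (G_history %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10L == 0L) {
        loss <- sqrt(sum((G_history - W %*% H)^2))
        if (is.finite(loss_old) && loss_old - loss < tol * max(loss_old, 1))
          break
        loss_old <- loss
      }
    }
    cs <- colSums(W)
    cs[cs == 0] <- 1
    W <- sweep(W, 2, cs, "/")
    H <- H * cs
    structure(list(Omega = W, E = H, K = K,
                   loss = sqrt(sum((G_history - W %*% H)^2))),
              class = "nnmf_result")
  })
}
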
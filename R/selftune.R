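#' Temperature-magnetization feedback controller
#'
#' The negative feedback `dT/dt = |M_t| - alpha T`, integrated by one Euler
#' step of size `dtau` per MC step.  Starting above the Ising critical
#' temperature, the feedback cools the tissue through criticality; once the
#' symmetry breaks and `|M|` grows, the temperature settles at the fixed
#' point `|M|/alpha` below it.
#'
#' @param T0 initial temperature.
#' @param alpha relaxation coefficient (> 0).
#' @param dtau Euler step per MC step.
#' @param T_min positive temperature floor (guards `exp(-dE/T)` overflow).
#' @return an object of class `feedback_controller` with fields `T`, `alpha`,
#'   `dtau`, `T_min`.
#' @export
feedback_controller <- function(T0 = 2.8, alpha = 0.8, dtau = 5e-7,
                                T_min = 0.01) {
  if (alpha <= 0) stop("`alpha` must be positive")
  if (T_min <= 0) stop("`T_min` must be positive")
  if (T0 < T_min) stop("`T0` must be >= T_min")
  structure(list(T = T0, alpha = alpha, dtau = dtau, T_min = T_min),
            class = "feedback_controller")
}

#' One Euler step of the feedback equation
#'
#' `T <- max(T_min, T + dtau (|M_t| - alpha T))`.
#'
#' @param ctrl a [feedback_controller()].
#' @param M_t instantaneous magnetization, `|M_t| <= 1`.
#' @return the controller with updated temperature.
#' @export
feedback_step <- function(ctrl, M_t) {
  if (abs(M_t) > 1 + 1e-12) stop("`M_t` must lie in [-1, 1]")
  ctrl$T <- max(ctrl$T_min, ctrl$T + ctrl$dtau * (abs(M_t) - ctrl$alpha * ctrl$T))
  ctrl
}

#' Self-tuned tissue differentiation run
#'
#' The self-tuning regime: `r = 1`, `h = h0 = 0` (the CK layer is a standard
#' 2D Ising model), with the tissue temperature driven by the feedback
#' equation from the instantaneous cell-type magnetization (spectral weights
#' on the exact pinned basis).  Per step: hybrid MC step, population
#' distribution, magnetization, one Euler step of the feedback.
#'
#' @param net the shared [boolean_network()].
#' @param Lx,Ly lattice dimensions.
#' @param ctrl a [feedback_controller()].
#' @param q per-cell gene perturbation parameter.
#' @param n_mc cells attempted per MC step.
#' @param steps number of MC steps.
#' @param seed integer seed (initial states and trajectory).
#' @param J pairwise coupling.
#' @param init_w initial CK pin value index (default 2: CK gene set to 1, so
#'   the run starts at `M = 1`).
#' @param record_G_every record the population distribution and tissue-mean
#'   gene state every this many steps.
#' @param basis optional precomputed [pinned_steady_states()] list (r = 1);
#'   computed exactly when omitted.
#' @return list with per-step traces `M_t` and `T_trace`, `T_final`, recorded
#'   `G_hist`, `mean_state`, `steps_recorded`, and the final `tissue`.
#' @export
run_selftuned <- function(net, Lx, Ly, ctrl, q = 0.02, n_mc = 10L, steps,
                          seed = NULL, J = 1, init_w = 2L,
                          record_G_every = 1000L, basis = NULL) {
  if (is.null(basis)) basis <- pinned_steady_states(net, 1L, q)
  params <- ising_params(J = J, h0 = 0, h = 0, T = ctrl$T, n_mc = n_mc)
  local_seed(seed, {
    tissue <- build_tissue(net, Lx, Ly, r = 1L, init = "pinned", w = init_w)
    res <- run_tissue(tissue, params, q, steps, basis = basis,
                      feedback = ctrl, record_G_every = record_G_every)
    list(M_t = res$M_type, T_trace = res$T_trace, T_final = res$T_final,
         G_hist = res$G_hist, mean_state = res$mean_state,
         steps_recorded = res$steps_recorded, tissue = res$tissue)
  })
}

#' Ensemble of self-tuned differentiation runs
#'
#' Runs `n_reps` independent, identically configured self-tuned tissues with
#' seeds `base_seed .. base_seed + n_reps - 1`, and summarizes each
#' replicate: the tissue-mean gene state at the requested checkpoints, the
#' final magnetization and temperature, and the mean `|M|` over the last 10%
#' of steps.
#'
#' @inheritParams run_selftuned
#' @param n_reps number of replicates (>= 2).
#' @param base_seed first replicate seed.
#' @param checkpoints step indices at which the tissue-mean gene state is
#'   collected (rounded up to the recording grid).
#' @param checkpoint_window number of recorded frames (ending at the
#'   checkpoint) averaged into each checkpoint value; a short time average
#'   suppresses the single-snapshot sampling noise of small tissues without
#'   touching the dynamics.
#' @return an object of class `ensemble_summary`: list with `final_M`,
#'   `final_T`, `mean_abs_M_late` (per replicate), `mean_state` (replicates x
#'   checkpoints matrix) and `checkpoints`.
#' @export
replicate_ensemble <- function(net, Lx, Ly, ctrl, q = 0.02, n_mc = 10L,
                               steps, n_reps, base_seed,
                               checkpoints = steps, J = 1, init_w = 2L,
                               record_G_every = 1000L,
                               checkpoint_window = 10L) {
  if (n_reps < 2L) stop("`n_reps` must be >= 2")
  basis <- pinned_steady_states(net, 1L, q)
  ck_idx <- pmax(1L, ceiling(checkpoints / record_G_every))
  first_M <- final_M <- final_T <- mean_abs_late <- numeric(n_reps)
  ms <- matrix(0, n_reps, length(checkpoints))
  late <- seq.int(max(1L, floor(0.9 * steps)), steps)
  for (rep in seq_len(n_reps)) {
    res <- run_selftuned(net, Lx, Ly, ctrl, q = q, n_mc = n_mc,
                         steps = steps, seed = base_seed + rep - 1L,
                         record_G_every = record_G_every, J = J,
                         init_w = init_w, basis = basis)
    first_M[rep] <- res$M_t[1]
    final_M[rep] <- res$M_t[steps]
    final_T[rep] <- res$T_final
    mean_abs_late[rep] <- mean(abs(res$M_t[late]))
    ms[rep, ] <- vapply(ck_idx, function(ci) {
      win <- seq.int(max(1L, ci - checkpoint_window + 1L), ci)
      mean(res$mean_state[win])
    }, numeric(1))
  }
  structure(list(first_M = first_M, final_M = final_M, final_T = final_T,
                 mean_abs_M_late = mean_abs_late,
                 mean_state = ms, checkpoints = checkpoints),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  n <- length(x$final_M)
  cat(sprintf("Ensemble of %d self-tuned tissue runs\n", n))
  cat(sprintf("  final M > 0 in %d/%d replicates; mean final T = %.3f\n",
              sum(x$final_M > 0), n, mean(x$final_T)))
  invisible(x)
}
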
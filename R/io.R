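#' Read and write Boolean networks
#'
#' Two interchange formats: a JSON object `{n, k, p, seed, inputs,
#' truth_tables}`, and bnet-style text (header `targets, factors`, then one
#' line per gene `name, boolean-expression` with operators `!`, `&`, `|` and
#' parentheses) for interoperability with Boolean-network toolchains.  Both
#' round-trip the wiring and truth tables exactly; the bnet form drops the
#' generation metadata (`p`, `seed`).
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @return `read_network_*` return a [boolean_network()]; writers return
#'   `path` invisibly.
#' @name network_io
NULL

#' @rdname network_io
#' @export
write_network_json <- function(net, path) {
  obj <- list(n = net$n, k = net$k, p = net$p, seed = net$seed,
              inputs = net$inputs, truth_tables = net$truth_tables)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("inputs", "truth_tables")) {
    if (is.null(obj[[field]])) stop("missing field `", field, "` in ", path)
    if (!is.list(obj[[field]]))
      obj[[field]] <- lapply(seq_len(nrow(obj[[field]])),
                             function(i) obj[[field]][i, ])
    obj[[field]] <- unname(obj[[field]])
  }
  boolean_network(obj$inputs, obj$truth_tables,
                  p = if (is.null(obj$p)) NA_real_ else obj$p,
                  seed = obj$seed)
}

#' @rdname network_io
#' @details `load_network()` dispatches on the file extension: `.json` is
#'   parsed as the JSON form, anything else as bnet-style text.
#' @export
load_network <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_network_json(path)
  else read_network_bnet(path)
}

gene_names <- function(n) paste0("g", seq_len(n))

# Minterm DNF of one gene's truth table; constant tables expand to
# tautology/contradiction forms that still mention every input (in order),
# so the parser recovers the identical input list.
bnet_expression <- function(inputs, tt, nms) {
  vars <- nms[inputs]
  k <- length(inputs)
  if (all(tt == 1L))
    return(paste(sprintf("(%s | !%s)", vars, vars), collapse = " & "))
  if (all(tt == 0L))
    return(paste(sprintf("(%s & !%s)", vars, vars), collapse = " | "))
  rows <- which(tt == 1L) - 1L
  terms <- vapply(rows, function(v) {
    bits <- bitwAnd(bitwShiftR(v, k - seq_len(k)), 1L)
    paste0("(", paste(ifelse(bits == 1L, vars, paste0("!", vars)),
                      collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' @rdname network_io
#' @export
write_network_bnet <- function(net, path) {
  nms <- gene_names(net$n)
  lines <- c("targets, factors",
             vapply(seq_len(net$n), function(i) {
               paste0(nms[i], ", ",
                      bnet_expression(net$inputs[[i]], net$truth_tables[[i]], nms))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname network_io
#' @export
read_network_bnet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) stop("no gene definitions in ", path)
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  targets <- trimws(vapply(parts, `[`, character(1), 1L))
  exprs <- trimws(vapply(parts, `[`, character(1), 2L))
  n <- length(targets)
  name2idx <- stats::setNames(seq_len(n), targets)
  inputs <- vector("list", n)
  tts <- vector("list", n)
  for (i in seq_len(n)) {
    e <- exprs[i]
    if (is.na(e) || !nzchar(e))
      stop(sprintf("line %d (gene %s): missing expression", i, targets[i]))
    if (grepl("[^A-Za-z0-9_!&|() ]", e))
      stop(sprintf("line %d (gene %s): unsupported characters in expression",
                   i, targets[i]))
    ast <- tryCatch(str2lang(e), error = function(err)
      stop(sprintf("line %d (gene %s): parse error: %s", i, targets[i],
                   conditionMessage(err))))
    vars <- all.vars(ast)
    if (!all(vars %in% targets))
      stop(sprintf("line %d (gene %s): unknown gene(s): %s", i, targets[i],
                   paste(setdiff(vars, targets), collapse = ", ")))
    k <- length(vars)
    if (k < 1L)
      stop(sprintf("line %d (gene %s): expression references no genes", i, targets[i]))
    combos <- state_matrix(k)
    tt <- integer(2^k)
    for (row in seq_len(nrow(combos))) {
      env <- as.list(as.numeric(combos[row, ]))
      names(env) <- vars
      tt[row] <- as.integer(as.logical(eval(ast, envir = env)))
    }
    inputs[[i]] <- unname(name2idx[vars])
    tts[[i]] <- tt
  }
  boolean_network(inputs, tts)
}

#' Read and write dynamic control-kernel processes as JSON
#'
#' Serializes the pin-state Markov chain of [dynamic_ck_process()] as a JSON
#' object `{states, transition_probs}`; round-trips exactly.
#'
#' @param proc a [dynamic_ck_process()].
#' @param path file path.
#' @return the process (reader) or `path` invisibly (writer).
#' @name dynamic_ck_io
NULL

#' @rdname dynamic_ck_io
#' @export
write_dynamic_ck_json <- function(proc, path) {
  stopifnot(inherits(proc, "dynamic_ck"))
  jsonlite::write_json(list(states = proc$states,
                            transition_probs = proc$transition_probs),
                       path, digits = NA)
  invisible(path)
}

#' @rdname dynamic_ck_io
#' @export
read_dynamic_ck_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dynamic_ck_process(obj$states, obj$transition_probs)
}

#' Read and write steady-state distributions as CSV
#'
#' Two columns: `s` (1-based decimal state index) and `prob`.
#'
#' @param g probability vector over `1..2^n`.
#' @param path file path.
#' @return the probability vector (reader) or `path` invisibly (writer).
#' @name distribution_io
NULL

#' @rdname distribution_io
#' @export
write_distribution_csv <- function(g, path) {
  write.csv(data.frame(s = seq_along(g), prob = g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname distribution_io
#' @export
read_distribution_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("s", "prob") %in% names(df))) stop("expected columns `s`, `prob`")
  g <- numeric(max(df$s))
  g[df$s] <- df$prob
  g
}

#' Built-in reference networks and their steady-state artifacts
#'
#' `"toy2"` is the hand-specified 2-gene AND/OR network (gene 1 = AND of both
#' genes, gene 2 = OR; fixed points (0,0) and (1,1)).  `"model6"` is a seeded
#' 6-gene RBN with k = 2, p = 0.5 — the package's stand-in demonstration
#' network — bundled with its exact unpinned steady state at q = 0.1 and the
#' pinned steady states for CK sizes 1 and 2.  `"custom"` generates an RBN
#' from `n`, `k`, `p` and the seed.
#'
#' @param kind `"model6"`, `"toy2"` or `"custom"`.
#' @param seed generation seed for the RBN kinds.
#' @param dir optional directory; when given, the network (JSON + bnet) and
#'   all reference distributions (CSV) are written there.
#' @param n,k,p RBN parameters for `kind = "custom"`.
#' @return list with `net`, and for the RBN kinds `q`, `g0`, `pinned_r1`,
#'   `pinned_r2`.
#' @export
make_fixture <- function(kind = c("model6", "toy2", "custom"), seed = 1L,
                         dir = NULL, n = 6L, k = 2L, p = 0.5) {
  kind <- match.arg(kind)
  if (kind == "toy2") {
    net <- boolean_network(inputs = list(c(1L, 2L), c(1L, 2L)),
                           truth_tables = list(c(0L, 0L, 0L, 1L),
                                               c(0L, 1L, 1L, 1L)))
    out <- list(net = net)
  } else {
    if (kind == "model6") { n <- 6L; k <- 2L; p <- 0.5 }
    net <- generate_rbn(n, k, p, seed)
    q <- 0.1
    out <- list(net = net, q = q,
                g0 = stationary_distribution(transition_matrix(net, q)),
                pinned_r1 = pinned_steady_states(net, 1L, q),
                pinned_r2 = pinned_steady_states(net, 2L, q))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_network_json(out$net, file.path(dir, paste0(kind, ".json")))
    write_network_bnet(out$net, file.path(dir, paste0(kind, ".bnet")))
    if (!is.null(out$g0)) {
      write_distribution_csv(out$g0, file.path(dir, "g0.csv"))
      for (w in seq_along(out$pinned_r1))
        write_distribution_csv(out$pinned_r1[[w]],
                               file.path(dir, sprintf("g%d_r1.csv", w)))
      for (w in seq_along(out$pinned_r2))
        write_distribution_csv(out$pinned_r2[[w]],
                               file.path(dir, sprintf("g%d_r2.csv", w)))
    }
  }
  out
}

#' Validate a run configuration
#'
#' A run configuration ties a network (file path or RBN generator
#' parameters), tissue geometry, Ising and noise parameters, a mode-specific
#' horizon and a mandatory seed into one reproducible experiment.
#'
#' @param mode `"simulate"`, `"anneal"`, `"selftune"` or `"ensemble"`.
#' @param ... configuration fields, see Details.
#' @details Common fields: `network` (path) or `n`/`k`/`p`/`net_seed`; `Lx`,
#'   `Ly`, `r`, `J`, `h0`, `h`, `T`, `q`, `n_mc`, `seed` (mandatory).
#'   Mode-specific: `t_eq`/`t_sample` (simulate, anneal); `vary`/`values`
#'   (anneal); `steps`/`alpha`/`dtau`/`T0`/`T_min`/`record_G_every`
#'   (selftune, ensemble); `n_reps`/`base_seed`/`checkpoints` (ensemble).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "anneal", "selftune", "ensemble"),
                       ...) {
  mode <- match.arg(mode)
  cfg <- list(...)
  defaults <- list(Lx = 10L, Ly = 10L, r = 1L, J = 1, h0 = 0, h = 0, T = 1,
                   q = 0.1, n_mc = 10L, t_eq = 1000L, t_sample = 1000L,
                   steps = 10000L, alpha = 0.8, dtau = 5e-7, T0 = 2.8,
                   T_min = 0.01, record_G_every = 100L, n_reps = 2L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$seed)) stop("a `seed` is mandatory in every run configuration")
  if (is.null(cfg$network) && (is.null(cfg$n) || is.null(cfg$k) ||
                               is.null(cfg$p) || is.null(cfg$net_seed)))
    stop("provide `network` (a file) or generator parameters n, k, p, net_seed")
  if (mode == "anneal" && (is.null(cfg$vary) || is.null(cfg$values)))
    stop("anneal mode needs `vary` (\"h0\" or \"T\") and `values`")
  if (mode == "ensemble" && is.null(cfg$base_seed)) cfg$base_seed <- cfg$seed
  cfg$mode <- mode
  class(cfg) <- "run_config"
  cfg
}

config_network <- function(cfg) {
  if (!is.null(cfg$network)) {
    if (grepl("\\.json$", cfg$network)) read_network_json(cfg$network)
    else read_network_bnet(cfg$network)
  } else {
    generate_rbn(cfg$n, cfg$k, cfg$p, cfg$net_seed)
  }
}

#' Execute a configured experiment
#'
#' Runs the configured pipeline and writes the configuration copy, a log
#' (seed, package version, timings, perturbation-event count) and all CSV
#' outputs into `outdir`.  Outputs land in a temporary sibling directory that
#' is renamed on success, so a crashed run never leaves a partial bundle.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (must not exist).
#' @return the output directory, invisibly.
#' @export
run_experiment <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  if (file.exists(outdir)) stop("`outdir` already exists: ", outdir)
  tmp <- paste0(outdir, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  t0 <- Sys.time()
  net <- config_network(cfg)
  write_network_json(net, file.path(tmp, "network.json"))
  jsonlite::write_json(unclass(cfg), file.path(tmp, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  n_perturb <- 0
  if (cfg$mode %in% c("simulate", "anneal")) {
    basis <- c(list(g0 = stationary_distribution(transition_matrix(net, cfg$q))),
               pinned_steady_states(net, cfg$r, cfg$q))
    params <- ising_params(J = cfg$J, h0 = cfg$h0, h = cfg$h, T = cfg$T,
                           n_mc = cfg$n_mc)
    res <- local_seed(cfg$seed, {
      tissue <- build_tissue(net, cfg$Lx, cfg$Ly, cfg$r)
      if (cfg$mode == "simulate") {
        eq <- run_tissue(tissue, params, cfg$q, cfg$t_eq)
        sm <- run_tissue(eq$tissue, params, cfg$q, cfg$t_sample,
                         record_G_every = 1L)
        n_perturb <- eq$n_perturbations + sm$n_perturbations
        K <- length(basis)
        Wmat <- matrix(0, cfg$t_sample, K, dimnames = list(NULL, names(basis)))
        eps <- numeric(cfg$t_sample)
        for (t in seq_len(cfg$t_sample)) {
          fit <- fit_mixture_ls(sm$G_hist[, t], basis)
          Wmat[t, ] <- fit$weights
          eps[t] <- fit$epsilon
        }
        df <- data.frame(t = seq_len(cfg$t_sample), T = cfg$T, h0 = cfg$h0,
                         Wmat, epsilon = eps, M_spin = sm$M_spin)
        write.csv(df, file.path(tmp, "trace.csv"), row.names = FALSE)
        grid <- matrix(cell_states(sm$tissue), cfg$Ly, cfg$Lx, byrow = TRUE)
        write.table(grid, file.path(tmp, "snapshot.csv"), sep = ",",
                    row.names = FALSE, col.names = FALSE)
        list(n_perturb = n_perturb)
      } else {
        an <- anneal_sweep(tissue, params, cfg$q, vary = cfg$vary,
                           values = cfg$values, t_eq = cfg$t_eq,
                           t_sample = cfg$t_sample, basis = basis)
        write.csv(an$summary, file.path(tmp, "anneal.csv"), row.names = FALSE)
        list(n_perturb = NA_real_)
      }
    })
    n_perturb <- res$n_perturb
  } else {
    ctrl <- feedback_controller(T0 = cfg$T0, alpha = cfg$alpha,
                                dtau = cfg$dtau, T_min = cfg$T_min)
    if (cfg$mode == "selftune") {
      res <- run_selftuned(net, cfg$Lx, cfg$Ly, ctrl, q = cfg$q,
                           n_mc = cfg$n_mc, steps = cfg$steps,
                           seed = cfg$seed, J = cfg$J,
                           record_G_every = cfg$record_G_every)
      thin <- res$steps_recorded
      df <- data.frame(t = thin, T = res$T_trace[thin], M_t = res$M_t[thin],
                       mean_state = res$mean_state)
      write.csv(df, file.path(tmp, "selftune_trace.csv"), row.names = FALSE)
    } else {
      ens <- replicate_ensemble(net, cfg$Lx, cfg$Ly, ctrl, q = cfg$q,
                                n_mc = cfg$n_mc, steps = cfg$steps,
                                n_reps = cfg$n_reps, base_seed = cfg$base_seed,
                                checkpoints = cfg$checkpoints %||% cfg$steps,
                                J = cfg$J,
                                record_G_every = cfg$record_G_every)
      df <- data.frame(replicate = seq_along(ens$final_M),
                       final_M = ens$final_M, final_T = ens$final_T,
                       mean_abs_M_late = ens$mean_abs_M_late)
      write.csv(cbind(df, ens$mean_state), file.path(tmp, "ensemble.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(n_reps = length(ens$final_M),
             split_positive = sum(ens$final_M > 0),
             mean_final_T = mean(ens$final_T)),
        file.path(tmp, "ensemble_summary.json"), auto_unbox = TRUE, digits = NA)
    }
    n_perturb <- NA_real_
  }
  log <- list(seed = cfg$seed, mode = cfg$mode,
              package_version = as.character(utils::packageVersion("bntissue")),
              perturbation_events = n_perturb,
              elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(log, file.path(tmp, "log.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!file.rename(tmp, outdir))
    stop("could not finalize output directory ", outdir)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
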
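# Experiment driver: model construction from declarative specs, algorithm
# dispatch, error metrics, and reproducible trace files.

#' L2 error between two distributions
#'
#' Euclidean norm of the difference between the learned and reference
#' distributions, the accuracy measure used throughout the benchmark runs.
#'
#' @param est,ref numeric vectors of equal length.
#' @return Nonnegative scalar.
#' @export
l2_error <- function(est, ref) {
  if (length(est) != length(ref)) stop("length mismatch")
  sqrt(sum((est - ref)^2))
}

#' Build a benchmark kernel from a declarative model spec
#'
#' @param model list with a `name` in `"loopy"`, `"mm1"`, `"sis"`,
#'   `"random"`, or `"file"`, plus the model's parameters (`eps`, `m`; `N`,
#'   `rho`; `N`, `beta`, `gamma`; `n`, `leak`, `density`, `seed`; `path`).
#' @return A [sub_markov_kernel()].
#' @export
build_model <- function(model) {
  stopifnot(is.list(model), !is.null(model$name))
  switch(model$name,
    loopy = loopy_chain(model$eps, if (is.null(model$m)) 3L else model$m),
    mm1 = mm1_queue(queue_spec(model$N,
                               if (is.null(model$rho)) 1.25 else model$rho)),
    sis = sis_extinction_chain(model$N, model$beta, model$gamma),
    random = random_submarkov(model$n,
                              if (is.null(model$leak)) 1L else model$leak,
                              if (is.null(model$density)) 0.5 else model$density,
                              if (is.null(model$seed)) 1L else model$seed),
    file = read_kernel(model$path),
    stop(sprintf("unknown model '%s'; use loopy, mm1, sis, random or file",
                 model$name))
  )
}

#' Initial logits presets
#'
#' `"zeros"`; `"ramp:a,b"` (linear from `a` to `b` over the free logits);
#' `"tent:h,s,m"` (peak height `h`, slope `s`, centre state `m` -- a ramp up
#' then down, used for peaked targets); `"mm1-ramp"` (the benchmark constant
#' drift queue initialisation: linear from -35 towards 0 over the first
#' `n - 2` logits, last free logit 3); or a file of logits.
#'
#' @param spec preset string or path.
#' @param n number of states (logit vector has length `n - 1`).
#' @return Numeric vector of length `n - 1`.
#' @export
theta0_preset <- function(spec, n) {
  m <- n - 1L
  if (is.numeric(spec)) {
    if (length(spec) != m) stop("theta0 must have length n - 1")
    return(as.numeric(spec))
  }
  if (identical(spec, "zeros")) return(numeric(m))
  if (identical(spec, "mm1-ramp"))
    return(c(-35 + 35 / (m - 1) * (seq_len(m - 1) - 1), 3))
  if (startsWith(spec, "ramp:")) {
    ab <- as.numeric(strsplit(sub("^ramp:", "", spec), ",")[[1]])
    return(seq(ab[1], ab[2], length.out = m))
  }
  if (startsWith(spec, "tent:")) {
    hsm <- as.numeric(strsplit(sub("^tent:", "", spec), ",")[[1]])
    return(hsm[1] - hsm[2] * abs(seq_len(m) - hsm[3]))
  }
  if (file.exists(spec)) {
    v <- scan(spec, quiet = TRUE, comment.char = "#")
    if (length(v) != m) stop("theta0 file must contain n - 1 logits")
    return(v)
  }
  stop(sprintf("unknown theta0 preset '%s'", spec))
}

#' Run a reproducible experiment over several seeds
#'
#' Dispatches one of the five algorithms (`"ac"`, `"vanilla"`,
#' `"projection"`, `"polyak"`, `"fv"`) on a benchmark model, one run per
#' seed, writing a trace CSV per seed (with the fully resolved configuration
#' embedded as `#`-prefixed header lines) plus a summary table of final and
#' best errors.
#'
#' @param cfg list with elements `model` (see [build_model()]), `algorithm`,
#'   `params` (algorithm hyperparameters), `seeds` (integer vector),
#'   `out_dir` (optional; no files written when `NULL`), `label` (file-name
#'   stem).
#' @return Invisibly, a list with `summary` (data frame: seed, final and
#'   best error) and `fits` (per-seed fit objects).
#' @export
run_experiment <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$model), !is.null(cfg$algorithm))
  K <- build_model(cfg$model)
  seeds <- if (is.null(cfg$seeds)) 1L else as.integer(cfg$seeds)
  params <- if (is.null(cfg$params)) list() else cfg$params
  label <- if (is.null(cfg$label)) cfg$algorithm else cfg$label
  ref <- exact_qsd(K)$qsd
  fits <- vector("list", length(seeds))
  final_err <- best_err <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    fit <- .dispatch_algorithm(K, cfg$algorithm, params, seeds[i], ref)
    fits[[i]] <- fit
    errcol <- if ("l2_error" %in% names(fit$trace)) "l2_error" else "linf_error"
    final_err[i] <- fit$trace[[errcol]][nrow(fit$trace)]
    best_err[i] <- min(fit$trace[[errcol]])
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(cfg$out_dir, sprintf("%s_seed%d.csv", label, seeds[i]))
      .write_trace(path, fit$trace, c(
        list(model = .model_string(cfg$model), algorithm = cfg$algorithm,
             seed = seeds[i],
             package_version = as.character(utils::packageVersion("qsdlearn"))),
        params))
    }
  }
  summary <- data.frame(seed = seeds, final_error = final_err,
                        best_error = best_err)
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(summary,
                     file.path(cfg$out_dir, sprintf("%s_summary.csv", label)),
                     row.names = FALSE)
  }
  invisible(list(summary = summary, fits = fits, reference = ref))
}

.model_string <- function(model) {
  paste(vapply(names(model), function(k) {
    paste0(k, "=", paste(format(model[[k]], digits = 10), collapse = ";"))
  }, character(1)), collapse = " ")
}

.write_trace <- function(path, trace, header) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) {
    v <- header[[k]]
    if (inherits(v, "lr_schedule")) v <- attr(v, "spec")
    if (is.numeric(v) && length(v) > 6)
      v <- sprintf("<numeric[%d]>", length(v))
    writeLines(sprintf("# %s: %s", k, paste(format(v), collapse = ",")), con)
  }
  # canonical column layout: iteration,l2_error,r_est,kl_rate
  full <- data.frame(iteration = trace$iteration,
                     l2_error = if ("l2_error" %in% names(trace))
                       trace$l2_error else trace$linf_error,
                     r_est = if ("r_est" %in% names(trace))
                       trace$r_est else NA_real_,
                     kl_rate = if ("kl_rate" %in% names(trace))
                       trace$kl_rate else NA_real_)
  utils::write.csv(full, con, row.names = FALSE)
  invisible(path)
}

.dispatch_algorithm <- function(K, algorithm, params, seed, ref) {
  p <- params
  switch(algorithm,
    ac = {
      n <- K$n_states
      theta0 <- if (is.null(p$theta0)) numeric(n - 1)
                else theta0_preset(p$theta0, n)
      cfg <- ac_config(
        lr_theta = if (is.null(p$lr_theta)) "fpow:0.1,0.2" else p$lr_theta,
        lr_psi = if (is.null(p$lr_psi)) 1e-4 else p$lr_psi,
        lr_r = if (is.null(p$lr_r)) 1e-4 else p$lr_r,
        batch_size = if (is.null(p$batch_size)) 4L else p$batch_size,
        n_iterations = if (is.null(p$n_iterations)) 10000L else p$n_iterations,
        eval_every = if (is.null(p$eval_every)) 100L else p$eval_every,
        conditioning = if (is.null(p$conditioning)) "none" else p$conditioning,
        theta0 = theta0, psi0 = p$psi0,
        r0 = if (is.null(p$r0)) 0 else p$r0,
        seed = seed,
        track_kl = isTRUE(p$track_kl))
      run_actor_critic(K, cfg, reference = ref)
    },
    vanilla = run_vanilla(K,
      n_episodes = if (is.null(p$n_episodes)) 10000L else p$n_episodes,
      seed = seed, reference = ref),
    projection = run_projection(K,
      n_episodes = if (is.null(p$n_episodes)) 10000L else p$n_episodes,
      eps_n = if (is.null(p$eps_n)) "pow:0.99" else p$eps_n,
      seed = seed, reference = ref,
      normalized = isTRUE(p$normalized)),
    polyak = run_projection(K,
      n_episodes = if (is.null(p$n_episodes)) 10000L else p$n_episodes,
      eps_n = if (is.null(p$eps_n)) "pow:0.99" else p$eps_n,
      seed = seed, reference = ref,
      normalized = isTRUE(p$normalized), polyak = TRUE),
    fv = run_fleming_viot(K,
      n_particles = if (is.null(p$n_particles)) 1000L else p$n_particles,
      n_steps = if (is.null(p$n_steps)) 2000L else p$n_steps,
      seed = seed, reference = ref),
    stop(sprintf("unknown algorithm '%s'; use ac, vanilla, projection, polyak or fv",
                 algorithm))
  )
}

#' Log-log convergence slope of an error trace
#'
#' Least-squares slope of `log(error)` against `log(iteration)`, used to
#' check the `O(n^-1/2)` rate of the empirical scheme.
#'
#' @param trace data frame with `iteration` and an error column.
#' @param from discard evaluation points before this iteration (transient).
#' @return Scalar slope.
#' @export
loglog_slope <- function(trace, from = 10) {
  errcol <- setdiff(names(trace), "iteration")[1]
  keep <- trace$iteration >= from & trace[[errcol]] > 0
  x <- log(trace$iteration[keep])
  y <- log(trace[[errcol]][keep])
  unname(stats::coef(stats::lm(y ~ x))[2])
}
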
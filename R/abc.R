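#' Prior specification for one parameter
#'
#' Either a log-uniform prior over `[low, high]` (draws are `10^U` with `U`
#' uniform between the log10 bounds) or a point mass (a parameter fixed at
#' its estimated value).
#'
#' @param name Parameter name (e.g. `"d"`, `"e_leak"`, `"e_lys"`).
#' @param kind `"log_uniform"` or `"point"`.
#' @param low,high Bounds on the natural scale (log-uniform; must satisfy
#'   `0 < low < high`).
#' @param value Fixed value (point prior).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(name, kind = c("log_uniform", "point"),
                       low = NULL, high = NULL, value = NULL) {
  kind <- match.arg(kind)
  if (kind == "log_uniform") {
    stopifnot(!is.null(low), !is.null(high))
    if (low <= 0) stop("log-uniform priors need a positive lower bound")
    if (low >= high) stop("log-uniform priors need low < high")
  } else {
    stopifnot(!is.null(value))
  }
  structure(list(name = name, kind = kind, low = low, high = high,
                 value = value),
            class = "prior_spec")
}

#' Log-uniform prior spanning decades around a central value
#'
#' Builds the log-uniform prior whose log10 bounds are centred on
#' `log10(center)` and span `decades` orders of magnitude, e.g. one decade
#' around 3.88e-5 L/h gives log10 bounds -4.911 and -3.911.
#'
#' @param name Parameter name.
#' @param center Central value (natural scale).
#' @param decades Total width in orders of magnitude.
#' @return A [prior_spec()].
#' @export
prior_around <- function(name, center, decades = 1) {
  stopifnot(center > 0, decades > 0)
  prior_spec(name, "log_uniform",
             low = 10^(log10(center) - decades / 2),
             high = 10^(log10(center) + decades / 2))
}

#' @export
print.prior_spec <- function(x, ...) {
  if (x$kind == "point") {
    cat(sprintf("%s: point mass at %.6g\n", x$name, x$value))
  } else {
    cat(sprintf("%s: log-uniform on [%.6g, %.6g] (log10 %.3f to %.3f)\n",
                x$name, x$low, x$high, log10(x$low), log10(x$high)))
  }
  invisible(x)
}

#' Rejection-ABC configuration
#'
#' Bundles the priors, the observed statistic (mean and standard
#' deviation), the acceptance multiplier `k` and the statistic settings.
#' A draw is accepted when its simulated statistic lies within
#' `k * sd` of the observed mean — for `statistic_mode = "per_strain"`,
#' when that holds for *both* strains simultaneously.
#'
#' @param priors List of [prior_spec()]s.
#' @param observed For `mode = "mean"`, `list(mean =, sd =)`; for
#'   `per_strain`, `list(mean = c(dLys =, dIle =), sd = c(dLys =, dIle =))`.
#' @param k Acceptance multiplier (`> 0`; `Inf` accepts everything).
#' @param statistic_mode `"mean"` or `"per_strain"`.
#' @param t_statistic Yield comparison time, hours.
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(priors, observed, k,
                       statistic_mode = c("mean", "per_strain"),
                       t_statistic = 48) {
  statistic_mode <- match.arg(statistic_mode)
  stopifnot(k > 0, all(unlist(observed["sd"]) > 0))
  nm <- vapply(priors, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate prior names")
  names(priors) <- nm
  structure(list(priors = priors, observed = observed, k = k,
                 statistic_mode = statistic_mode,
                 t_statistic = t_statistic),
            class = "abc_config")
}

#' @export
print.abc_config <- function(x, ...) {
  cat(sprintf("Rejection-ABC config: %d priors, k = %g, mode = %s, t = %g h\n",
              length(x$priors), x$k, x$statistic_mode, x$t_statistic))
  for (p in x$priors) print(p)
  cat("observed mean:", paste(signif(unlist(x$observed$mean), 4),
                              collapse = ", "),
      " sd:", paste(signif(unlist(x$observed$sd), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Named ABC presets
#'
#' The three standard analyses, read from the YAML shipped in
#' `inst/extdata/abc_presets.yaml`:
#' \describe{
#'   \item{`equal`}{shared leakage stoichiometry for both strains.
#'     Diffusion prior: one decade of log-uniform centred on the measured
#'     mean amino-acid diffusion rate 3.88e-5 L/h (log10 bounds -4.911 to
#'     -3.911); leakage prior: log-uniform over 1e-2 to 10 mmol/gDW.
#'     Observed statistic 1.14 (sd 0.235), k = 2, mean mode.}
#'   \item{`unequal`}{independent lysine and isoleucine leakage priors
#'     (same 3-decade range), diffusion fixed at 3.88e-5 L/h. Per-strain
#'     observed statistics 0.925 (sd 0.015) and 1.35 (sd 0.026), k = 10,
#'     acceptance requires both strains.}
#'   \item{`noisy`}{as `equal`, but every literature-estimated kinetic
#'     parameter (all except the volumes) additionally gets a one-decade
#'     log-uniform prior around its default.}
#' }
#'
#' @param name `"equal"`, `"unequal"` or `"noisy"`.
#' @return An [abc_config()].
#' @export
abc_preset <- function(name = c("equal", "unequal", "noisy")) {
  name <- match.arg(name)
  path <- system.file("extdata", "abc_presets.yaml", package = "coculture",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)[[name]]
  priors <- lapply(y$priors, function(p) {
    if (identical(p$kind, "point")) {
      prior_spec(p$name, "point", value = as.numeric(p$value))
    } else {
      prior_spec(p$name, "log_uniform", low = as.numeric(p$low),
                 high = as.numeric(p$high))
    }
  })
  observed <- if (y$statistic_mode == "per_strain") {
    list(mean = c(dLys = y$observed$mean$dLys, dIle = y$observed$mean$dIle),
         sd = c(dLys = y$observed$sd$dLys, dIle = y$observed$sd$dIle))
  } else {
    list(mean = y$observed$mean, sd = y$observed$sd)
  }
  abc_config(priors, observed, k = y$k, statistic_mode = y$statistic_mode,
             t_statistic = y$t_statistic)
}

#' Draw parameter vectors from the prior
#'
#' Log-uniform parameters are drawn as `10^U`, `U` uniform on the log10
#' bounds; point parameters repeat their value. Uses R's RNG: call
#' `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param config An [abc_config()].
#' @param n Number of draws.
#' @param seed Optional integer seed applied before drawing.
#' @return A data frame, one column per parameter, `n` rows.
#' @export
sample_prior <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "abc_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(config$priors, function(p) {
    if (p$kind == "point") {
      rep(p$value, n)
    } else {
      10^stats::runif(n, log10(p$low), log10(p$high))
    }
  })
  as.data.frame(draws, col.names = names(config$priors))
}

#' Default simulator hook mapping a parameter draw to the statistic
#'
#' Builds the paired simulations (same-well positive control and
#' membrane-separated coculture) for one parameter vector and returns the
#' growth-ratio statistic. Recognised parameter names: `d`, `e_leak`
#' (shared leakage), `e_lys` / `e_ile` (leakage of that amino acid, carried
#' by the partner strain), and the literature kinetics `vmax_glc`,
#' `km_glc`, `vmax_aa`, `km_aa`, `y_glc`, `y_aa_dLys`, `y_aa_dIle`.
#'
#' @param config An [abc_config()] (for the statistic mode and time).
#' @param ... Overrides passed to [build_experiment()] (e.g. `aa_seed_mM`).
#' @return A function `params -> statistic` suitable for [run_rejection()].
#' @export
make_simulator_hook <- function(config, ...) {
  build_args <- list(...)
  t_stat <- config$t_statistic
  mode <- config$statistic_mode
  function(params) {
    params <- as.list(params)
    e_lys <- params$e_lys %||% params$e_leak %||% 1
    e_ile <- params$e_ile %||% params$e_leak %||% 1
    strain_args <- params[intersect(names(params),
                                    c("vmax_glc", "km_glc", "vmax_aa",
                                      "km_aa", "y_glc"))]
    strains <- do.call(default_strains,
                       c(list(e_lys = e_lys, e_ile = e_ile), strain_args))
    if (!is.null(params$y_aa_dLys)) strains$dLys$y_aa <- params$y_aa_dLys
    if (!is.null(params$y_aa_dIle)) strains$dIle$y_aa <- params$y_aa_dIle
    d <- params$d %||% 3.88e-5
    args <- c(list(strains = strains, d = d), build_args)
    sim <- function(scenario) {
      simulate_coculture(
        do.call(build_experiment, c(list(scenario = scenario), args)),
        t_end = t_stat, times = c(0, t_stat))
    }
    growth_ratio_statistic(sim("same_well_positive"),
                           sim("separated_coculture"),
                           t = t_stat, mode = mode)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rejection approximate Bayesian computation
#'
#' Draws `n` parameter vectors from the prior, simulates the statistic for
#' each, and accepts a draw when the simulated statistic lies within
#' `k * sd` of the observed mean (for per-strain mode: for both strains).
#' All draws are retained — accepted or not — so the prior, the posterior
#' and parameter-space maps of the statistic can all be read from the
#' result. A simulation failure marks the draw rejected with the error
#' recorded in `status`; it is never silently dropped.
#'
#' @param config An [abc_config()].
#' @param n Number of prior draws.
#' @param model Hook `params -> statistic`; defaults to
#'   [make_simulator_hook()] over the coculture model.
#' @param seed Optional integer seed.
#' @return An object of class `abc_posterior`: list with `draws` (data
#'   frame of parameters, statistic column(s) `S` or `S_dLys`/`S_dIle`,
#'   `accepted`, `status`), `config`, `acceptance_rate`.
#' @export
run_rejection <- function(config, n, model = NULL, seed = NULL) {
  stopifnot(inherits(config, "abc_config"))
  if (is.null(model)) model <- make_simulator_hook(config)
  draws <- sample_prior(config, n, seed = seed)
  per_strain <- config$statistic_mode == "per_strain"
  s_cols <- if (per_strain) c("S_dLys", "S_dIle") else "S"
  stat_mat <- matrix(NA_real_, n, length(s_cols),
                     dimnames = list(NULL, s_cols))
  accepted <- logical(n)
  status <- character(n)
  for (i in seq_len(n)) {
    s <- tryCatch(model(draws[i, , drop = FALSE]), error = function(e) e)
    if (inherits(s, "error")) {
      status[i] <- paste("error:", conditionMessage(s))
      accepted[i] <- FALSE
      next
    }
    stat_mat[i, ] <- as.numeric(s)
    accepted[i] <- abc_accepts(config, stat_mat[i, ])
    status[i] <- "ok"
  }
  out <- cbind(draws, as.data.frame(stat_mat))
  out$accepted <- accepted
  out$status <- status
  structure(list(draws = out, config = config,
                 acceptance_rate = mean(accepted)),
            class = "abc_posterior")
}

#' Acceptance rule of the rejection sampler
#'
#' @param config An [abc_config()].
#' @param statistic Simulated statistic (length 1, or 2 for per-strain).
#' @return `TRUE` when the draw would be accepted.
#' @export
abc_accepts <- function(config, statistic) {
  if (anyNA(statistic)) return(FALSE)
  m <- unlist(config$observed$mean)
  s <- unlist(config$observed$sd)
  all(abs(statistic - m) <= config$k * s)
}

#' @export
print.abc_posterior <- function(x, ...) {
  n_ok <- sum(x$draws$status == "ok")
  cat(sprintf(
    "Rejection-ABC posterior: %d draws (%d simulated ok), %d accepted (%.1f%%)\n",
    nrow(x$draws), n_ok, sum(x$draws$accepted), 100 * x$acceptance_rate))
  invisible(x)
}

#' Posterior summary table
#'
#' Per free (non-point) parameter: posterior median and central 50% / 95%
#' intervals on the log10 scale, from the accepted draws. With no accepted
#' draws the intervals are `NA` and the acceptance rate is zero.
#'
#' @param object An [run_rejection()] result.
#' @param ... Unused.
#' @return An object of class `summary.abc_posterior`: list with `table`
#'   (data frame) and `acceptance_rate`.
#' @export
summary.abc_posterior <- function(object, ...) {
  free <- names(Filter(function(p) p$kind != "point", object$config$priors))
  acc <- object$draws[object$draws$accepted, , drop = FALSE]
  rows <- lapply(free, function(p) {
    if (nrow(acc) == 0) {
      data.frame(parameter = p, n_accepted = 0L, log10_median = NA_real_,
                 log10_q25 = NA_real_, log10_q75 = NA_real_,
                 log10_q2.5 = NA_real_, log10_q97.5 = NA_real_)
    } else {
      q <- stats::quantile(log10(acc[[p]]),
                           c(0.5, 0.25, 0.75, 0.025, 0.975), names = FALSE)
      data.frame(parameter = p, n_accepted = nrow(acc), log10_median = q[1],
                 log10_q25 = q[2], log10_q75 = q[3],
                 log10_q2.5 = q[4], log10_q97.5 = q[5])
    }
  })
  structure(list(table = do.call(rbind, rows),
                 acceptance_rate = object$acceptance_rate),
            class = "summary.abc_posterior")
}

#' @export
print.summary.abc_posterior <- function(x, ...) {
  cat(sprintf("Acceptance rate: %.2f%%\n", 100 * x$acceptance_rate))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter-space map of the simulated statistic
#'
#' All (parameter, parameter, statistic) triples for two chosen free
#' parameters — the scatter underlying a heat-map of the statistic over
#' the prior box.
#'
#' @param post An [run_rejection()] result.
#' @param x_param,y_param Parameter names; default the first two free
#'   parameters.
#' @return Data frame with the two parameter columns, the statistic
#'   column(s), and `accepted`.
#' @export
statistic_map <- function(post, x_param = NULL, y_param = NULL) {
  stopifnot(inherits(post, "abc_posterior"))
  free <- names(Filter(function(p) p$kind != "point", post$config$priors))
  if (is.null(x_param)) x_param <- free[1]
  if (is.null(y_param)) y_param <- free[min(2, length(free))]
  s_cols <- grep("^S", names(post$draws), value = TRUE)
  post$draws[, c(x_param, y_param, s_cols, "accepted")]
}

#' @export
plot.abc_posterior <- function(x, param = NULL, ...) {
  free <- names(Filter(function(p) p$kind != "point", x$config$priors))
  if (is.null(param)) param <- free[length(free)]
  all_lg <- log10(x$draws[[param]])
  acc_lg <- log10(x$draws[[param]][x$draws$accepted])
  brks <- seq(min(all_lg), max(all_lg), length.out = 25)
  h_all <- graphics::hist(all_lg, breaks = brks, plot = FALSE)
  h_acc <- if (length(acc_lg) > 0) {
    graphics::hist(acc_lg, breaks = brks, plot = FALSE)
  } else NULL
  graphics::plot(h_all, col = grDevices::grey(0.8, 0.7), border = NA,
                 xlab = bquote(log[10] ~ .(param)),
                 main = "prior (grey) vs posterior (gold)", ...)
  if (!is.null(h_acc)) {
    graphics::plot(h_acc, col = grDevices::adjustcolor("goldenrod", 0.8),
                   border = NA, add = TRUE)
  }
  invisible(x)
}
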
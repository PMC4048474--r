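# Replicate ensembles, senescence summaries, histograms, Gompertz fitting.

#' Senescence summary of one simulation
#'
#' @param sim A `telo_sim` (or its trajectory data frame).
#' @return List with `pd_first` (population doublings when the first
#'   senescent cell appears in the tracked sample; NA if none appeared),
#'   `final_pd` and `final_g` (doublings/generation at full senescence),
#'   `mean_length_at_senescence` (tracked-sample mean telomere length at
#'   that generation) and `censored` (TRUE when the run ended before full
#'   senescence, in which case the final quantities are NA rather than
#'   silent zeros).
#' @export
senescence_summary <- function(sim) {
  tr <- if (inherits(sim, "telo_sim")) sim$trajectory else sim
  stopifnot(is.data.frame(tr), nrow(tr) >= 1L)
  first <- which(tr$n_senescent >= 1L)[1L]
  last <- tr[nrow(tr), ]
  censored <- last$phi_sen < 1
  list(
    pd_first = if (is.na(first)) NA_real_ else tr$pd[first],
    final_pd = if (censored) NA_real_ else last$pd,
    final_g = if (censored) NA_integer_ else last$g,
    mean_length_at_senescence = if (censored) NA_real_ else last$mean_length,
    censored = censored
  )
}

#' Run a replicate ensemble
#'
#' Runs `R` independent simulations of the same configuration, replicate
#' `i` seeded with `base_seed + i - 1`, and aggregates them.  Trajectories
#' are aligned on generation number; replicates that senesce early are
#' extended by their final (plateau) record so every generation averages
#' over all `R` replicates.
#'
#' @param config A [sim_config()].
#' @param R Number of replicates (>= 2, so dispersions are defined).
#' @param base_seed Seed of the first replicate (default `config$seed`).
#' @return Object of class `telo_ensemble`: list with `per_generation`
#'   (data frame of ensemble mean and sd per generation for mean_length,
#'   mean_shortest, phi_div, phi_pot, phi_sen, pd, notional_N),
#'   `senescence` (per-replicate summary data frame), `summary` (ensemble
#'   mean/sd/standard error of pd_first, final_pd, final_g and mean length
#'   at senescence over uncensored replicates, plus the censored count),
#'   `trajectories` (list of per-replicate trajectories), `R`, `config`.
#' @export
run_ensemble <- function(config, R = config$replicates,
                         base_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(R) || R < 2) stop("`R` must be at least 2")
  R <- as.integer(R)
  sims <- vector("list", R)
  for (i in seq_len(R))
    sims[[i]] <- run_simulation(config, seed = base_seed + i - 1L)
  trajs <- lapply(sims, `[[`, "trajectory")

  G <- max(vapply(trajs, nrow, 1L))
  vars <- c("mean_length", "mean_shortest", "phi_div", "phi_pot", "phi_sen",
            "pd", "notional_N")
  pad <- function(tr, v) {
    x <- tr[[v]]
    c(x, rep(x[length(x)], G - length(x)))
  }
  per_gen <- data.frame(g = seq_len(G) - 1L)
  for (v in vars) {
    M <- vapply(trajs, pad, numeric(G), v = v)   # G x R
    per_gen[[paste0("mean_", v)]] <- rowMeans(M)
    per_gen[[paste0("sd_", v)]] <- apply(M, 1L, stats::sd)
  }

  sen <- do.call(rbind, lapply(seq_len(R), function(i) {
    s <- senescence_summary(sims[[i]])
    data.frame(replicate = i, seed = base_seed + i - 1L,
               pd_first = s$pd_first, final_pd = s$final_pd,
               final_g = s$final_g,
               mean_length_at_senescence = s$mean_length_at_senescence,
               censored = s$censored)
  }))

  msd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(mean = NA_real_, sd = NA_real_,
                                  se = NA_real_))
    c(mean = mean(x), sd = stats::sd(x),
      se = stats::sd(x) / sqrt(length(x)))
  }
  summary <- list(pd_first = msd(sen$pd_first),
                  final_pd = msd(sen$final_pd),
                  final_g = msd(sen$final_g),
                  mean_length_at_senescence =
                    msd(sen$mean_length_at_senescence),
                  n_censored = sum(sen$censored))

  structure(list(per_generation = per_gen, senescence = sen,
                 summary = summary, trajectories = trajs, R = R,
                 config = config, base_seed = base_seed),
            class = "telo_ensemble")
}

#' @export
print.telo_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("telomere ensemble: R = %d replicates (%d censored)\n",
              x$R, s$n_censored))
  fmt <- function(nm, v) if (!is.na(v[["mean"]]))
    cat(sprintf("  %-28s %.2f (sd %.2f)\n", nm, v[["mean"]], v[["sd"]]))
  fmt("pd at first senescence:", s$pd_first)
  fmt("final pd:", s$final_pd)
  fmt("mean length at senescence:", s$mean_length_at_senescence)
  invisible(x)
}

#' Ensemble profile on a population-doubling grid
#'
#' Interpolates a trajectory variable of every replicate onto a common
#' population-doubling grid (constant extrapolation at the ends) and
#' averages across replicates, for plots indexed by pd rather than
#' generation.
#'
#' @param ens A [run_ensemble()] result.
#' @param var Trajectory column to profile (default `"mean_length"`).
#' @param pd_grid Numeric grid of population doublings; default 200 points
#'   spanning the ensemble.
#' @return Data frame with columns `pd`, `mean`, `sd`.
#' @export
ensemble_on_pd <- function(ens, var = "mean_length", pd_grid = NULL) {
  stopifnot(inherits(ens, "telo_ensemble"))
  if (is.null(pd_grid)) {
    top <- max(vapply(ens$trajectories, function(tr) max(tr$pd), 0))
    pd_grid <- seq(0, top, length.out = 200L)
  }
  M <- vapply(ens$trajectories, function(tr)
    stats::approx(tr$pd, tr[[var]], xout = pd_grid, rule = 2,
                  ties = "ordered")$y,
    numeric(length(pd_grid)))
  data.frame(pd = pd_grid, mean = rowMeans(M), sd = apply(M, 1L, stats::sd))
}

#' Telomere-length histogram of a population snapshot
#'
#' Bins either the per-cell mean telomere length or the per-cell shortest
#' telomere over the tracked sample.
#'
#' @param pop A `telo_population` (e.g. a [run_simulation()] snapshot).
#' @param mode `"mean"` or `"shortest"`.
#' @param bin_width Bin width in bp (> 0), default 100.
#' @param generation Optional generation label carried in the result.
#' @return Object of class `telo_histogram`: list with `breaks`, `mid`,
#'   `counts` (integers summing to the number of tracked cells), `mode`,
#'   `bin_width`, `generation`.
#' @export
telomere_histogram <- function(pop, mode = c("mean", "shortest"),
                               bin_width = 100, generation = NA_integer_) {
  stopifnot(inherits(pop, "telo_population"))
  mode <- match.arg(mode)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be positive")
  v <- if (mode == "mean") cell_mean(pop) else cell_min(pop)
  hi <- max(6000, bin_width * (floor(max(v) / bin_width) + 1L))
  breaks <- seq(0, hi, by = bin_width)
  counts <- as.integer(table(cut(v, breaks = breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(breaks = breaks, mid = breaks[-1L] - bin_width / 2,
                 counts = counts, mode = mode, bin_width = bin_width,
                 generation = generation),
            class = "telo_histogram")
}

#' Count modes of a telomere-length histogram
#'
#' Operationalizes "bimodal": bins with fewer than `min_count` cells are
#' treated as empty, and a mode is a (plateau-merged) local maximum of the
#' remaining counts.
#'
#' @param hist A [telomere_histogram()].
#' @param min_count Minimum occupancy for a bin to count (default 2).
#' @return Integer number of modes.
#' @export
histogram_modes <- function(hist, min_count = 2L) {
  stopifnot(inherits(hist, "telo_histogram"))
  x <- hist$counts
  x[x < min_count] <- 0L
  x <- c(0L, x, 0L)
  n_modes <- 0L
  rising <- FALSE
  for (i in 2L:length(x)) {
    if (x[i] > x[i - 1L]) rising <- TRUE
    if (x[i] < x[i - 1L]) {
      if (rising) n_modes <- n_modes + 1L
      rising <- FALSE
    }
  }
  n_modes
}

#' Fit a Gompertz growth law
#'
#' Fits `N(t) = a * exp(-b * exp(-c * t))` to population sizes by nonlinear
#' least squares on the log scale (sizes span many orders of magnitude).
#' Starting values come from linearizing `log(log(a / N))`; the fit itself
#' uses Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param t Time points (e.g. generation numbers); at least 4.
#' @param n Population sizes (> 0).
#' @return List with `a`, `b`, `c` (all > 0), `residual` (residual sum of
#'   squares of log N), `r_squared` (on log N), and `fitted`.
#'   Non-convergence raises an error carrying the optimizer diagnostics.
#' @export
#' @examples
#' t <- 0:80
#' n <- 1000 * exp(-5 * exp(-0.05 * t))
#' unlist(gompertz_fit(t, n)[c("a", "b", "c")])
gompertz_fit <- function(t, n) {
  stopifnot(is.numeric(t), is.numeric(n), length(t) == length(n))
  if (length(t) < 4L) stop("need at least 4 points for a Gompertz fit")
  if (any(n <= 0)) stop("population sizes must be positive")
  logn <- log(n)
  a0 <- max(n) * 1.05
  w <- which(n < a0 & log(a0 / n) > 1e-12)
  z <- log(log(a0 / n[w]))
  lin <- stats::lm(z ~ t[w])
  b0 <- exp(stats::coef(lin)[[1L]])
  c0 <- max(-stats::coef(lin)[[2L]], 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(logn ~ log(a) - b * exp(-cc * t),
                      start = list(a = a0, b = b0, cc = c0),
                      lower = c(a = max(n), b = 1e-12, cc = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Gompertz fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  fitted <- log(cf[["a"]]) - cf[["b"]] * exp(-cf[["cc"]] * t)
  rss <- sum((logn - fitted)^2)
  tss <- sum((logn - mean(logn))^2)
  list(a = cf[["a"]], b = cf[["b"]], c = cf[["cc"]], residual = rss,
       r_squared = 1 - rss / tss, fitted = exp(fitted))
}
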
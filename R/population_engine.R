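# Population-level simulation engine.
#
# A population holds k individuals ("cells"), each a fixed block of N
# chromosomes; the chromosome-level model is the special case N = 1.  State
# is a (k*N) x 4 matrix of telomere lengths with rows grouped by cell, so
# all per-generation work is vectorized over rows.
#
# Random-number consumption per generation (one base-R stream, so runs are
# reproducible given a seed):
#   1. one uniform per non-senescent cell (division draw, in cell order);
#   2. if p_w > 0, one uniform per chromosome of each attempting cell
#      (replication event, in row order);
#   3. one uniform per Werner event (variant choice);
#   4. one uniform per chromosome of each dividing cell (daughter
#      allocation coin);
#   5. the passaging subsample, if the cap is exceeded.

#' Create a population of cells
#'
#' @param quartet Initial telomere quartet given to every chromosome (see
#'   [chromosome_quartet()]).
#' @param n_chromosomes Chromosomes per cell (1 for the chromosome-level
#'   model, 46 for a human cell).
#' @param n_cells Number of starting cells (default 1).
#' @return An object of class `telo_population`: list with `Q` (the
#'   `(n_cells * n_chromosomes) x 4` length matrix) and `N` (chromosomes
#'   per cell).
#' @export
new_population <- function(quartet, n_chromosomes = 1L, n_cells = 1L) {
  q <- unclass(as_quartet(quartet))
  stopifnot(n_chromosomes >= 1L, n_cells >= 1L)
  Q <- matrix(rep(q, each = n_cells * n_chromosomes), ncol = 4L)
  colnames(Q) <- c("top_left", "top_right", "bottom_left", "bottom_right")
  structure(list(Q = Q, N = as.integer(n_chromosomes)),
            class = "telo_population")
}

#' Number of cells tracked in a population
#' @param pop A `telo_population`.
#' @return Integer count.
#' @export
n_cells <- function(pop) nrow(pop$Q) %/% pop$N

# per-cell summaries ---------------------------------------------------------

cell_min <- function(pop) {
  rmin <- pmin(pop$Q[, 1L], pop$Q[, 2L], pop$Q[, 3L], pop$Q[, 4L])
  if (pop$N == 1L) rmin else apply(matrix(rmin, nrow = pop$N), 2L, min)
}

cell_mean <- function(pop) {
  rmean <- (pop$Q[, 1L] + pop$Q[, 2L] + pop$Q[, 3L] + pop$Q[, 4L]) / 4
  if (pop$N == 1L) rmean else colMeans(matrix(rmean, nrow = pop$N))
}

#' Advance a population by one generation
#'
#' Classifies every cell and applies the division rules: a cell with any
#' telomere below the threshold is senescent and retained unchanged; a
#' non-senescent cell divides with probability `P_div(n_bar)` evaluated at
#' its mean telomere length; a cell that attempts division samples one
#' replication event per chromosome (normal or a Werner deletion variant)
#' and, if any chromosome's event is infeasible, the whole cell is retained
#' unchanged (classified "potential") and may try again next generation.
#' When a cell divides, each chromosome's two daughter quartets are
#' allocated to the two daughter cells independently and uniformly at
#' random (2^N possible allocations).
#'
#' @param pop A [new_population()].
#' @param models A [model_set()].
#' @return List with `pop` (post-division population; dividing cells are
#'   replaced in place by their two daughters), `counts` (named integer
#'   vector: divided, potential, senescent), and `stats` (pre-division
#'   tracked-sample statistics: `mean_length`, `sd_length`,
#'   `mean_shortest`).
#' @export
step_population <- function(pop, models) {
  stopifnot(inherits(pop, "telo_population"), inherits(models, "telo_models"))
  N <- pop$N
  Q <- pop$Q
  k <- nrow(Q) %/% N
  if (k == 0L) stop("empty population")

  cmin <- cell_min(pop)
  cmean <- cell_mean(pop)
  stats <- c(mean_length = mean(cmean),
             sd_length = if (k > 1L) stats::sd(cmean) else 0,
             mean_shortest = mean(cmin))

  sen <- cmin < models$threshold
  status <- integer(k)              # 0 senescent, 1 potential, 2 divided
  status[!sen] <- 1L
  ns <- which(!sen)

  attempt <- integer(0)
  if (length(ns) > 0L) {
    u <- stats::runif(length(ns))
    attempt <- ns[u < p_div(cmean[ns], models$division)]
  }

  D1 <- D2 <- NULL
  dv <- integer(0)
  if (length(attempt) > 0L) {
    arows <- as.vector(outer(seq_len(N), (attempt - 1L) * N, `+`))
    nA <- length(arows)
    pw <- models$werner$p_w
    x <- models$werner$x
    variant <- integer(nA)
    if (pw > 0) {
      w <- stats::runif(nA) < pw
      nw <- sum(w)
      if (nw > 0L) variant[w] <- as.integer(floor(stats::runif(nw) * 4)) + 1L
    }
    tl <- Q[arows, 1L]; tr <- Q[arows, 2L]
    bl <- Q[arows, 3L]; br <- Q[arows, 4L]

    # daughters under normal aging, then variant-specific deletions; a
    # deletion leaving any telomere at the deleted end below the critical
    # length is infeasible and blocks the whole division
    flo <- if (is.null(models$werner_floor)) models$threshold
           else models$werner_floor
    y_tr <- loss_y(tr, models$loss)
    y_bl <- loss_y(bl, models$loss)
    ID <- cbind(tl, tr, tl, pmax(tr - y_tr, 0))
    SH <- cbind(pmax(bl - y_bl, 0), br, bl, br)
    feas <- rep(TRUE, nA)
    zero_x <- x <= 0   # deletion-free variants reduce to normal replication
    v1 <- variant == 1L & !zero_x; v2 <- variant == 2L & !zero_x
    v3 <- variant == 3L & !zero_x; v4 <- variant == 4L & !zero_x
    if (any(v1)) {
      cmpl <- tr[v1] - x - loss_y(pmax(tr[v1] - x, 0), models$loss)
      feas[v1] <- tr[v1] - x >= flo & cmpl >= flo
      ID[v1, 2L] <- tr[v1] - x
      ID[v1, 4L] <- cmpl
    }
    if (any(v2)) {
      feas[v2] <- tl[v2] - x >= flo
      ID[v2, 1L] <- ID[v2, 3L] <- tl[v2] - x
    }
    if (any(v3)) {
      feas[v3] <- br[v3] - x >= flo
      SH[v3, 2L] <- SH[v3, 4L] <- br[v3] - x
    }
    if (any(v4)) {
      cmpl <- bl[v4] - x - loss_y(pmax(bl[v4] - x, 0), models$loss)
      feas[v4] <- bl[v4] - x >= flo & cmpl >= flo
      SH[v4, 1L] <- cmpl
      SH[v4, 3L] <- bl[v4] - x
    }

    cell_ok <- if (N == 1L) feas else colSums(matrix(!feas, nrow = N)) == 0L
    dv <- attempt[cell_ok]
    status[dv] <- 2L
    if (length(dv) > 0L) {
      drows <- rep(cell_ok, each = N)
      IDd <- ID[drows, , drop = FALSE]
      SHd <- SH[drows, , drop = FALSE]
      coin <- stats::runif(nrow(IDd)) < 0.5
      D1 <- SHd; D1[!coin, ] <- IDd[!coin, ]
      D2 <- IDd; D2[!coin, ] <- SHd[!coin, ]
    }
  }

  counts <- c(divided = length(dv),
              potential = k - length(dv) - sum(sen),
              senescent = sum(sen))

  # assemble the next population: dividing cells are replaced in place by
  # their two daughters (first daughter first), all other cells keep order
  if (length(dv) == 0L) {
    newQ <- Q
  } else {
    reps <- rep(1L, k); reps[dv] <- 2L
    start <- cumsum(reps) - reps + 1L
    newQ <- matrix(0, sum(reps) * N, 4L)
    nd <- which(status != 2L)
    if (length(nd) > 0L) {
      src <- as.vector(outer(seq_len(N), (nd - 1L) * N, `+`))
      dst <- as.vector(outer(seq_len(N), (start[nd] - 1L) * N, `+`))
      newQ[dst, ] <- Q[src, ]
    }
    dst1 <- as.vector(outer(seq_len(N), (start[dv] - 1L) * N, `+`))
    newQ[dst1, ] <- D1
    newQ[dst1 + N, ] <- D2
    colnames(newQ) <- colnames(Q)
  }

  list(pop = structure(list(Q = newQ, N = N), class = "telo_population"),
       counts = counts, stats = stats)
}

#' Passage a population down to a tracking cap
#'
#' Mimics experimental passaging: when more than `cap` cells are tracked, a
#' uniform without-replacement sample of `cap` cells is retained (in their
#' original relative order).  The notional population size is unaffected.
#'
#' @param pop A `telo_population`.
#' @param cap Maximum number of tracked cells (>= 1).
#' @return The (possibly subsampled) population.
#' @export
passage <- function(pop, cap) {
  stopifnot(inherits(pop, "telo_population"), cap >= 1L)
  k <- n_cells(pop)
  if (k <= cap) return(pop)
  keep <- sort(sample.int(k, cap))
  rows <- as.vector(outer(seq_len(pop$N), (keep - 1L) * pop$N, `+`))
  pop$Q <- pop$Q[rows, , drop = FALSE]
  pop
}

#' Generation accounting
#'
#' Converts the classification counts of one generation into the dividing,
#' potential and senescent fractions, propagates the notional population
#' size `N(g+1) = (1 + phi_div(g)) N(g)`, and computes population
#' doublings `pd = log2(N(g) / N(0))`.  The notional size keeps growing by
#' the sampled dividing fraction even while the tracked sample is capped by
#' passaging.
#'
#' @param state List with `notional_N` (current notional size, > 0) and
#'   `initial_N0` (size at generation 0).
#' @param counts Named vector from [step_population()] (divided, potential,
#'   senescent).
#' @return List with `phi_div`, `phi_pot`, `phi_sen`, `pd` (doublings at
#'   the current generation) and `notional_next`.
#' @export
accounting_update <- function(state, counts) {
  total <- sum(counts)
  if (total <= 0) stop("empty classification")
  if (!is.numeric(state$notional_N) || state$notional_N <= 0)
    stop("notional population size must be positive")
  phi_div <- counts[["divided"]] / total
  phi_sen <- counts[["senescent"]] / total
  phi_pot <- 1 - phi_div - phi_sen
  list(phi_div = phi_div, phi_pot = phi_pot, phi_sen = phi_sen,
       pd = log2(state$notional_N / state$initial_N0),
       notional_next = (1 + phi_div) * state$notional_N)
}

#' Run one telomere-shortening simulation
#'
#' Iterates classification, division, accounting and passaging until every
#' tracked cell is senescent or the generation budget is exhausted.  Each
#' trajectory row reports the tracked-sample state at generation `g`
#' (before that generation's divisions) together with the fractions
#' classified in the `g -> g+1` step, so `pd` equals `g` exactly while all
#' cells divide every generation.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`); identical config and
#'   seed give an identical trajectory.
#' @return Object of class `telo_sim`: list with `trajectory` (data frame
#'   with columns g, notional_N, pd, mean_length, sd_length, mean_shortest,
#'   phi_div, phi_pot, phi_sen, n_divided, n_potential, n_senescent,
#'   n_tracked), `population` (final tracked population), `snapshots`
#'   (populations at `config$snapshot_at` generations), `censored` (TRUE if
#'   the budget ran out before full senescence), `config`, `seed`.
#' @export
#' @examples
#' cfg <- sim_config(model = "chromosome", case = "A1", max_generations = 30)
#' run_simulation(cfg, seed = 1)$trajectory[1:3, 1:6]
run_simulation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pop <- new_population(config$initial_quartet, config$chromosomes,
                        config$initial_cells)
  models <- config$models
  state <- list(notional_N = config$initial_cells,
                initial_N0 = config$initial_cells)
  snapshots <- list()
  rows <- vector("list", config$max_generations + 1L)
  g <- 0L
  censored <- TRUE
  # a fully senescent population is frozen, but keep iterating far enough
  # to take any requested late snapshots
  last_snap <- if (length(config$snapshot_at)) max(config$snapshot_at) else -1L
  repeat {
    if (g %in% config$snapshot_at) snapshots[[as.character(g)]] <- pop
    st <- step_population(pop, models)
    acc <- accounting_update(state, st$counts)
    rows[[g + 1L]] <- data.frame(
      g = g, notional_N = state$notional_N, pd = acc$pd,
      mean_length = st$stats[["mean_length"]],
      sd_length = st$stats[["sd_length"]],
      mean_shortest = st$stats[["mean_shortest"]],
      phi_div = acc$phi_div, phi_pot = acc$phi_pot, phi_sen = acc$phi_sen,
      n_divided = st$counts[["divided"]],
      n_potential = st$counts[["potential"]],
      n_senescent = st$counts[["senescent"]],
      n_tracked = sum(st$counts))
    if (acc$phi_sen >= 1 && g >= last_snap) { censored <- FALSE; break }
    if (g >= config$max_generations) break
    state$notional_N <- acc$notional_next
    pop <- passage(st$pop, config$passage_cap)
    g <- g + 1L
  }
  structure(list(trajectory = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                 population = pop, snapshots = snapshots,
                 censored = censored, config = config, seed = seed),
            class = "telo_sim")
}

#' @export
print.telo_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat(sprintf(
    "telomere simulation: %d generations, final pd %.1f, phi_sen %.2f%s\n",
    last$g, last$pd, last$phi_sen,
    if (x$censored) " (censored: generation budget reached)" else ""))
  invisible(x)
}

#' @export
print.telo_population <- function(x, ...) {
  cat(sprintf("telomere population: %d cells x %d chromosomes\n",
              n_cells(x), x$N))
  invisible(x)
}
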
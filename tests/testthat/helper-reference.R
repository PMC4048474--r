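# A plain-loop reference engine built from the exported per-chromosome
# operations.  It consumes the RNG stream in the same documented order as
# step_population() (division draws, then replication events, then variant
# choices, then allocation coins, then passaging), so matched seeds must
# reproduce the vectorized engine exactly.

ref_cells <- function(pop) {
  N <- pop$N
  lapply(seq_len(nrow(pop$Q) %/% N), function(j)
    pop$Q[((j - 1L) * N + 1L):(j * N), , drop = FALSE])
}

ref_step <- function(cells, N, models) {
  k <- length(cells)
  cmin <- vapply(cells, min, 0)
  cmean <- vapply(cells, mean, 0)
  sen <- cmin < models$threshold
  ns <- which(!sen)
  attempt <- integer(0)
  if (length(ns)) {
    u <- stats::runif(length(ns))
    attempt <- ns[u < p_div(cmean[ns], models$division)]
  }
  pw <- models$werner$p_w
  x <- models$werner$x
  events <- vector("list", k)
  if (length(attempt)) {
    variants <- matrix(0L, N, length(attempt))
    if (pw > 0) {
      # phase 2: event draw for every chromosome of every attempting cell
      isw <- matrix(stats::runif(length(attempt) * N) < pw, nrow = N)
      # phase 3: variant draws for Werner events, in cell-major order
      if (any(isw))
        variants[isw] <- as.integer(floor(stats::runif(sum(isw)) * 4)) + 1L
    }
    for (j in seq_along(attempt)) events[[attempt[j]]] <- variants[, j]
  }
  out <- list()
  status <- integer(k)
  status[!sen] <- 1L
  daughters <- vector("list", k)
  for (i in attempt) {
    ok <- TRUE
    ds <- vector("list", N)
    for (c in seq_len(N)) {
      v <- events[[i]][c]
      if (v == 0L) {
        ds[[c]] <- replicate_normal(cells[[i]][c, ], models$loss)
      } else {
        o <- replicate_werner(cells[[i]][c, ], models$loss, x, v,
                              floor = models$werner_floor)
        if (!o$divided) { ok <- FALSE } else ds[[c]] <- o$daughters
      }
    }
    if (ok) {
      status[i] <- 2L
      daughters[[i]] <- ds
    }
  }
  for (i in seq_len(k)) {
    if (status[i] != 2L) {
      out[[length(out) + 1L]] <- cells[[i]]
    } else {
      coin <- stats::runif(N) < 0.5
      d1 <- d2 <- matrix(0, N, 4L)
      for (c in seq_len(N)) {
        if (coin[c]) {
          d1[c, ] <- unclass(daughters[[i]][[c]]$shorter)
          d2[c, ] <- unclass(daughters[[i]][[c]]$identical)
        } else {
          d1[c, ] <- unclass(daughters[[i]][[c]]$identical)
          d2[c, ] <- unclass(daughters[[i]][[c]]$shorter)
        }
      }
      out[[length(out) + 1L]] <- d1
      out[[length(out) + 1L]] <- d2
    }
  }
  list(cells = out,
       counts = c(divided = sum(status == 2L),
                  potential = sum(status == 1L),
                  senescent = sum(status == 0L)))
}

ref_run <- function(config, seed, generations) {
  set.seed(seed)
  pop <- new_population(config$initial_quartet, config$chromosomes,
                        config$initial_cells)
  cells <- ref_cells(pop)
  N <- config$chromosomes
  models <- config$models
  traj <- list()
  for (g in seq_len(generations)) {
    st <- ref_step(cells, N, models)
    cells <- st$cells
    if (length(cells) > config$passage_cap) {
      keep <- sort(sample.int(length(cells), config$passage_cap))
      cells <- cells[keep]
    }
    traj[[g]] <- st$counts
    if (st$counts[["senescent"]] == sum(st$counts)) break
  }
  list(cells = cells, counts = do.call(rbind, traj))
}

# flatten a reference cell list back into an engine-layout matrix
ref_matrix <- function(cells) do.call(rbind, cells)

# run the vectorized engine for a fixed number of generations, mirroring
# ref_run's loop structure
engine_run <- function(config, seed, generations) {
  set.seed(seed)
  pop <- new_population(config$initial_quartet, config$chromosomes,
                        config$initial_cells)
  traj <- list()
  for (g in seq_len(generations)) {
    st <- step_population(pop, config$models)
    pop <- passage(st$pop, config$passage_cap)
    traj[[g]] <- st$counts
    if (st$counts[["senescent"]] == sum(st$counts)) break
  }
  list(pop = pop, counts = do.call(rbind, traj))
}
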
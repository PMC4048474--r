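small_cfg <- function(...) {
  sim_config(model = "chromosome", case = "A1", ...)
}

test_that("a single dividing chromosome yields one identical and one shorter daughter", {
  set.seed(1)
  pop <- new_population(c(6000, 6000, 6000, 5800))
  st <- step_population(pop, preset_case("A1"))
  expect_equal(n_cells(st$pop), 2L)
  expect_equal(unname(st$counts), c(1L, 0L, 0L))
  rows <- lapply(seq_len(2), function(i) unname(st$pop$Q[i, ]))
  expect_true(any(vapply(rows, identical, TRUE, y = c(6000, 6000, 6000, 5800))))
  expect_true(any(vapply(rows, identical, TRUE, y = c(5800, 5800, 6000, 5800))))
})

test_that("a threshold above every telomere freezes the population at once", {
  cfg <- small_cfg(threshold = 7000)
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(sim$trajectory), 1L)
  expect_equal(sim$trajectory$phi_sen, 1)
  expect_equal(sim$trajectory$pd, 0)
  expect_false(sim$censored)
})

test_that("a 46-chromosome cell population doubles while every telomere is long", {
  cfg <- sim_config(model = "cell", case = "A1",
                    initial_quartet = rep(6000, 4), max_generations = 10)
  sim <- run_simulation(cfg, seed = 2)
  tr <- sim$trajectory
  expect_true(all(tr$phi_div[1:10] == 1))
  expect_equal(tr$pd[1:10], 0:9)
  # one starting cell needs eight generations to reach the 200-cell cap
  expect_equal(tr$notional_N[9], 256)
  expect_gte(tr$notional_N[9], 200)
  expect_equal(tr$n_tracked[10], 200)
})

test_that("accounting converts counts to fractions and doublings", {
  st <- list(notional_N = 100, initial_N0 = 1)
  acc <- accounting_update(st, c(divided = 50, potential = 30, senescent = 20))
  expect_equal(acc$phi_div, 0.5)
  expect_equal(acc$phi_pot, 0.3)
  expect_equal(acc$phi_sen, 0.2)
  expect_equal(acc$phi_div + acc$phi_pot + acc$phi_sen, 1)
  expect_equal(acc$notional_next, 150)
  # eight straight doublings from one cell give pd 8 and 256 cells
  s <- list(notional_N = 1, initial_N0 = 1)
  for (i in 1:8) {
    a <- accounting_update(s, c(divided = 10, potential = 0, senescent = 0))
    s$notional_N <- a$notional_next
  }
  expect_equal(s$notional_N, 256)
  expect_equal(accounting_update(s, c(divided = 0, potential = 0,
                                      senescent = 10))$pd, 8)
  a0 <- accounting_update(s, c(divided = 0, potential = 5, senescent = 5))
  expect_equal(a0$notional_next, s$notional_N)
  expect_error(accounting_update(s, c(divided = 0, potential = 0,
                                      senescent = 0)), "empty")
})

test_that("passaging caps the tracked sample without biasing lengths", {
  set.seed(3)
  pop <- new_population(c(6000, 6000, 6000, 5800), n_cells = 300)
  pop$Q[, 1] <- runif(300, 500, 6000)   # heterogeneous lengths
  expect_equal(n_cells(passage(pop, 200)), 200L)
  small <- new_population(c(100, 100, 100, 100), n_cells = 150)
  expect_identical(passage(small, 200), small)
  # uniform sampling: retained mean is unbiased over many passages
  full_mean <- mean(cell_mean <- rowMeans(pop$Q))
  set.seed(104)
  devs <- replicate(2000, {
    kept <- passage(pop, 200)
    mean(rowMeans(kept$Q)) - full_mean
  })
  se <- sd(cell_mean) * sqrt((1 / 200 - 1 / 300)) / sqrt(2000)
  expect_lt(abs(mean(devs)), 3 * se)
})

test_that("identical configuration and seed reproduce the trajectory", {
  cfg <- small_cfg(pw = 0.4, max_generations = 40)
  s1 <- run_simulation(cfg, seed = 9)
  s2 <- run_simulation(cfg, seed = 9)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$population$Q, s2$population$Q)
})

test_that("the vectorized engine matches the per-chromosome reference rules", {
  # chromosome-level normal aging
  cfg <- small_cfg(passage_cap = 50, max_generations = 30)
  e <- engine_run(cfg, seed = 5, generations = 30)
  r <- ref_run(cfg, seed = 5, generations = 30)
  expect_equal(e$pop$Q, ref_matrix(r$cells), ignore_attr = TRUE)
  expect_equal(e$counts, r$counts)

  # Werner deletions with feasibility blocking, several chromosomes per cell
  cfgw <- sim_config(model = "cell", chromosomes = 3, case = "A1",
                     pw = 0.5, x = 900,
                     initial_quartet = c(2600, 2600, 2600, 2400),
                     passage_cap = 40, max_generations = 25)
  ew <- engine_run(cfgw, seed = 11, generations = 25)
  rw <- ref_run(cfgw, seed = 11, generations = 25)
  expect_equal(ew$pop$Q, ref_matrix(rw$cells), ignore_attr = TRUE)
  expect_equal(ew$counts, rw$counts)

  # length-dependent division probability (three-way classification)
  cfgb <- sim_config(model = "chromosome", case = "B2.2",
                     passage_cap = 60, max_generations = 40)
  eb <- engine_run(cfgb, seed = 13, generations = 40)
  rb <- ref_run(cfgb, seed = 13, generations = 40)
  expect_equal(eb$pop$Q, ref_matrix(rb$cells), ignore_attr = TRUE)
  expect_equal(eb$counts, rb$counts)
})

test_that("p_w = 0 reduces the Werner engine to normal aging on matched seeds", {
  cfg_norm <- small_cfg(max_generations = 60)
  cfg_w0 <- small_cfg(pw = 0, x = 0, max_generations = 60)
  cfg_w0$models$werner$x <- 500  # deletion size irrelevant at p_w = 0
  s1 <- run_simulation(cfg_norm, seed = 21)
  s2 <- run_simulation(cfg_w0, seed = 21)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("a unit exponent case with alpha = 0 reduces case B to case A", {
  cfgB <- sim_config(model = "chromosome", case = "B1.4", alpha = 0, y0 = 200,
                     max_generations = 60)
  cfgA <- small_cfg(max_generations = 60)
  sB <- run_simulation(cfgB, seed = 31)
  sA <- run_simulation(cfgA, seed = 31)
  expect_identical(sB$trajectory, sA$trajectory)
})

test_that("senescence is monotone below the passaging cap", {
  cfg <- small_cfg(initial_quartet = c(1000, 1000, 1000, 800),
                   passage_cap = 100000, max_generations = 40)
  sim <- run_simulation(cfg, seed = 41)
  expect_true(all(diff(sim$trajectory$n_senescent) >= 0))
  expect_gt(sim$trajectory$phi_sen[nrow(sim$trajectory)], 0.5)
})

test_that("population doublings never exceed the generation number", {
  for (case in c("A1", "B1.2")) {
    sim <- run_simulation(sim_config(model = "chromosome", case = case,
                                     max_generations = 120), seed = 51)
    tr <- sim$trajectory
    expect_true(all(tr$pd <= tr$g + 1e-9))
    all_div <- cumprod(c(1, tr$phi_div == 1))[seq_len(nrow(tr))] == 1
    expect_equal(tr$pd[all_div], tr$g[all_div])
  }
})

test_that("the early mean-length drift matches the enumeration value y0/4", {
  # enumeration of the division rule: a canonical parent of mean mu yields
  # daughters of mean mu and mu - y/2, so the population mean is expected
  # to fall by y0 / 4 = 50 bp per generation before any senescence
  drops <- numeric(400)
  cfg <- small_cfg(max_generations = 8)
  for (i in seq_len(400)) {
    tr <- run_simulation(cfg, seed = 2000 + i)$trajectory
    drops[i] <- mean(diff(tr$mean_length))
  }
  se <- sd(drops) / sqrt(length(drops))
  expect_lt(abs(mean(drops) - (-50)), 3 * se)
})
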
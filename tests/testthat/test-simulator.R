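test_that("event rates reproduce the hand-evaluated single-pair example", {
  # S = K = 1, C = 2, rho = 4, eta = 0.5, eps = 1, R = 3, N = 2
  p <- structure(list(S = 1, K = 1, eps = 1, n = 2, r = 3, rho = 4,
                      eta = 0.5, eta_bar = 0.5, generation_time = 2),
                 class = "community_params")
  rs <- event_rates(p, matrix(2, 1, 1), N = 2, R = 3)
  expect_equal(rs$inflow, 4)
  expect_equal(rs$death, 1)
  expect_equal(as.numeric(rs$cons_birth), 12)
  expect_equal(as.numeric(rs$cons_nobirth), 0)
  expect_equal(rs$total, 17)
  # eps = 0.5 splits consumption but leaves the total invariant
  p$eps <- 0.5
  rs2 <- event_rates(p, matrix(2, 1, 1), N = 2, R = 3)
  expect_equal(as.numeric(rs2$cons_birth), 6)
  expect_equal(as.numeric(rs2$cons_nobirth), 6)
  expect_equal(rs2$total, 17)
  # empty resource silences consumption
  rs3 <- event_rates(p, matrix(2, 1, 1), N = 2, R = 0)
  expect_equal(as.numeric(rs3$cons_birth) + as.numeric(rs3$cons_nobirth), 0)
  expect_error(event_rates(p, matrix(2, 1, 1), N = 0, R = 3), "floor")
})

test_that("event selection frequencies match the exact category probabilities", {
  p <- structure(list(S = 1, K = 1, eps = 1, n = 2, r = 3, rho = 4,
                      eta = 0.5, eta_bar = 0.5, generation_time = 2),
                 class = "community_params")
  rs <- event_rates(p, matrix(2, 1, 1), N = 2, R = 3)
  draws <- withr::with_seed(77, replicate(40000, {
    ev <- draw_next_event(rs)
    c(ev$type == "inflow", ev$type == "death", ev$type == "cons_birth",
      ev$wait)
  }))
  freq <- rowMeans(draws[1:3, ])
  expected <- c(4, 1, 12) / 17
  sigma <- sqrt(expected * (1 - expected) / 40000)
  expect_true(all(abs(freq - expected) < 3.5 * sigma))
  # waiting times are Exponential(17)
  expect_equal(mean(draws[4, ]), 1 / 17,
               tolerance = 3.5 / (17 * sqrt(40000)) * 17)
  # degenerate rate set: only inflow
  rs0 <- rs
  rs0$death <- 0; rs0$cons_birth[] <- 0; rs0$cons_nobirth[] <- 0
  rs0$total <- sum(rs0$inflow)
  types <- withr::with_seed(3, replicate(50, draw_next_event(rs0)$type))
  expect_true(all(types == "inflow"))
})

test_that("event bookkeeping follows the transition rules including the floor", {
  st <- apply_event(N = c(5, 1), R = c(3, 0),
                    list(type = "death", species = 1, resource = NA))
  expect_equal(st$N, c(4, 1)); expect_false(st$extinction)
  st <- apply_event(N = c(5, 1), R = c(3, 0),
                    list(type = "death", species = 2, resource = NA))
  expect_equal(st$N, c(5, 1)); expect_true(st$extinction)
  st <- apply_event(N = c(2, 1), R = c(3, 2),
                    list(type = "cons_birth", species = 1, resource = 1))
  expect_equal(st$N, c(3, 1)); expect_equal(st$R, c(2, 2))
  st <- apply_event(N = c(2, 1), R = c(3, 2),
                    list(type = "cons_nobirth", species = 2, resource = 2))
  expect_equal(st$N, c(2, 1)); expect_equal(st$R, c(3, 1))
  st <- apply_event(N = c(2, 1), R = c(3, 2),
                    list(type = "inflow", species = NA, resource = 2))
  expect_equal(st$R, c(3, 3))
  expect_error(apply_event(N = c(2, 1), R = c(0, 2),
                           list(type = "cons_birth", species = 1,
                                resource = 1)),
               "empty resource")
})

test_that("compiled simulator matches the brute-force truncated-chain stationary law", {
  C <- as_consumption_matrix(matrix(1, 1, 1))
  p <- community_params(C, n = 2, r = 1)      # rho = 2, eta = 1
  exact <- truncated_chain_stationary(rho = 2, eta = 1, eps = 1,
                                      Rmax = 25, Nmax = 40)
  margN <- tapply(exact$pi, exact$states$N, sum)
  tr <- simulate_community(C, p, burn_in = 50, n_generations = 12000,
                           cadence = 0.5, seed = 5)
  expect_lt(max(tr$snapshots$abundance), 40)   # far from the truncation cap
  emp <- tabulate(tr$snapshots$abundance, nbins = 40) / nrow(tr$snapshots)
  expect_lt(0.5 * sum(abs(emp - margN)), 0.03) # total-variation distance
  expect_equal(mean(tr$snapshots$abundance),
               sum(seq_len(40) * margN), tolerance = 0.03)
})

test_that("compiled core and R reference operations agree on a tiny system", {
  C <- as_consumption_matrix(matrix(1, 1, 1))
  p <- community_params(C, n = 3, r = 2)
  ref <- simulate_reference(C, p, n_events = 12000, thin = 1, seed = 9)
  burn <- ref[ref$event > 3000, ]
  # states persist until the next event: weight by dwell time, not by event
  w <- diff(burn$t)
  refN <- weighted.mean(head(burn$N, -1), w)
  refR <- weighted.mean(head(burn$R, -1), w)
  tr <- simulate_community(C, p, burn_in = 20, n_generations = 2000,
                           cadence = 0.5, seed = 10)
  expect_equal(refN, mean(tr$snapshots$abundance), tolerance = 0.08)
  expect_equal(refR, mean(tr$resources$abundance), tolerance = 0.12)
})

test_that("trajectories are bit-for-bit reproducible from the seed", {
  fix <- tiny_neutral(S = 6, n = 15, r = 15)
  a <- simulate_community(fix$C, fix$params, burn_in = 20,
                          n_generations = 100, cadence = 5, seed = 123)
  b <- simulate_community(fix$C, fix$params, burn_in = 20,
                          n_generations = 100, cadence = 5, seed = 123)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$extinctions, b$extinctions)
  expect_identical(a$meta$n_events, b$meta$n_events)
  c_ <- simulate_community(fix$C, fix$params, burn_in = 20,
                           n_generations = 100, cadence = 5, seed = 124)
  expect_false(identical(a$snapshots, c_$snapshots))
})

test_that("the speciation floor keeps every abundance at or above one", {
  fix <- tiny_neutral(S = 8, n = 5, r = 10)
  tr <- simulate_community(fix$C, fix$params, burn_in = 10,
                           n_generations = 500, cadence = 1, seed = 2)
  expect_gte(min(tr$snapshots$abundance), 1)
  expect_equal(min(tr$snapshots$abundance), 1)   # drift does reach the floor
  expect_gt(nrow(tr$extinctions), 0)
  expect_true(all(tr$linked_obs$wait_generations > 0))
  expect_true(all(tr$linked_obs$abundance >= 1))
})

test_that("with eps = 1 every consumption event yields exactly one birth", {
  fix <- tiny_neutral(S = 5, n = 20, r = 20)
  tr <- simulate_community(fix$C, fix$params, burn_in = 10,
                           n_generations = 200, cadence = 50,
                           record_events = TRUE, seed = 6)
  cnt <- tr$meta$event_type_counts
  expect_equal(unname(cnt["cons_nobirth"]), 0)
  expect_equal(sum(tr$event_counts), unname(cnt["cons_birth"]))
  # eps = 0.5: births are a fair split of consumption events
  C <- fix$C
  p5 <- community_params(C, n = 20, r = 20, eps = 0.5)
  tr5 <- simulate_community(C, p5, burn_in = 10, n_generations = 100,
                            cadence = 50, seed = 6)
  cnt5 <- tr5$meta$event_type_counts
  frac <- cnt5["cons_birth"] / (cnt5["cons_birth"] + cnt5["cons_nobirth"])
  expect_equal(unname(frac), 0.5, tolerance = 0.02)
})

test_that("neutral species are exchangeable in their time averages", {
  fix <- tiny_neutral(S = 6, n = 30, r = 30)
  tr <- simulate_community(fix$C, fix$params, burn_in = 100,
                           n_generations = 4000, cadence = 2, seed = 14)
  means <- tapply(tr$snapshots$abundance, tr$snapshots$species, mean)
  expect_lt(max(abs(means - mean(means))) / mean(means), 0.6)
  expect_equal(mean(tr$snapshots$abundance), 30, tolerance = 0.15)
})

test_that("time-averaged abundance is self-consistent against a much longer run", {
  fix <- tiny_neutral(S = 10, n = 25, r = 25)
  short <- simulate_community(fix$C, fix$params, burn_in = 150,
                              n_generations = 1000, cadence = 5, seed = 8)
  long <- simulate_community(fix$C, fix$params, burn_in = 150,
                             n_generations = 10000, cadence = 5, seed = 81)
  expect_equal(mean(short$snapshots$abundance),
               mean(long$snapshots$abundance), tolerance = 0.1)
  expect_lt(stationarity_check(long)$rel_diff, 0.05)
})

test_that("snapshot schedule, custom initial states and exports behave", {
  fix <- tiny_neutral(S = 4, n = 10, r = 10)
  tr <- simulate_community(fix$C, fix$params, burn_in = 7,
                           n_generations = 40, cadence = 10, seed = 3)
  expect_equal(unique(tr$snapshots$time_generations), c(17, 27, 37, 47))
  expect_equal(nrow(tr$snapshots), 4 * 4)
  tr2 <- simulate_community(fix$C, fix$params, burn_in = 1,
                            n_generations = 10, cadence = 10,
                            init = list(N = c(3, 3, 3, 3), R = rep(2, 4)),
                            seed = 4)
  expect_s3_class(tr2$snapshots, "tbl_df")
  expect_error(simulate_community(fix$C, fix$params, burn_in = -1,
                                  n_generations = 10, cadence = 1, seed = 1))
})
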
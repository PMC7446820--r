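test_that("ODE right-hand side vanishes at the calibrated point and matches hand evaluation", {
  fix <- tiny_neutral(S = 4, n = 10, r = 5)
  rhs <- ode_rhs(fix$params, fix$C, rep(5, 4), rep(10, 4))
  expect_equal(c(rhs$dR, rhs$dN), rep(0, 8))
  # N = 0 is absorbing in the ODE
  rhs0 <- ode_rhs(fix$params, fix$C, rep(5, 4), rep(0, 4))
  expect_equal(rhs0$dN, rep(0, 4))
  # term-by-term hand evaluation at a random S = K = 2 state
  M <- withr::with_seed(5, matrix(runif(4, 0.2, 2), 2, 2))
  p <- community_params(as_consumption_matrix(M), n = 7, r = 3, eps = 0.6)
  R <- c(2.5, 4); N <- c(6, 1.5)
  rhs2 <- ode_rhs(p, M, R, N)
  for (k in 1:2) {
    expect_equal(rhs2$dR[k],
                 p$rho[k] - R[k] * (M[k, 1] * N[1] + M[k, 2] * N[2]))
  }
  for (i in 1:2) {
    expect_equal(rhs2$dN[i],
                 0.6 * N[i] * (M[1, i] * R[1] + M[2, i] * R[2]) - p$eta[i] * N[i])
  }
})

test_that("equilibrium residual is zero only at fixed points", {
  fix <- tiny_neutral(S = 3, n = 10, r = 5)
  expect_lt(equilibrium_residual(fix$params, fix$C), 1e-10)
  expect_gt(equilibrium_residual(fix$params, fix$C,
                                 R = rep(5.5, 3), N = rep(10, 3)), 0)
  # non-uniform targets: rates built for an arbitrary positive point fix it
  M <- withr::with_seed(8, matrix(runif(9, 0.1, 2), 3, 3))
  Rstar <- c(2, 5, 9); Nstar <- c(4, 11, 30); eps <- 0.8
  rho <- Rstar * drop(M %*% Nstar)
  eta <- eps * drop(crossprod(M, Rstar))
  p <- structure(list(S = 3, K = 3, eps = eps, n = NA, r = NA, rho = rho,
                      eta = eta, eta_bar = mean(eta),
                      generation_time = 1 / mean(eta)),
                 class = "community_params")
  expect_lt(equilibrium_residual(p, M, Rstar, Nstar), 1e-8)
})

test_that("analytic Jacobian agrees with central finite differences", {
  for (seed in 1:5) {
    M <- withr::with_seed(seed, matrix(runif(12, 0.1, 2), 4, 3))
    p <- community_params(as_consumption_matrix(M), n = 20, r = 10, eps = 0.9)
    R <- rep(10, 4); N <- rep(20, 3)
    J <- jacobian_at(p, M, R, N)
    h <- 1e-5
    f <- function(x) {
      rhs <- ode_rhs(p, M, x[1:4], x[5:7])
      c(rhs$dR, rhs$dN)
    }
    x0 <- c(R, N)
    Jfd <- sapply(seq_along(x0), function(j) {
      e <- numeric(7); e[j] <- h
      (f(x0 + e) - f(x0 - e)) / (2 * h)
    })
    expect_equal(J, Jfd, tolerance = 1e-6)
  }
})

test_that("neutral consumer-consumer block is zero at the calibrated point", {
  fix <- tiny_neutral(S = 5, n = 30, r = 15)
  J <- jacobian_at(fix$params, fix$C)
  expect_equal(J[6:10, 6:10], matrix(0, 5, 5))
  expect_equal(dim(J), c(10, 10))
})

test_that("the hand-solvable neutral 2x2 spectrum is {-20, 0, -10 +/- 10i}", {
  C <- as_consumption_matrix(matrix(1, 2, 2))
  p <- community_params(C, n = 10, r = 5, eps = 1)
  sp <- suppressWarnings(community_spectrum(p, C))
  want <- c(-20 + 0i, -10 - 10i, -10 + 10i, 0 + 0i)
  expect_equal(sort(Re(sp$eigenvalues)), sort(Re(want)), tolerance = 1e-10)
  expect_equal(sort(Im(sp$eigenvalues)), sort(Im(want)), tolerance = 1e-10)
  # the marginal neutral direction sits in the consumer bulk
  expect_true(any(Mod(sp$eigenvalues[sp$consumer_bulk]) < 1e-10))
})

test_that("neutral limit has exactly S-1 marginal consumer directions", {
  for (S in c(5, 10, 50)) {
    C <- as_consumption_matrix(matrix(1, S, S))
    p <- community_params(C, n = 100, r = 100)
    sp <- suppressWarnings(community_spectrum(p, C))
    n_zero <- sum(Mod(sp$eigenvalues) < 1e-8 * max(Mod(sp$eigenvalues)))
    expect_equal(n_zero, S - 1)
  }
})

test_that("bulk separation is structural at the default parameterizations", {
  for (nr in list(c(100, 100), c(245, 100), c(500, 100))) {
    C <- generalist_matrix(50, 50, mean = 1, cv = 0.1, seed = 17)
    p <- community_params(C, n = nr[1], r = nr[2])
    sp <- community_spectrum(p, C)
    expect_gte(sp$separation_ratio, 10)
    expect_length(sp$resource_bulk, 50)
    expect_length(sp$consumer_bulk, 50)
  }
})

test_that("specialist spectrum is continuous in Cd -> Co and |lambda+| grows with Cd/Co", {
  p_of <- function(cd) {
    C <- specialist_matrix(10, cd, 1)
    community_params(C, n = 50, r = 50)
  }
  neutral <- suppressWarnings(community_spectrum(p_of(1), specialist_matrix(10, 1, 1)))
  near <- suppressWarnings(community_spectrum(p_of(1 + 1e-6),
                                              specialist_matrix(10, 1 + 1e-6, 1)))
  expect_equal(sort(Re(near$eigenvalues)), sort(Re(neutral$eigenvalues)),
               tolerance = 1e-3)
  lam <- sapply(c(1.5, 2.5, 4, 8), function(cd) {
    abs(Re(suppressWarnings(
      community_spectrum(p_of(cd), specialist_matrix(10, cd, 1)))$lambda_plus))
  })
  expect_true(all(diff(lam) > 0))
})

test_that("generalist |lambda+| grows with CV in the ensemble median", {
  med_lam <- sapply(c(0.05, 0.2, 0.4), function(cv) {
    median(sapply(1:7, function(s) {
      C <- generalist_matrix(15, 15, mean = 1, cv = cv, seed = 300 + s)
      p <- community_params(C, n = 50, r = 50)
      abs(Re(suppressWarnings(community_spectrum(p, C))$lambda_plus))
    }))
  })
  expect_true(all(diff(med_lam) > 0))
})

test_that("generalist threshold formula matches arithmetic and scalings", {
  expect_equal(predict_generalist_threshold(50, 245, 100, correction = FALSE),
               sqrt(50 / 980), tolerance = 1e-12)
  expect_equal(predict_generalist_threshold(50, 245, 100, correction = FALSE),
               0.2259, tolerance = 5e-4)
  # exponent -1/2 without the correction
  expect_equal(predict_generalist_threshold(30, 100, 10, correction = FALSE) /
                 predict_generalist_threshold(30, 400, 10, correction = FALSE),
               2)
  # increasing in S
  th <- predict_generalist_threshold(c(10, 20, 40, 80), 100, 50)
  expect_true(all(diff(th) > 0))
  expect_error(predict_generalist_threshold(50, 10, 100),
               "radicand")
})

test_that("specialist threshold formula is the gamma expression, linear in S", {
  expect_equal(gamma_coef(100, 100, 1), 0.005)
  expect_equal(predict_specialist_threshold(50, 100, 100), 1.245 / 0.995,
               tolerance = 1e-12)
  expect_equal(predict_specialist_threshold(50, 100, 100), 1.2513,
               tolerance = 1e-4)
  # gamma = 0 -> exactly 1 (neutral limit); eps r = 2 n makes gamma vanish
  expect_equal(predict_specialist_threshold(37, 50, 100, eps = 1), 1)
  # linearity: threshold(2S) - threshold(S) = gamma * S / (1 - gamma)
  g <- gamma_coef(80, 60)
  expect_equal(predict_specialist_threshold(60, 80, 60) -
                 predict_specialist_threshold(30, 80, 60),
               g * 30 / (1 - g))
  expect_error(predict_specialist_threshold(10, 0.4, 0.1), "diverges")
})

test_that("drift timescale reduces to the k = 1 closed form and scales with n", {
  expect_equal(drift_timescale(1, 0.5, eta_bar = 1), -log(0.5) / 0.5)
  expect_equal(drift_timescale(1, 0.9, eta_bar = 2), -log(0.1) / 0.9 / 2)
  p <- fit_logseries_p(50)
  tt <- sapply(c(5, 20, 80, 300), drift_timescale, p = p, eta_bar = 1)
  expect_true(all(diff(tt) > 0))
})

test_that("stabilization/drift timescale ratio falls as the community grows less neutral", {
  p_ls <- fit_logseries_p(50)
  ratio <- sapply(c(1.2, 2, 4, 8), function(cd) {
    C <- specialist_matrix(10, cd, 1)
    pp <- community_params(C, n = 50, r = 50)
    sp <- suppressWarnings(community_spectrum(pp, C))
    sp$stabilization_timescale / drift_timescale(50, p_ls, pp$eta_bar)
  })
  expect_true(all(diff(ratio) < 0))
})
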
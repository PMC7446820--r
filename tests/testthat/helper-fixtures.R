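# Small fixtures shared across test files. Everything is generated in code.

tiny_neutral <- function(S = 10, n = 20, r = 20, eps = 1, seed = 1) {
  C <- generalist_matrix(S, S, mean = 1, cv = 0, seed = seed)
  list(C = C, params = community_params(C, n, r, eps))
}

# brute-force mean pairwise cosine between columns, independent of the
# vectorised implementation
brute_force_nni <- function(M) {
  S <- ncol(M)
  cs <- c()
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    cs <- c(cs, sum(M[, i] * M[, j]) /
              sqrt(sum(M[, i]^2) * sum(M[, j]^2)))
  }
  1 - mean(cs)
}

# stationary distribution of the truncated S = K = 1 chain by linear algebra
truncated_chain_stationary <- function(rho, eta, eps, Rmax, Nmax) {
  states <- expand.grid(R = 0:Rmax, N = 1:Nmax)
  ns <- nrow(states)
  Q <- matrix(0, ns, ns)
  at <- function(R, N) which(states$R == R & states$N == N)
  for (s in seq_len(ns)) {
    R <- states$R[s]; N <- states$N[s]
    if (R < Rmax) Q[s, at(R + 1, N)] <- Q[s, at(R + 1, N)] + rho
    if (N > 1) Q[s, at(R, N - 1)] <- Q[s, at(R, N - 1)] + eta * N
    if (R > 0) {
      if (N < Nmax) {
        Q[s, at(R - 1, N + 1)] <- Q[s, at(R - 1, N + 1)] + eps * R * N
      }
      # non-birth consumption keeps N
      if (eps < 1) Q[s, at(R - 1, N)] <- Q[s, at(R - 1, N)] + (1 - eps) * R * N
    }
    Q[s, s] <- -sum(Q[s, ])
  }
  ev <- eigen(t(Q))
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  list(states = states, pi = v / sum(v))
}
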
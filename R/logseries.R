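#' Fisher log-series probability mass function
#'
#' `P_k = alpha * p^k / k` for `k >= 1`, with `alpha = -1/log(1 - p)`. This
#' is the stationary species abundance distribution of neutral drift with a
#' speciation floor in high-diversity communities.
#'
#' @param k Positive integer abundance(s).
#' @param p Log-series parameter in (0, 1).
#' @param log Return log-probabilities.
#' @export
dlogseries <- function(k, p, log = FALSE) {
  stopifnot(p > 0, p < 1)
  if (any(k < 1)) stop("log-series support starts at k = 1")
  alpha <- -1 / log1p(-p)
  lp <- log(alpha) + k * log(p) - log(k)
  if (log) lp else exp(lp)
}

#' @rdname dlogseries
#' @param q Abundance at which to evaluate the CDF `P(X <= q)`.
#' @export
plogseries <- function(q, p) {
  stopifnot(p > 0, p < 1)
  kmax <- max(1, floor(max(q)))
  cdf <- cumsum(dlogseries(seq_len(kmax), p))
  out <- numeric(length(q))
  out[q >= 1] <- cdf[pmin(kmax, floor(q[q >= 1]))]
  pmin(out, 1)
}

#' @rdname dlogseries
#' @param n Number of draws.
#' @return `rlogseries` returns integer draws by CDF inversion (the far tail
#'   beyond cumulative mass `1 - 1e-12` is truncated).
#' @export
rlogseries <- function(n, p) {
  stopifnot(p > 0, p < 1)
  kmax <- logseries_support_max(p)
  pmf <- dlogseries(seq_len(kmax), p)
  cdf <- cumsum(pmf) / sum(pmf)
  findInterval(stats::runif(n), cdf) + 1L
}

logseries_support_max <- function(p, tail = 1e-12) {
  # p^k/k tail is bounded by the geometric tail; solve p^k < tail * (1-p)
  max(10L, ceiling(log(tail * (1 - p)) / log(p)))
}

#' Mean abundance implied by a log-series parameter
#'
#' `alpha * p / (1 - p)` with `alpha = -1/log(1-p)`.
#'
#' @inheritParams dlogseries
#' @export
logseries_mean <- function(p) {
  -p / ((1 - p) * log1p(-p))
}

#' Fit the log-series parameter from a mean abundance
#'
#' Solves `alpha p / (1 - p) = mean` for `p` in (0, 1). The mean of a
#' log-series always exceeds 1, so `mean <= 1` is an error.
#'
#' @param mean_abundance Observed mean abundance (> 1), or a sample of
#'   abundances whose mean is used.
#' @return The fitted `p`.
#' @examples
#' fit_logseries_p(1 / log(2)) # 0.5
#' @export
fit_logseries_p <- function(mean_abundance) {
  m <- if (length(mean_abundance) > 1) mean(mean_abundance) else mean_abundance
  if (!is.finite(m) || m <= 1) {
    stop("log-series mean abundance must exceed 1; got ", format(m))
  }
  # solve on log(1-p) scale: mean = -(1-q)/(q log q), q = 1 - p
  f <- function(lq) {
    q <- exp(lq)
    -(1 - q) / (q * lq) - m
  }
  # mean ~ 1/(q log(1/q)): bracket q generously
  lo <- log(min(0.5, 1 / (m * (log(m) + 10) + 10)^2))
  root <- stats::uniroot(f, lower = lo, upper = log(1 - 1e-12),
                         tol = 1e-15)
  p <- 1 - exp(root$root)
  # one Newton polish on g(p) = logseries_mean(p) - m
  p
}

#' Expected neutral extinction time (generations)
#'
#' Life expectancy of a species currently at abundance `k` under neutral
#' drift:
#' \deqn{T_k = \frac{1}{1-p}\left(p^{-k} B(p; 1+k, 0) + H_k +
#'   \log(1-p)\right),}
#' with `H_k` the k-th harmonic number and `B(z; a, 0)` the incomplete beta
#' function with vanishing second argument. The combined term
#' `p^{-k} B(p; 1+k, 0)` is evaluated as the cancellation-free series
#' `sum_{i>=1} p^i / (i + k)`, which is stable for `k` well beyond 1e4 and
#' extends smoothly to real `k` (harmonic numbers via `digamma`).
#'
#' @param k Abundance (>= 1); may be non-integer when evaluating at, e.g., a
#'   bin's geometric mean.
#' @param p Log-series parameter in (0, 1).
#' @return Expected extinction time in generations (units of `1/eta_bar`).
#' @examples
#' neutral_extinction_time(1, 0.5) # -log(0.5)/0.5
#' @export
neutral_extinction_time <- function(k, p) {
  stopifnot(p > 0, p < 1)
  if (any(k < 1)) stop("abundance must be >= 1")
  vapply(k, function(kk) {
    s <- pbeta_zero_series(kk, p)
    if (!is.finite(s)) stop("incomplete beta series failed to converge")
    Hk <- digamma(kk + 1) + 0.5772156649015328606
    (s + Hk + log1p(-p)) / (1 - p)
  }, numeric(1))
}

# sum_{i>=1} p^i / (i + k) == p^{-k} * B(p; 1+k, 0), computed term-wise in
# blocks until the geometric tail bound drops below tol.
pbeta_zero_series <- function(k, p, tol = 1e-13) {
  total <- 0
  i0 <- 0
  block <- 4096L
  repeat {
    i <- i0 + seq_len(block)
    total <- total + sum(exp(i * log(p) - log(i + k)))
    i0 <- i0 + block
    # tail bound: p^{i0+1}/(1-p) / (i0 + k)
    tail <- exp((i0 + 1) * log(p)) / ((1 - p) * (i0 + k))
    if (tail < tol * max(total, 1)) break
    if (i0 > 5e7) stop("series for incomplete beta did not converge")
  }
  total
}

#' Predicted variance of relative abundance fluctuations D(t)
#'
#' For neutral dynamics matched to a subcritical linear birth-death process
#' (per-capita death rate 1 per generation, per-capita birth rate `p`), the
#' abundance `n(t)` given `n(0) = n0` has closed-form moments that include
#' the absorbing state at 0:
#' `E n(t) = n0 e^{-(1-p)t}` and
#' `Var n(t) = n0 (1+p)/(1-p) e^{-(1-p)t} (1 - e^{-(1-p)t})`.
#' The relative change `D(t) = (n(t) - n0)/n0` therefore has variance
#' `Var n(t) / n0^2`, zero at `t = 0` and saturating as the ensemble goes
#' extinct.
#'
#' @param n0 Initial abundance (>= 1).
#' @param t_grid Times in generations.
#' @param p Log-series / birth-death parameter in (0, 1).
#' @return Tibble with columns `t`, `n0`, `var_D`.
#' @export
predicted_var_D <- function(n0, t_grid, p) {
  stopifnot(all(n0 >= 1), p > 0, p < 1)
  grid <- tidyr::expand_grid(n0 = n0, t = t_grid)
  decay <- exp(-(1 - p) * grid$t)
  var_n <- grid$n0 * (1 + p) / (1 - p) * decay * (1 - decay)
  tibble::tibble(t = grid$t, n0 = grid$n0, var_D = var_n / grid$n0^2)
}

#' Transition moments of the matched linear birth-death process
#'
#' First two moments of `n(t) | n0` for the subcritical linear birth-death
#' process with death rate 1 and birth rate `p` per capita per generation,
#' plus the extinction probability `P(n(t) = 0)`. Exposed mainly for
#' validation against Monte-Carlo runs.
#'
#' @inheritParams predicted_var_D
#' @param t Time in generations.
#' @export
bd_transition_moments <- function(n0, t, p) {
  lam <- p; mu <- 1
  g <- exp((lam - mu) * t)
  alpha <- mu * (g - 1) / (lam * g - mu)      # extinction prob of one lineage
  tibble::tibble(
    t = t,
    mean = n0 * g,
    var = n0 * (lam + mu) / (lam - mu) * g * (g - 1),
    p_extinct = alpha^n0
  )
}

#' Tabulate a neutral extinction-time curve
#'
#' @param k Vector of abundances.
#' @inheritParams neutral_extinction_time
#' @return Tibble `(k, T_k)` in generations.
#' @export
extinction_curve <- function(k, p) {
  tibble::tibble(k = k, T_k = neutral_extinction_time(k, p))
}
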
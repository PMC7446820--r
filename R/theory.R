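#' Right-hand side of the deterministic (mean-field) model
#'
#' \deqn{\dot R_k = \rho_k - R_k \sum_j C_{kj} N_j, \qquad
#'       \dot N_i = \epsilon N_i \sum_j C_{ji} R_j - \eta_i N_i.}
#'
#' @param params A `community_params`.
#' @param C Consumption matrix.
#' @param R,N Non-negative state vectors (length K and S).
#' @return List with `dR` and `dN`.
#' @export
ode_rhs <- function(params, C, R, N) {
  M <- cm_entries(C)
  if (length(R) != params$K || length(N) != params$S) {
    stop("state dimensions do not match the community")
  }
  dR <- params$rho - R * drop(M %*% N)
  dN <- params$eps * N * drop(crossprod(M, R)) - params$eta * N
  list(dR = dR, dN = dN)
}

#' Max-norm residual of a candidate equilibrium
#'
#' Zero iff `(R, N)` is a fixed point of the deterministic model; the
#' calibrated uniform point must give a residual below 1e-10.
#'
#' @inheritParams ode_rhs
#' @export
equilibrium_residual <- function(params, C, R = rep(params$r, params$K),
                                 N = rep(params$n, params$S)) {
  rhs <- ode_rhs(params, C, R, N)
  max(abs(c(rhs$dR, rhs$dN)))
}

#' Jacobian of the deterministic model at a fixed point
#'
#' Analytic blocks, ordered resources first:
#' `dRdot/dR = diag(-sum_j C_kj N_j)`, `dRdot/dN = -R_k C_kj`,
#' `dNdot/dR = eps N_i C_ji` (transposed consumption), and
#' `dNdot/dN = diag(eps sum_l C_li R_l - eta_i)` — identically zero at the
#' calibrated point, which is what makes consumer dynamics slow.
#'
#' @inheritParams ode_rhs
#' @return `(K+S) x (K+S)` matrix.
#' @export
jacobian_at <- function(params, C, R = rep(params$r, params$K),
                        N = rep(params$n, params$S)) {
  M <- cm_entries(C)
  K <- params$K; S <- params$S
  J <- matrix(0, K + S, K + S)
  J[seq_len(K), seq_len(K)] <- diag(-drop(M %*% N), K)
  J[seq_len(K), K + seq_len(S)] <- -R * M
  J[K + seq_len(S), seq_len(K)] <- params$eps * N * t(M)
  J[K + seq_len(S), K + seq_len(S)] <-
    diag(params$eps * drop(crossprod(M, R)) - params$eta, S)
  J
}

#' Split a Jacobian spectrum into resource and consumer bulks
#'
#' The bipartite consumer-resource structure separates the spectrum into
#' `K + 1` fast modes — `K - 1` resource relaxations plus a complex pair of
#' collective (total resource/total consumer biomass) oscillations — and
#' `S - 1` slow niche modes that govern how between-species abundance
#' differences relax. The bulks are assigned by magnitude with the sizes
#' fixed at K (resource) and S (consumer), so one member of the collective
#' pair necessarily lands in the consumer bulk; `lambda_plus` is therefore
#' taken over the `S - 1` smallest-magnitude eigenvalues (the consumer bulk
#' minus its collective member): the most negative real part among the niche
#' modes, which sets the fastest deterministic consumer stabilization
#' timescale `1/|Re lambda_plus|`. In the exact neutral limit all niche
#' modes vanish and the timescale is infinite.
#'
#' `separation_ratio` measures the structural timescale gap: the smallest
#' magnitude among the `K + 1` fast modes divided by the largest magnitude
#' among the `S - 1` niche modes. A warning is raised when this falls
#' below 2.
#'
#' @param J Jacobian matrix from [jacobian_at()].
#' @param K,S Numbers of resources and consumers.
#' @return A `cr_spectrum` object with fields `eigenvalues`,
#'   `resource_bulk`, `consumer_bulk` (index vectors), `lambda_plus`,
#'   `stabilization_timescale` (in model time), `separation_ratio`.
#' @export
spectrum_split <- function(J, K, S) {
  ev <- eigen(J, only.values = TRUE)$values
  if (any(!is.finite(ev))) stop("non-finite eigenvalues")
  ord <- order(Mod(ev), decreasing = TRUE)
  resource_bulk <- ord[seq_len(K)]
  consumer_bulk <- ord[K + seq_len(S)]
  niche <- if (S > 1) ord[K + 1 + seq_len(S - 1)] else consumer_bulk
  sep <- Mod(ev[ord[K + 1]]) / max(Mod(ev[niche]))
  if (is.finite(sep) && sep < 2) {
    warning(sprintf(
      "fast and niche eigenvalue bulks are not well separated (ratio %.3g)",
      sep))
  }
  lambda_plus <- ev[niche][which.min(Re(ev[niche]))]
  structure(
    list(eigenvalues = ev, resource_bulk = resource_bulk,
         consumer_bulk = consumer_bulk, niche_modes = niche,
         lambda_plus = lambda_plus,
         stabilization_timescale = 1 / abs(Re(lambda_plus)),
         separation_ratio = sep, K = K, S = S),
    class = "cr_spectrum"
  )
}

#' Spectrum of a community at its calibrated equilibrium
#'
#' Convenience wrapper: Jacobian at the uniform fixed point, then
#' [spectrum_split()].
#'
#' @inheritParams ode_rhs
#' @export
community_spectrum <- function(params, C) {
  spectrum_split(jacobian_at(params, C), params$K, params$S)
}

#' @export
print.cr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<cr_spectrum> %d resource + %d consumer eigenvalues\n  lambda_plus = %s, stabilization timescale %.4g\n  bulk separation ratio %.3g\n",
    x$K, x$S, format(x$lambda_plus, digits = 4),
    x$stabilization_timescale, x$separation_ratio))
  invisible(x)
}

#' @export
tidy.cr_spectrum <- function(x, ...) {
  idx <- seq_along(x$eigenvalues)
  tibble::tibble(
    eigenvalue = x$eigenvalues,
    re = Re(x$eigenvalues),
    im = Im(x$eigenvalues),
    modulus = Mod(x$eigenvalues),
    bulk = ifelse(idx %in% x$resource_bulk, "resource", "consumer")
  )
}

#' @export
glance.cr_spectrum <- function(x, ...) {
  tibble::tibble(
    lambda_plus_re = Re(x$lambda_plus),
    stabilization_timescale = x$stabilization_timescale,
    separation_ratio = x$separation_ratio,
    n_zero_modes = sum(Mod(x$eigenvalues[x$consumer_bulk]) < 1e-8)
  )
}

#' Dimensionless drift-vs-stabilization coefficient
#'
#' `gamma = (1/n) * (1 - eps * r / (2 n))`: the per-generation scale of
#' demographic drift relative to abundance, entering both threshold
#' predictions.
#'
#' @param n Mean consumer abundance.
#' @param r Mean resource abundance.
#' @param eps Conversion efficiency.
#' @export
gamma_coef <- function(n, r, eps = 1) {
  (1 / n) * (1 - eps * r / (2 * n))
}

#' Predicted generalist CV threshold
#'
#' Scale of the consumption-matrix coefficient of variation at which niche
#' stabilization begins to outrun drift:
#' \deqn{CV^{thr} \sim \sqrt{\frac{S}{4n}\Big(1 - \frac{\epsilon r}{2n}\Big)}
#'      = \sqrt{S\gamma/4},}
#' defined up to a multiplicative constant. With the parenthetical correction
#' disregarded the threshold is exactly `sqrt(S / (4 n))`, i.e. a power law
#' in `n` with exponent -1/2.
#'
#' @param S Number of consumers.
#' @inheritParams gamma_coef
#' @param correction Include the `(1 - eps r / 2n)` correction (default TRUE).
#' @export
predict_generalist_threshold <- function(S, n, r, eps = 1, correction = TRUE) {
  stopifnot(n > 0, r > 0)
  radicand <- if (correction) (S / (4 * n)) * (1 - eps * r / (2 * n)) else S / (4 * n)
  if (any(radicand <= 0)) {
    stop("correction term makes the radicand non-positive ",
         "(eps * r >= 2 n); the predicted threshold is undefined here")
  }
  sqrt(radicand)
}

#' Predicted specialist Cd/Co threshold
#'
#' \deqn{C_d/C_o \sim \frac{1 + \gamma (S - 1)}{1 - \gamma},}
#' linear in `S` at fixed `gamma`; equals 1 (neutral limit) when `gamma = 0`.
#' Defined up to a multiplicative constant.
#'
#' @inheritParams predict_generalist_threshold
#' @export
predict_specialist_threshold <- function(S, n, r, eps = 1) {
  g <- gamma_coef(n, r, eps)
  if (any(g >= 1)) stop("gamma >= 1: specialist threshold formula diverges")
  (1 + g * (S - 1)) / (1 - g)
}

#' Characteristic drift timescale in model time
#'
#' Expected time for pure drift to take a species from abundance `n` all the
#' way to extinction: the neutral extinction time `T_n` (generations, Fisher
#' log-series parameter `p`) divided by the mean mortality rate.
#'
#' @param n Abundance at which to evaluate (rounded to an integer count).
#' @param p Log-series parameter in (0,1).
#' @param eta_bar Mean per-capita mortality rate (1/time).
#' @return Time in model units; multiply by `eta_bar` to recover generations.
#' @export
drift_timescale <- function(n, p, eta_bar = 1) {
  neutral_extinction_time(round(n), p) / eta_bar
}

#' @rdname plot_spectrum
#' @export
autoplot.cr_spectrum <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$re, y = .data$im,
                                    colour = .data$bulk)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Re(eigenvalue)", y = "Im(eigenvalue)",
                  colour = "bulk",
                  title = "Jacobian spectrum at the calibrated equilibrium") +
    ggplot2::theme_minimal()
}

#' Plot a Jacobian spectrum in the complex plane
#'
#' @param object A `cr_spectrum`.
#' @param ... Ignored.
#' @export
plot_spectrum <- function(object, ...) autoplot.cr_spectrum(object, ...)
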
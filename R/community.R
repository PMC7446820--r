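#' Calibrate inflow and mortality rates to a uniform equilibrium
#'
#' Chooses the unique positive inflow vector `rho` and per-capita mortality
#' vector `eta` for which the deterministic consumer-resource model has the
#' uniform point (`r` for every resource, `n` for every consumer) as a fixed
#' point:
#' \deqn{\rho_k = r\,n \sum_j C_{kj}, \qquad \eta_i = \epsilon\, r \sum_j C_{ji}.}
#'
#' @param C A `consumption_matrix` (or K x S matrix) with strictly positive
#'   row and column sums.
#' @param n Target mean consumer abundance at equilibrium (individuals).
#' @param r Target mean resource abundance at equilibrium (units).
#' @param eps Conversion efficiency in (0, 1]: probability that a consumption
#'   event also produces a new consumer individual.
#' @return List with components `rho` (length K) and `eta` (length S).
#' @examples
#' calibrate_rates(specialist_matrix(2, 2, 1), n = 1, r = 1, eps = 1)
#' @export
calibrate_rates <- function(C, n, r, eps = 1) {
  M <- cm_entries(C)
  stopifnot(n > 0, r > 0, eps > 0, eps <= 1)
  rs <- rowSums(M)
  cs <- colSums(M)
  if (any(rs <= 0) || any(cs <= 0)) {
    stop("calibration requires strictly positive row and column sums of C")
  }
  list(rho = r * n * rs, eta = eps * r * cs)
}

#' Bundle community parameters with calibrated rates
#'
#' Holds everything the simulator and the deterministic theory need: sizes,
#' efficiency, the target uniform equilibrium, and the calibrated rate
#' vectors. One generation is defined as the expected individual lifespan
#' `1/mean(eta)`; all schedule times in this package are expressed in
#' generations.
#'
#' @inheritParams calibrate_rates
#' @return A `community_params` object: list with `S`, `K`, `eps`, `n`, `r`,
#'   `rho`, `eta`, `eta_bar`, `generation_time`.
#' @examples
#' C <- generalist_matrix(10, 10, cv = 0, seed = 1)
#' p <- community_params(C, n = 50, r = 50)
#' p$generation_time
#' @export
community_params <- function(C, n, r, eps = 1) {
  M <- cm_entries(C)
  rates <- calibrate_rates(M, n, r, eps)
  eta_bar <- mean(rates$eta)
  structure(
    list(S = ncol(M), K = nrow(M), eps = eps, n = n, r = r,
         rho = rates$rho, eta = rates$eta, eta_bar = eta_bar,
         generation_time = 1 / eta_bar),
    class = "community_params"
  )
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf(
    "<community_params> S = %d consumers, K = %d resources\n  eps = %g, target equilibrium n = %g, r = %g\n  mean mortality %.4g (generation time %.4g model-time units)\n",
    x$S, x$K, x$eps, x$n, x$r, x$eta_bar, x$generation_time))
  invisible(x)
}
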
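#' Discrete Cramér-von Mises goodness-of-fit test against the log-series
#'
#' Fits the log-series parameter `p` from the sample mean, computes the
#' discrete Cramér-von Mises statistic
#' `W^2 = N * sum_j p_j (F_obs(j) - F_fit(j))^2` over the support cells
#' `1..max(sample)` plus one aggregated tail cell, and calibrates the
#' p-value by parametric bootstrap: each replicate resamples `N` abundances
#' from the fitted log-series, re-fits `p`, and recomputes `W^2`
#' (re-estimation is essential — asymptotic null tables do not apply when
#' the parameter is estimated from the data). The fit is declared successful
#' when the p-value exceeds `cutoff`.
#'
#' @param x Integer abundance sample (all >= 1, length >= 2).
#' @param n_boot Bootstrap replicates (default 999).
#' @param cutoff Significance cutoff for "success" (default 0.05).
#' @param seed Optional seed for the bootstrap.
#' @return A `cvm_gof` object: list with `statistic`, `p_value`, `success`,
#'   `p_hat`, `n`, `n_boot`, `cutoff`, and the observed sample.
#' @examples
#' x <- withr::with_seed(1, rlogseries(60, 0.98))
#' cvm_logseries_test(x, n_boot = 99, seed = 2)
#' @export
cvm_logseries_test <- function(x, n_boot = 999, cutoff = 0.05, seed = NULL) {
  x <- as.integer(x)
  if (length(x) < 2) stop("need at least two abundances")
  if (any(x < 1)) stop("abundances must be >= 1")
  if (mean(x) <= 1) {
    stop("sample mean must exceed 1 to fit a log-series")
  }
  p_hat <- fit_logseries_p(mean(x))
  stat <- cvm_discrete_stat(x, p_hat)
  boot <- function() {
    kmax <- logseries_support_max(p_hat)
    pmf <- dlogseries(seq_len(kmax), p_hat)
    cdf <- cumsum(pmf) / sum(pmf)
    n <- length(x)
    vapply(seq_len(n_boot), function(b) {
      repeat {
        xb <- findInterval(stats::runif(n), cdf) + 1L
        if (mean(xb) > 1) break
      }
      cvm_discrete_stat(xb, fit_logseries_p(mean(xb)))
    }, numeric(1))
  }
  stat_boot <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  p_value <- (1 + sum(stat_boot >= stat)) / (n_boot + 1)
  structure(
    list(statistic = stat, p_value = p_value, success = p_value > cutoff,
         p_hat = p_hat, n = length(x), n_boot = n_boot, cutoff = cutoff,
         sample = x),
    class = "cvm_gof"
  )
}

# W^2 over cells 1..max(x) with an aggregated tail cell; the tail cell
# contributes zero because both CDFs are 1 there.
cvm_discrete_stat <- function(x, p) {
  n <- length(x)
  kmax <- max(x)
  cells <- seq_len(kmax)
  pj <- dlogseries(cells, p)
  F_fit <- cumsum(pj)
  F_obs <- cumsum(tabulate(x, nbins = kmax)) / n
  n * sum(pj * (F_obs - F_fit)^2)
}

#' @export
print.cvm_gof <- function(x, ...) {
  cat(sprintf(
    "<cvm_gof> discrete Cramér-von Mises vs log-series\n  n = %d, fitted p = %.6g\n  W^2 = %.4g, bootstrap p-value = %.4g (%d replicates) -> %s\n",
    x$n, x$p_hat, x$statistic, x$p_value, x$n_boot,
    if (x$success) "fit retained" else "fit rejected"))
  invisible(x)
}

#' @export
tidy.cvm_gof <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 success = x$success, p_hat = x$p_hat, n = x$n,
                 n_boot = x$n_boot, cutoff = x$cutoff)
}

#' @export
glance.cvm_gof <- function(x, ...) tidy(x)

#' @export
autoplot.cvm_gof <- function(object, ...) {
  emp <- tibble::tibble(abundance = object$sample)
  kmax <- max(object$sample)
  fit <- tibble::tibble(
    abundance = seq_len(kmax),
    expected = length(object$sample) * dlogseries(seq_len(kmax), object$p_hat)
  )
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$abundance)) +
    ggplot2::geom_histogram(bins = min(30, kmax), fill = "grey70") +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(y = .data$expected), colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "abundance", y = "species count",
                  title = sprintf("SAD vs fitted log-series (p-value %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}

#' Logistic-regression estimate of the neutrality threshold
#'
#' Fits a maximum-likelihood logistic regression of fit success on a
#' non-neutrality index and reports the index value at which the fitted
#' success probability crosses `prob_cutoff` (for the default 0.5 this is
#' `-b0/b1`). The standard error comes from the delta method on the
#' coefficient covariance. Complete separation is detected and flagged: the
#' threshold is then bracketed between the extreme observed indices and the
#' SE is unreliable.
#'
#' @param data Data frame with one row per tested community.
#' @param index,success Column names (tidy-eval) holding the non-neutrality
#'   index and the logical/0-1 fit outcome.
#' @param prob_cutoff Success probability defining the threshold
#'   (default 0.5).
#' @return A `threshold_estimate`: list with `threshold`, `se`,
#'   `coefficients`, `prob_cutoff`, `separation`, `data`.
#' @examples
#' d <- tibble::tibble(cv = rep(seq(0.05, 0.45, by = 0.1), each = 20))
#' d$ok <- withr::with_seed(1, stats::rbinom(nrow(d), 1, stats::plogis(10 * (0.25 - d$cv))))
#' logistic_threshold(d, cv, ok)
#' @export
logistic_threshold <- function(data, index, success, prob_cutoff = 0.5) {
  x <- dplyr::pull(data, {{ index }})
  y <- as.numeric(dplyr::pull(data, {{ success }}))
  if (length(unique(y)) < 2) {
    stop("both successful and rejected fits are required to locate a threshold")
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  beta <- stats::coef(fit)
  # complete separation: divergent slope / fitted probs all ~0 or ~1
  phat <- stats::fitted(fit)
  separation <- !fit$converged || abs(beta[2]) > 1e3 ||
    all(phat > 1 - 1e-8 | phat < 1e-8)
  logit_c <- stats::qlogis(prob_cutoff)
  threshold <- (logit_c - beta[1]) / beta[2]
  if (separation) {
    lo <- suppressWarnings(max(x[y == 1]))
    hi <- suppressWarnings(min(x[y == 0]))
    threshold <- mean(c(lo, hi))
    se <- NA_real_
  } else {
    V <- stats::vcov(fit)
    grad <- c(-1 / beta[2], -(logit_c - beta[1]) / beta[2]^2)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  structure(
    list(threshold = unname(threshold), se = unname(se),
         coefficients = beta, vcov = if (separation) NULL else stats::vcov(fit),
         prob_cutoff = prob_cutoff, separation = separation,
         data = tibble::tibble(index = x, success = y)),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> index at %g%% success probability: %.4g (SE %.3g)%s\n",
    100 * x$prob_cutoff, x$threshold, x$se,
    if (x$separation) " [complete separation: bracketed, SE unreliable]" else ""))
  invisible(x)
}

#' @export
tidy.threshold_estimate <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, se = x$se,
                 intercept = unname(x$coefficients[1]),
                 slope = unname(x$coefficients[2]),
                 prob_cutoff = x$prob_cutoff, separation = x$separation)
}

#' @export
glance.threshold_estimate <- function(x, ...) tidy(x)

#' @export
autoplot.threshold_estimate <- function(object, ...) {
  d <- object$data |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(p = mean(.data$success), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(se = sqrt(.data$p * (1 - .data$p) / .data$n))
  curve <- tibble::tibble(index = seq(min(d$index), max(d$index),
                                      length.out = 200))
  curve$p <- stats::plogis(object$coefficients[1] +
                             object$coefficients[2] * curve$index)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$p - .data$se),
                                          ymax = pmin(1, .data$p + .data$se))) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$prob_cutoff, linetype = 3) +
    ggplot2::labs(x = "non-neutrality index", y = "P(log-series fit retained)") +
    ggplot2::theme_minimal()
}

#' Binned extinction-time statistics vs the neutral prediction
#'
#' Assigns each linked (abundance, wait-until-extinction) pair to a
#' logarithmic abundance bin (base 2 by default), and reports the per-bin
#' mean wait, its standard error, the count, and the neutral life expectancy
#' evaluated at the bin's geometric-mean abundance.
#'
#' @param linked_obs Tibble with columns `abundance` and `wait_generations`
#'   (as produced in `cr_trajectory$linked_obs`).
#' @param p Log-series parameter for the neutral prediction; fit it from the
#'   realized mean abundance of the run being tested.
#' @param bin_base Base of the logarithmic binning (default 2).
#' @return Tibble `(bin, abundance_gm, mean_wait, se_wait, n_obs,
#'   predicted_wait, flagged)`; single-observation bins have `se_wait = NA`
#'   and are flagged.
#' @export
extinction_statistics <- function(linked_obs, p, bin_base = 2) {
  if (nrow(linked_obs) == 0) stop("extinction log is empty")
  out <- linked_obs |>
    dplyr::mutate(bin = floor(log(.data$abundance, base = bin_base))) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      abundance_gm = exp(mean(log(.data$abundance))),
      mean_wait = mean(.data$wait_generations),
      se_wait = stats::sd(.data$wait_generations) / sqrt(dplyr::n()),
      n_obs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      predicted_wait = neutral_extinction_time(pmax(1, .data$abundance_gm), p),
      flagged = .data$n_obs < 2
    )
  if (any(out$flagged)) {
    warning(sum(out$flagged), " bin(s) with a single observation: SE undefined")
  }
  out
}

#' Observed-vs-predicted extinction-time slope
#'
#' Weighted regression through the origin of the binned mean waits on the
#' neutral predictions; a slope of 1 is a perfect match to neutral drift,
#' above 1 the neutral model underpredicts life expectancy.
#'
#' @param stats_tbl Output of [extinction_statistics()].
#' @param min_obs Drop bins with fewer observations (default 5).
#' @return Tibble with `slope`, `se`, `n_bins`.
#' @export
extinction_slope <- function(stats_tbl, min_obs = 5) {
  d <- dplyr::filter(stats_tbl, .data$n_obs >= min_obs)
  if (nrow(d) < 2) stop("need at least two well-populated bins")
  fit <- stats::lm(mean_wait ~ 0 + predicted_wait, data = d,
                   weights = d$n_obs)
  tibble::tibble(slope = unname(stats::coef(fit)[1]),
                 se = summary(fit)$coefficients[1, 2],
                 n_bins = nrow(d))
}

#' Empirical variance of relative abundance fluctuations
#'
#' For an ensemble of replicate histories started from a common snapshot,
#' computes for each species with initial abundance `n0 >= n0_min` the
#' across-history variance of `D(t) = (n(t) - n0) / n0`, then averages over
#' qualifying species, with the standard error of that mean. Species are
#' treated as having abundance 0 from their first extinction (turnover)
#' onwards within each history, so supply abundances already zeroed, or pass
#' each history's extinction log via `zero_after`.
#'
#' @param ensemble Tibble with columns `history`, `time_generations`,
#'   `species`, `abundance`; time 0 rows define `n0`.
#' @param n0_min Minimum initial abundance for a species to qualify
#'   (default 20).
#' @param horizon Use times `<= horizon` generations (default 100).
#' @param zero_after Optional tibble (`history`, `species`,
#'   `time_generations`) of first-extinction times; abundances at later
#'   times are set to 0.
#' @return Tibble `(t, var_D, se, n_species)`.
#' @export
empirical_var_D <- function(ensemble, n0_min = 20, horizon = 100,
                            zero_after = NULL) {
  if (dplyr::n_distinct(ensemble$history) < 2) {
    stop("need at least two replicate histories")
  }
  d <- dplyr::filter(ensemble, .data$time_generations <= horizon)
  if (!is.null(zero_after) && nrow(zero_after) > 0) {
    first_ext <- zero_after |>
      dplyr::group_by(.data$history, .data$species) |>
      dplyr::summarise(t_ext = min(.data$time_generations), .groups = "drop")
    d <- d |>
      dplyr::left_join(first_ext, by = c("history", "species")) |>
      dplyr::mutate(abundance = ifelse(
        !is.na(.data$t_ext) & .data$time_generations >= .data$t_ext,
        0L, .data$abundance)) |>
      dplyr::select(-"t_ext")
  }
  n0 <- d |>
    dplyr::filter(.data$time_generations == min(.data$time_generations)) |>
    dplyr::select("history", "species", n0 = "abundance")
  qualifying <- n0 |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n0 = .data$n0[1], .groups = "drop") |>
    dplyr::filter(.data$n0 >= n0_min)
  if (nrow(qualifying) == 0) {
    stop("no species meets the n0 >= ", n0_min, " cutoff")
  }
  d |>
    dplyr::inner_join(qualifying, by = "species") |>
    dplyr::mutate(D = (.data$abundance - .data$n0) / .data$n0) |>
    dplyr::group_by(.data$species, t = .data$time_generations) |>
    dplyr::summarise(v = stats::var(.data$D), .groups = "drop") |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(var_D = mean(.data$v),
                     se = stats::sd(.data$v) / sqrt(dplyr::n()),
                     n_species = dplyr::n(), .groups = "drop")
}

#' Mean pairwise cosine of observed consumption preferences
#'
#' Treats each consumer's column of per-resource consumption-event counts as
#' its empirical preference vector, computes the cosine similarity for every
#' unordered consumer pair, and returns the mean with a normal-approximation
#' 95% confidence interval over pairs (pairs are treated as approximately
#' independent; the method is recorded in the output). Consumers with zero
#' recorded events are excluded with a warning.
#'
#' @param event_counts K x S matrix of consumption-event counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean_cosine`, `ci` (length 2), `se`, `n_pairs`,
#'   `n_consumers`, `method`.
#' @export
observed_preference_cosines <- function(event_counts, conf_level = 0.95) {
  M <- as.matrix(event_counts)
  tot <- colSums(M)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " consumer(s) with no recorded events excluded")
    M <- M[, tot > 0, drop = FALSE]
  }
  S <- ncol(M)
  if (S < 2) stop("need at least two consumers with recorded events")
  U <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  G <- crossprod(U)
  cosines <- G[upper.tri(G)]
  m <- mean(cosines)
  se <- stats::sd(cosines) / sqrt(length(cosines))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(mean_cosine = m, ci = c(m - z * se, m + z * se), se = se,
       n_pairs = length(cosines), n_consumers = S,
       method = "normal approximation over unordered pairs")
}
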
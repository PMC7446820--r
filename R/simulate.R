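#' Event rates of the stochastic consumer-resource process
#'
#' Pure-R evaluation of the transition rates at a given state: resource
#' inflow `rho_k`, consumer death `eta_i N_i`, and consumption of resource k
#' by consumer i at `R_k C_ki N_i`, split into a birth fraction `eps` and a
#' non-birth fraction `1 - eps`. This is the reference implementation used to
#' cross-check the compiled simulator; the total rate is invariant to `eps`.
#'
#' @param params A [community_params()] object.
#' @param C Consumption matrix.
#' @param N Integer consumer abundances (length S, all >= 1).
#' @param R Integer resource abundances (length K, all >= 0).
#' @return A `rate_set`: list with `inflow` (K), `death` (S),
#'   `cons_birth` (K x S), `cons_nobirth` (K x S), and `total`.
#' @export
event_rates <- function(params, C, N, R) {
  M <- cm_entries(C)
  if (any(N < 1)) stop("consumer abundances must be >= 1 (speciation floor)")
  if (any(R < 0)) stop("resource abundances must be >= 0")
  cons <- (R * M) %*% diag(N, length(N))     # R_k C_ki N_i
  out <- list(
    inflow = params$rho,
    death = params$eta * N,
    cons_birth = params$eps * cons,
    cons_nobirth = (1 - params$eps) * cons
  )
  out$total <- sum(out$inflow) + sum(out$death) + sum(cons)
  class(out) <- "rate_set"
  out
}

#' Draw the next event and waiting time (reference implementation)
#'
#' Samples a waiting time `~ Exponential(total rate)` and an event category
#' with probability proportional to its rate. Consumption events select the
#' resource first (probability proportional to `R_k (CN)_k`) and then the
#' consumer (proportional to `C_ki N_i`), which is exactly equivalent to
#' joint selection. Used for unit-level validation; the production path is
#' the compiled event loop inside [simulate_community()].
#'
#' @param rates A `rate_set` from [event_rates()].
#' @return List with `type` (one of `"inflow"`, `"death"`, `"cons_birth"`,
#'   `"cons_nobirth"`), `resource`, `species` (NA where not applicable) and
#'   `wait`.
#' @export
draw_next_event <- function(rates) {
  if (rates$total <= 0) stop("total event rate is zero: absorbing state")
  wait <- stats::rexp(1, rates$total)
  pools <- c(sum(rates$inflow), sum(rates$death),
             sum(rates$cons_birth), sum(rates$cons_nobirth))
  type <- c("inflow", "death", "cons_birth", "cons_nobirth")[
    sample.int(4, 1, prob = pools)]
  resource <- species <- NA_integer_
  if (type == "inflow") {
    resource <- sample.int(length(rates$inflow), 1, prob = rates$inflow)
  } else if (type == "death") {
    species <- sample.int(length(rates$death), 1, prob = rates$death)
  } else {
    mat <- if (type == "cons_birth") rates$cons_birth else rates$cons_nobirth
    by_resource <- rowSums(mat)
    resource <- sample.int(nrow(mat), 1, prob = by_resource)
    species <- sample.int(ncol(mat), 1, prob = mat[resource, ])
  }
  list(type = type, resource = resource, species = species, wait = wait)
}

#' Apply an event to a state (reference implementation)
#'
#' Bookkeeping for one event, including the speciation floor: a death event
#' drawn for a species at abundance 1 leaves the state unchanged and records
#' an extinction (turnover) instead.
#'
#' @param N,R State vectors.
#' @param event List as returned by [draw_next_event()].
#' @return List with updated `N`, `R` and logical `extinction`.
#' @export
apply_event <- function(N, R, event) {
  extinction <- FALSE
  switch(event$type,
    inflow = { R[event$resource] <- R[event$resource] + 1 },
    death = {
      if (N[event$species] == 1) {
        extinction <- TRUE
      } else {
        N[event$species] <- N[event$species] - 1
      }
    },
    cons_nobirth = {
      if (R[event$resource] == 0) stop("consumption drawn from an empty resource")
      R[event$resource] <- R[event$resource] - 1
    },
    cons_birth = {
      if (R[event$resource] == 0) stop("consumption drawn from an empty resource")
      R[event$resource] <- R[event$resource] - 1
      N[event$species] <- N[event$species] + 1
    },
    stop("unknown event type")
  )
  list(N = N, R = R, extinction = extinction)
}

#' Simulate the stochastic consumer-resource community
#'
#' Exact continuous-time simulation of the event process with the
#' abundance-1 speciation floor. Time is scheduled in generations (one
#' generation = `1/mean(eta)`, the expected individual lifespan). After
#' `burn_in` generations the state is snapshotted every `cadence` generations
#' for `n_generations` further generations; every snapshot observation of a
#' species joins that species' pending list, which is flushed into the
#' extinction log when the species next suffers a turnover, yielding linked
#' (abundance, wait-until-extinction) pairs.
#'
#' @param C A `consumption_matrix`.
#' @param params A [community_params()]; defaults to calibrating `C` at
#'   `(n, r, eps)` if those are supplied instead.
#' @param burn_in Generations to discard before the first snapshot.
#' @param n_generations Generations of recorded runtime after burn-in.
#' @param cadence Generations between snapshots.
#' @param record_events Accumulate the K x S matrix of consumption-event
#'   counts over the recorded window plus burn-in.
#' @param record_resources Also snapshot resource abundances.
#' @param init Optional list with integer `N` and `R` giving the initial
#'   state; defaults to the deterministic equilibrium `round(n)`, `round(r)`.
#' @param seed Integer seed; the trajectory is bit-for-bit reproducible from
#'   `(C, params, schedule, seed)`.
#' @return A `cr_trajectory`: list with tibbles `snapshots`
#'   (`time_generations`, `species`, `abundance`), `resources`
#'   (`time_generations`, `resource`, `abundance`), `extinctions`
#'   (`species`, `time_generations`), `linked_obs` (`species`, `abundance`,
#'   `obs_generations`, `ext_generations`, `wait_generations`), matrix
#'   `event_counts` (or NULL), vectors `final_N`, `final_R`, and `meta`.
#' @examples
#' C <- generalist_matrix(5, 5, cv = 0, seed = 1)
#' p <- community_params(C, n = 20, r = 20)
#' traj <- simulate_community(C, p, burn_in = 10, n_generations = 50,
#'                            cadence = 10, seed = 1)
#' dplyr::count(traj$snapshots, time_generations)
#' @export
simulate_community <- function(C, params, burn_in = 500, n_generations = 2000,
                               cadence = 50, record_events = FALSE,
                               record_resources = TRUE, init = NULL,
                               seed = NULL) {
  stopifnot(inherits(params, "community_params"))
  if (burn_in < 0 || n_generations <= 0 || cadence <= 0) {
    stop("schedule entries must be positive (burn_in may be zero)")
  }
  M <- cm_entries(C)
  if (is.null(init)) {
    N0 <- rep(max(1L, as.integer(round(params$n))), params$S)
    R0 <- rep(as.integer(round(params$r)), params$K)
  } else {
    N0 <- as.integer(init$N); R0 <- as.integer(init$R)
  }
  snaps <- seq(burn_in + cadence, burn_in + n_generations, by = cadence)
  if (length(snaps) == 0) stop("schedule yields no snapshots")
  run <- function() {
    ssa_run(M, params$rho, params$eta, params$eps, N0, R0,
            params$generation_time, snaps, max(snaps), record_resources,
            record_events)
  }
  raw <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  S <- params$S; K <- params$K
  snapshots <- tibble::tibble(
    time_generations = rep(raw$snapshot_gens, times = S),
    species = rep(seq_len(S), each = length(raw$snapshot_gens)),
    abundance = as.vector(raw$N)
  )
  resources <- if (record_resources) {
    tibble::tibble(
      time_generations = rep(raw$snapshot_gens, times = K),
      resource = rep(seq_len(K), each = length(raw$snapshot_gens)),
      abundance = as.vector(raw$R)
    )
  } else NULL
  extinctions <- tibble::tibble(species = raw$ext_species,
                                time_generations = raw$ext_gen)
  linked_obs <- tibble::tibble(
    species = raw$lnk_species,
    abundance = raw$lnk_abundance,
    obs_generations = raw$lnk_obs_gen,
    ext_generations = raw$lnk_ext_gen,
    wait_generations = raw$lnk_ext_gen - raw$lnk_obs_gen
  )
  structure(
    list(snapshots = snapshots, resources = resources,
         extinctions = extinctions, linked_obs = linked_obs,
         event_counts = raw$event_counts,
         final_N = raw$final_N, final_R = raw$final_R,
         meta = list(S = S, K = K, eps = params$eps, n = params$n,
                     r = params$r, scenario =
                       if (inherits(C, "consumption_matrix")) C$scenario else "custom",
                     burn_in = burn_in, n_generations = n_generations,
                     cadence = cadence, seed = seed,
                     n_events = raw$n_events, event_type_counts = raw$counts)),
    class = "cr_trajectory"
  )
}

#' @export
print.cr_trajectory <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<cr_trajectory> S = %d, K = %d (%s), %d snapshots, %.3g events\n  burn-in %g + %g generations recorded every %g; %d extinctions logged\n",
    m$S, m$K, m$scenario, length(unique(x$snapshots$time_generations)),
    m$n_events, m$burn_in, m$n_generations, m$cadence, nrow(x$extinctions)))
  invisible(x)
}

#' Final-snapshot species abundance distribution
#'
#' @param traj A `cr_trajectory`.
#' @return Integer vector of the S abundances at the last snapshot.
#' @export
final_sad <- function(traj) {
  last_t <- max(traj$snapshots$time_generations)
  traj$snapshots$abundance[traj$snapshots$time_generations == last_t]
}

#' Stationarity check: first- vs second-half total abundance
#'
#' Compares the mean total consumer abundance over the first and second half
#' of the recorded window; a large relative difference signals insufficient
#' burn-in.
#'
#' @param traj A `cr_trajectory`.
#' @return Tibble with `mean_first`, `mean_second`, `rel_diff`.
#' @export
stationarity_check <- function(traj) {
  tot <- traj$snapshots |>
    dplyr::group_by(.data$time_generations) |>
    dplyr::summarise(total = sum(.data$abundance), .groups = "drop")
  half <- stats::median(tot$time_generations)
  m1 <- mean(tot$total[tot$time_generations <= half])
  m2 <- mean(tot$total[tot$time_generations > half])
  tibble::tibble(mean_first = m1, mean_second = m2,
                 rel_diff = abs(m2 - m1) / ((m1 + m2) / 2))
}

#' Reference simulator built from the R-level operations
#'
#' Slow event-by-event loop using [event_rates()], [draw_next_event()] and
#' [apply_event()]; only suitable for tiny systems, where it serves as an
#' implementation-independent cross-check of the compiled core.
#'
#' @inheritParams simulate_community
#' @param n_events Number of events to simulate.
#' @param thin Record the state every `thin` events.
#' @return Tibble with one row per recorded state: `event`, `t`, then
#'   `N1..NS`, `R1..RK` columns.
#' @export
simulate_reference <- function(C, params, n_events = 1000, thin = 1,
                               init = NULL, seed = NULL) {
  M <- cm_entries(C)
  if (is.null(init)) {
    N <- rep(max(1L, round(params$n)), params$S)
    R <- rep(round(params$r), params$K)
  } else {
    N <- init$N; R <- init$R
  }
  body <- function() {
    t <- 0
    rows <- list()
    for (e in seq_len(n_events)) {
      rates <- event_rates(params, M, N, R)
      ev <- draw_next_event(rates)
      t <- t + ev$wait
      st <- apply_event(N, R, ev)
      N <<- st$N; R <<- st$R
      if (e %% thin == 0) {
        rows[[length(rows) + 1L]] <- c(event = e, t = t, N = N, R = R)
      }
    }
    tibble::as_tibble(do.call(rbind, rows))
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}
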
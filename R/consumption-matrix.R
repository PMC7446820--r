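#' Build a generalist consumption matrix
#'
#' Samples every entry of the `K x S` consumption matrix independently from a
#' distribution with mean `mean` and standard deviation `mean * cv`. In the
#' generalist scenario each consumer uses every resource, with unstructured
#' variation in preferences; `cv = 0` recovers the neutral limit where all
#' consumers are identical.
#'
#' For the uniform distribution the support is the symmetric interval
#' `[mean - sqrt(3) * sd, mean + sqrt(3) * sd]` (the unique uniform with the
#' requested mean and variance), which requires `cv <= 1/sqrt(3)` so the lower
#' endpoint stays non-negative. Normal draws that land below zero are
#' resampled rather than truncated (truncation would bias the mean); the
#' number of resampled entries is recorded in the result.
#'
#' @param S Number of consumer species (columns).
#' @param K Number of resources (rows).
#' @param mean Mean consumption rate `mu` (> 0), per resource-unit per
#'   consumer per unit time.
#' @param cv Coefficient of variation `sigma/mu` (>= 0) of the entries.
#' @param seed Integer seed for the draw; recorded in the object.
#' @param distribution `"uniform"` (default) or `"normal"`.
#' @return A `consumption_matrix`: list with `entries` (K x S numeric
#'   matrix), `scenario`, `params` and `seed`.
#' @examples
#' C <- generalist_matrix(5, 5, mean = 1, cv = 0.2, seed = 1)
#' non_neutrality_index(C)
#' @export
generalist_matrix <- function(S, K = S, mean = 1, cv = 0.1, seed = NULL,
                              distribution = c("uniform", "normal")) {
  distribution <- match.arg(distribution)
  stopifnot(S >= 1, K >= 1, is.numeric(mean), is.numeric(cv))
  if (mean <= 0) stop("`mean` must be positive")
  if (cv < 0) stop("`cv` must be non-negative")
  if (distribution == "uniform" && cv > 1 / sqrt(3) + 1e-12) {
    stop("uniform generalist matrix requires cv <= 1/sqrt(3) ~ 0.577 ",
         "(the support would otherwise include negative rates)")
  }
  sd <- mean * cv
  n_resampled <- 0L
  draw <- function() {
    if (distribution == "uniform") {
      half <- sqrt(3) * sd
      matrix(stats::runif(K * S, mean - half, mean + half), K, S)
    } else {
      x <- stats::rnorm(K * S, mean, sd)
      while (any(bad <- x < 0)) {
        n_resampled <<- n_resampled + sum(bad)
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
      }
      matrix(x, K, S)
    }
  }
  entries <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_consumption_matrix(
    entries, "generalist",
    params = list(mean = mean, cv = cv, sd = sd, distribution = distribution,
                  n_resampled = n_resampled),
    seed = seed
  )
}

#' Build a specialist consumption matrix
#'
#' Square `S x S` matrix with every diagonal entry equal to `Cd` (each
#' consumer's privately preferred resource) and every off-diagonal entry equal
#' to `Co`. `Cd = Co` is the neutral limit; `Co = 0` is complete niche
#' differentiation (non-interacting consumers, NNI = 1).
#'
#' @param S Number of consumers (= number of resources).
#' @param Cd Diagonal (preferred-resource) consumption rate, > 0.
#' @param Co Off-diagonal rate, `0 <= Co <= Cd`.
#' @return A `consumption_matrix`.
#' @examples
#' specialist_matrix(3, Cd = 2, Co = 1)$entries
#' @export
specialist_matrix <- function(S, Cd, Co = 1) {
  stopifnot(S >= 1, is.numeric(Cd), is.numeric(Co))
  if (Cd <= 0) stop("`Cd` must be positive")
  if (Co < 0) stop("`Co` must be non-negative")
  if (Cd < Co) stop("specialist scenario requires Cd >= Co")
  entries <- matrix(Co, S, S)
  diag(entries) <- Cd
  new_consumption_matrix(entries, "specialist",
                         params = list(Cd = Cd, Co = Co), seed = NULL)
}

#' Wrap an arbitrary non-negative matrix as a consumption matrix
#'
#' @param entries K x S non-negative numeric matrix.
#' @param scenario Scenario tag; defaults to `"custom"`.
#' @param params,seed Optional metadata carried along.
#' @export
as_consumption_matrix <- function(entries, scenario = "custom",
                                  params = list(), seed = NULL) {
  entries <- as.matrix(entries)
  new_consumption_matrix(entries, scenario, params, seed)
}

new_consumption_matrix <- function(entries, scenario, params, seed) {
  if (any(entries < 0)) stop("consumption rates must be non-negative")
  storage.mode(entries) <- "double"
  structure(
    list(entries = entries, scenario = scenario, params = params, seed = seed),
    class = "consumption_matrix"
  )
}

#' @export
print.consumption_matrix <- function(x, ...) {
  cat(sprintf("<consumption_matrix> %s, %d resources x %d consumers\n",
              x$scenario, nrow(x$entries), ncol(x$entries)))
  if (x$scenario == "generalist") {
    cat(sprintf("  mean = %g, cv = %g (%s draws)\n",
                x$params$mean, x$params$cv, x$params$distribution))
  } else if (x$scenario == "specialist") {
    cat(sprintf("  Cd = %g, Co = %g\n", x$params$Cd, x$params$Co))
  }
  invisible(x)
}

#' @export
dim.consumption_matrix <- function(x) dim(x$entries)

cm_entries <- function(C) {
  if (inherits(C, "consumption_matrix")) C$entries else as.matrix(C)
}

#' Non-neutrality index of a consumption matrix
#'
#' `NNI = 1 - cos`, where `cos` is the cosine similarity between consumers'
#' resource-preference vectors (columns of C), averaged over all unordered
#' species pairs. Identical preferences give NNI = 0 (complete neutrality);
#' pairwise-orthogonal preferences (each consumer eats its own resource only)
#' give NNI = 1 (complete niche differentiation).
#'
#' @param C A `consumption_matrix` or plain K x S matrix.
#' @return A single number in `[0, 1]`.
#' @examples
#' non_neutrality_index(specialist_matrix(2, Cd = 2, Co = 1)) # 1 - 4/5
#' @export
non_neutrality_index <- function(C) {
  M <- cm_entries(C)
  S <- ncol(M)
  if (S < 2) stop("NNI is undefined for fewer than two consumers")
  norms <- sqrt(colSums(M^2))
  if (any(norms == 0)) stop("NNI is undefined when a consumer has an all-zero preference column")
  U <- sweep(M, 2, norms, "/")
  G <- crossprod(U)                     # S x S cosine matrix
  mean_cos <- (sum(G) - S) / (S * (S - 1))
  1 - mean_cos
}

#' Closed-form NNI of the specialist scenario
#'
#' For the specialist matrix every unordered pair has the same cosine,
#' `(2*Cd*Co + (S-2)*Co^2) / (Cd^2 + (S-1)*Co^2)`, so the NNI has a closed
#' form in `(S, Cd/Co)`. Used to place specialist scans on the common NNI
#' axis without constructing matrices.
#'
#' @inheritParams specialist_matrix
#' @export
specialist_nni <- function(S, Cd, Co = 1) {
  stopifnot(S >= 2)
  if (Co == 0) return(rep(1, length(Cd)))
  cosv <- (2 * Cd * Co + (S - 2) * Co^2) / (Cd^2 + (S - 1) * Co^2)
  1 - cosv
}

#' Diagonal/off-diagonal ratio giving a target specialist NNI
#'
#' Inverts [specialist_nni()] (with `Co = 1`) for `Cd`; `nni = 1` maps to
#' `Inf` (fully specialized, `Co = 0`).
#'
#' @param S Number of consumers.
#' @param nni Target non-neutrality index in `[0, 1)` (or 1 for `Inf`).
#' @export
specialist_cd_for_nni <- function(S, nni) {
  stopifnot(all(nni >= 0), all(nni <= 1))
  vapply(nni, function(x) {
    if (x >= 1) return(Inf)
    cosv <- 1 - x
    # cos = (2 d + (S-2)) / (d^2 + S-1) with Co = 1; larger root of the quadratic
    a <- cosv; b <- -2; cc <- cosv * (S - 1) - (S - 2)
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }, numeric(1))
}

#' Write / read a consumption matrix as delimited text with a JSON sidecar
#'
#' Resources are rows, consumers are columns. Scenario metadata and the seed
#' go to `<path>.json`.
#'
#' @param C A `consumption_matrix`.
#' @param path File path for the tab-delimited matrix.
#' @export
write_consumption_matrix <- function(C, path) {
  stopifnot(inherits(C, "consumption_matrix"))
  utils::write.table(C$entries, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(scenario = C$scenario, params = C$params, seed = C$seed,
               K = nrow(C$entries), S = ncol(C$entries))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_consumption_matrix
#' @export
read_consumption_matrix <- function(path) {
  entries <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(entries) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    new_consumption_matrix(entries, meta$scenario, as.list(meta$params),
                           meta$seed)
  } else {
    as_consumption_matrix(entries)
  }
}
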
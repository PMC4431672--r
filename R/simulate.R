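#' Configuration for the synthetic survey generator
#'
#' Defaults emulate a 130-host cashew survey: five host populations,
#' three surveyed by two observers (27 + 27 + 26 = 80 hosts) and two by
#' three observers (25 + 25 = 50 hosts); crown diameters drawn from a
#' normal distribution with mean 5.3 m and sd 2.5 m truncated to
#' [0.5, 15] m; 40% of hosts with an infected neighbour within 50 m; 9%
#' of hosts carrying an adult infection. The default coefficient vectors
#' give occupancy rising with host size and neighbour infection and
#' detectability around 0.78 at the covariate means, falling with host
#' size and rising with neighbour infection.
#'
#' @param populations list of `(n_hosts, n_surveys)` pairs, one per
#'   population; `n_surveys` must be 2 or 3.
#' @param size_dist numeric vector `(mean, sd, lower, upper)` in metres
#'   for the truncated-normal crown-diameter distribution.
#' @param prob_neighbor probability a host has an infected neighbour.
#' @param prob_infection probability a host carries an adult infection.
#' @param beta_psi logit-scale occupancy coefficients
#'   `(intercept, size, neighbor, infection)`; unused effects zero.
#' @param beta_p logit-scale detectability coefficients, same layout.
#' @param seed integer RNG seed; the same seed and configuration always
#'   reproduce the identical dataset.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(populations = list(c(27, 2), c(27, 2), c(26, 2),
                                          c(25, 3), c(25, 3)),
                       size_dist = c(mean = 5.3, sd = 2.5,
                                     lower = 0.5, upper = 15),
                       prob_neighbor = 0.4,
                       prob_infection = 0.09,
                       beta_psi = c(0.25, 0.18, 1.0, 0),
                       beta_p = c(1.75, -0.15, 0.8, 0),
                       seed = 1L) {
  cfg <- list(populations = populations, size_dist = unname(size_dist),
              prob_neighbor = prob_neighbor, prob_infection = prob_infection,
              beta_psi = beta_psi, beta_p = beta_p, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pops <- cfg$populations
  if (length(pops) == 0 ||
      !all(vapply(pops, function(p) length(p) == 2 && p[1] >= 1 &&
                    p[2] %in% c(2, 3), logical(1)))) {
    stop("configuration error: populations must be (n_hosts, n_surveys) pairs with 2 or 3 surveys",
         call. = FALSE)
  }
  sd <- cfg$size_dist
  if (length(sd) != 4 || sd[2] <= 0 || sd[3] <= 0 || sd[3] >= sd[4]) {
    stop("configuration error: size_dist must be (mean, sd, lower, upper) with 0 < lower < upper",
         call. = FALSE)
  }
  for (p in c(cfg$prob_neighbor, cfg$prob_infection)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (length(cfg$beta_psi) != 4 || length(cfg$beta_p) != 4 ||
      any(!is.finite(c(cfg$beta_psi, cfg$beta_p)))) {
    stop("configuration error: beta_psi and beta_p must be finite length-4 vectors",
         call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("configuration error: seed must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}

# Inverse-CDF draw from N(mean, sd) truncated to [lower, upper].
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Simulate a detection/non-detection survey dataset
#'
#' Draws host covariates, a latent occupancy state `z` from the logit
#' occupancy model, and per-occasion Bernoulli detections from the logit
#' detectability model, with occasions beyond each population's survey
#' effort marked missing. The latent state and the generating
#' probabilities are attached as a truth-side attribute (see
#' [sim_truth()]); estimation code never reads it.
#'
#' @param config a [sim_config()].
#' @return A [survey_dataset()] carrying a `truth` attribute with
#'   columns `host_id`, `z`, `psi_true`, `p_true`.
#' @examples
#' ds <- simulate_dataset(sim_config(seed = 42))
#' ds$n_sites
#' table(rowSums(!is.na(ds$y)))
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n_pop <- vapply(config$populations, `[`, numeric(1), 1)
  n_surv <- vapply(config$populations, `[`, numeric(1), 2)
  n <- sum(n_pop)
  pop_label <- rep(paste0("pop", seq_along(n_pop)), times = n_pop)
  surveys <- rep(n_surv, times = n_pop)
  max_occ <- max(n_surv)

  sd4 <- config$size_dist
  size <- rtruncnorm(n, sd4[1], sd4[2], sd4[3], sd4[4])
  neighbor <- stats::rbinom(n, 1, config$prob_neighbor)
  infection <- stats::rbinom(n, 1, config$prob_infection)

  x <- cbind(1, size, neighbor, infection)
  psi <- stats::plogis(drop(x %*% config$beta_psi))
  p <- stats::plogis(drop(x %*% config$beta_p))
  z <- stats::rbinom(n, 1, psi)

  y <- matrix(NA_integer_, n, max_occ)
  for (j in seq_len(max_occ)) {
    active <- surveys >= j
    y[active, j] <- stats::rbinom(sum(active), 1, z[active] * p[active])
  }

  records <- data.frame(
    host_id = sprintf("h%03d", seq_len(n)),
    population = pop_label,
    size = size, neighbor = neighbor, infection = infection,
    stringsAsFactors = FALSE
  )
  ds <- survey_dataset(records, y)
  attr(ds, "truth") <- data.frame(host_id = records$host_id, z = z,
                                  psi_true = psi, p_true = p)
  ds
}

#' Truth channel of a simulated dataset
#'
#' Returns the latent occupancy states and generating probabilities of a
#' dataset produced by [simulate_dataset()]. Kept separate from the
#' observable records so that fitting code cannot depend on it; intended
#' only for parameter-recovery assertions.
#'
#' @param data a simulated [survey_dataset()].
#' @return Data frame with `host_id`, `z`, `psi_true`, `p_true`.
#' @export
sim_truth <- function(data) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("dataset carries no truth channel", call. = FALSE)
  truth
}

#' Write the truth sidecar of a simulated dataset
#'
#' @param data a simulated [survey_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(data, path) {
  utils::write.csv(sim_truth(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
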
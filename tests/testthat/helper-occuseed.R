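# Shared fixtures and independent oracles, built in code.

# Minimal dataset from explicit histories; covariates default to benign values.
toy_dataset <- function(histories, size = NULL, neighbor = NULL, infection = NULL) {
  n <- length(histories)
  y <- t(vapply(histories, function(h) {
    v <- suppressWarnings(as.integer(strsplit(h, "")[[1]]))
    length(v) <- 3
    v
  }, integer(3)))
  survey_dataset(data.frame(
    host_id = paste0("h", seq_len(n)),
    population = "A",
    size = if (is.null(size)) rep(5, n) else size,
    neighbor = if (is.null(neighbor)) rep(0L, n) else neighbor,
    infection = if (is.null(infection)) rep(0L, n) else infection,
    stringsAsFactors = FALSE
  ), y)
}

# Random small dataset with random covariates and histories (no model behind
# the histories: the likelihood must handle any configuration).
random_dataset <- function(n = 20, p_det = 0.5) {
  y <- matrix(rbinom(n * 3, 1, p_det), n, 3)
  n2 <- sample(seq_len(n), size = floor(n / 3))  # some 2-survey hosts
  y[n2, 3] <- NA
  survey_dataset(data.frame(
    host_id = paste0("h", seq_len(n)),
    population = sample(c("A", "B"), n, replace = TRUE),
    size = runif(n, 0.5, 15),
    neighbor = sample(0:1, n, replace = TRUE),
    infection = sample(0:1, n, replace = TRUE),
    stringsAsFactors = FALSE
  ), y)
}

# Independent likelihood oracle: per-host probability by explicit summation
# over the latent state z in {0, 1}.
oracle_nll <- function(data, spec, beta_psi, beta_p) {
  xp_cols <- function(terms) cbind(1, as.matrix(data$records[terms]))
  psi <- plogis(drop(xp_cols(spec$psi_terms) %*% beta_psi))
  p <- plogis(drop(xp_cols(spec$p_terms) %*% beta_p))
  ll <- 0
  for (i in seq_len(data$n_sites)) {
    h <- data$y[i, ]
    obs <- !is.na(h)
    # z = 0: possible only if nothing was detected
    pr0 <- (1 - psi[i]) * as.numeric(all(h[obs] == 0))
    # z = 1: Bernoulli(p) per surveyed occasion
    pr1 <- psi[i] * prod(ifelse(h[obs] == 1, p[i], 1 - p[i]))
    ll <- ll + log(pr0 + pr1)
  }
  -ll
}

logit <- function(x) log(x / (1 - x))
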
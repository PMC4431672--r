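#' Specify an occupancy model
#'
#' A model is defined by which site covariates enter the logit-linear
#' occupancy term and which enter the logit-linear detectability term.
#' Both terms always contain an intercept. By default a term may not
#' contain both `size` and `infection` together: adult infections sit on
#' large hosts, and the two covariates are too collinear to separate.
#'
#' @param psi_terms character subset of
#'   `c("size", "neighbor", "infection")` for the occupancy term.
#' @param p_terms same, for the detectability term.
#' @param allow_collinear set `TRUE` to disable the size/infection
#'   exclusion.
#' @return A list of class `occu_spec`.
#' @examples
#' occu_spec(c("size", "neighbor"), c("size", "neighbor"))
#' occu_spec()  # intercept-only: psi(.) p(.)
#' @export
occu_spec <- function(psi_terms = character(), p_terms = character(),
                      allow_collinear = FALSE) {
  known <- c("size", "neighbor", "infection")
  psi_terms <- as.character(psi_terms)
  p_terms <- as.character(p_terms)
  bad <- setdiff(c(psi_terms, p_terms), known)
  if (length(bad) > 0) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(psi_terms) || anyDuplicated(p_terms)) {
    stop("duplicated covariate in a term", call. = FALSE)
  }
  if (!allow_collinear) {
    for (term in list(psi_terms, p_terms)) {
      if (all(c("size", "infection") %in% term)) {
        stop("'size' and 'infection' may not share a term (collinear); ",
             "set allow_collinear = TRUE to override", call. = FALSE)
      }
    }
  }
  structure(list(psi_terms = psi_terms, p_terms = p_terms), class = "occu_spec")
}

term_label <- function(terms) if (length(terms) == 0) "." else paste(terms, collapse = "+")

#' @export
format.occu_spec <- function(x, ...) {
  sprintf("psi(%s) p(%s)", term_label(x$psi_terms), term_label(x$p_terms))
}

#' @export
print.occu_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Intercept-first design matrix for one term.
design_matrix <- function(records, terms) {
  x <- matrix(1, nrow(records), 1 + length(terms))
  for (i in seq_along(terms)) x[, i + 1] <- records[[terms[i]]]
  colnames(x) <- c("(Intercept)", terms)
  x
}

#' Probability of one detection history
#'
#' The latent-state likelihood contribution of a single host. A history
#' with at least one detection proves occupancy, so its probability is
#' `psi` times the product over surveyed occasions of `p_j` (detected)
#' or `1 - p_j` (not detected). An all-zero history confounds a true
#' absence with an occupied host that was missed every time:
#' `psi * prod(1 - p_j) + (1 - psi)`. Missing occasions contribute no
#' factor.
#'
#' @param history vector over occasions with entries 0, 1 or `NA`
#'   (occasion not surveyed).
#' @param psi occupancy probability.
#' @param p per-occasion detection probability: a scalar, a vector over
#'   all occasions (missing entries ignored), or a vector over the
#'   surveyed occasions only.
#' @return The history probability.
#' @examples
#' history_probability(c(0, 1, 0), psi = 1, p = 0.5)        # 0.125
#' history_probability(c(0, 0, 0), psi = 0.3, p = 0.5)      # 0.7375
#' history_probability(c(1, NA, 0), psi = 0.6, p = 0.4)     # 0.144
#' @export
history_probability <- function(history, psi, p) {
  obs <- !is.na(history)
  if (!any(obs)) stop("history has no surveyed occasion", call. = FALSE)
  h <- history[obs]
  if (!all(h %in% c(0, 1))) stop("history entries must be 0, 1 or NA", call. = FALSE)
  if (length(p) == 1) {
    p <- rep(p, sum(obs))
  } else if (length(p) == length(history)) {
    p <- p[obs]
  } else if (length(p) != sum(obs)) {
    stop("p must be scalar, per-occasion, or per surveyed occasion", call. = FALSE)
  }
  if (any(!is.finite(c(psi, p))) || psi < 0 || psi > 1 || any(p < 0) || any(p > 1)) {
    stop("domain error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  cond <- prod(ifelse(h == 1, p, 1 - p))
  if (any(h == 1)) psi * cond else psi * cond + (1 - psi)
}

# Collapse a dataset to the sufficient per-host counts for a model with
# site covariates only (p constant across occasions within a host).
history_counts <- function(data) {
  list(d = rowSums(data$y == 1, na.rm = TRUE),   # detections
       q = rowSums(data$y == 0, na.rm = TRUE))   # non-detections
}

# theta = c(beta_psi, beta_p); returns per-host psi, p on the probability scale.
link_probs <- function(theta, xpsi, xp) {
  k1 <- ncol(xpsi)
  list(psi = stats::plogis(drop(xpsi %*% theta[seq_len(k1)])),
       p = stats::plogis(drop(xp %*% theta[-seq_len(k1)])))
}

#' Negative log-likelihood of an occupancy model
#'
#' Sums `-log` of the per-host detection-history probabilities, with
#' per-host occupancy and detectability obtained from the inverse-logit
#' of the linear predictors defined by `spec`.
#'
#' @param data a [survey_dataset()].
#' @param spec an [occu_spec()].
#' @param beta_psi occupancy coefficients, intercept first, one per
#'   `spec$psi_terms` entry after it.
#' @param beta_p detectability coefficients, same layout.
#' @return The negative log-likelihood; `Inf` when some history has
#'   probability zero under the parameters.
#' @export
occu_nll <- function(data, spec, beta_psi, beta_p) {
  stopifnot(inherits(data, "survey_dataset"), inherits(spec, "occu_spec"))
  if (length(beta_psi) != 1 + length(spec$psi_terms) ||
      length(beta_p) != 1 + length(spec$p_terms)) {
    stop("shape error: coefficient vectors do not conform to the model spec",
         call. = FALSE)
  }
  xpsi <- design_matrix(data$records, spec$psi_terms)
  xp <- design_matrix(data$records, spec$p_terms)
  cnt <- history_counts(data)
  nll_theta(c(beta_psi, beta_p), xpsi, xp, cnt$d, cnt$q)
}

nll_theta <- function(theta, xpsi, xp, d, q) {
  pr <- link_probs(theta, xpsi, xp)
  psi <- pr$psi; p <- pr$p
  ll <- numeric(length(d))
  det <- d > 0
  ll[det] <- log(psi[det]) + d[det] * log(p[det]) + q[det] * log1p(-p[det])
  nd <- !det
  ll[nd] <- log(psi[nd] * (1 - p[nd])^q[nd] + (1 - psi[nd]))
  -sum(ll)
}

# Analytic gradient of nll_theta; same parameterization.
nll_grad <- function(theta, xpsi, xp, d, q) {
  pr <- link_probs(theta, xpsi, xp)
  psi <- pr$psi; p <- pr$p
  det <- d > 0
  gpsi <- gp <- numeric(length(d))
  # detected hosts: ll = log psi + d log p + q log(1-p)
  gpsi[det] <- 1 - psi[det]
  gp[det] <- d[det] * (1 - p[det]) - q[det] * p[det]
  # all-zero hosts: L = psi (1-p)^q + (1 - psi)
  nd <- !det
  Lq <- (1 - p[nd])^q[nd]
  L <- psi[nd] * Lq + (1 - psi[nd])
  gpsi[nd] <- psi[nd] * (1 - psi[nd]) * (Lq - 1) / L
  gp[nd] <- -q[nd] * psi[nd] * p[nd] * Lq / L
  -unname(c(drop(crossprod(xpsi, gpsi)), drop(crossprod(xp, gp))))
}

default_starts <- function(data, spec, k1, k2) {
  detected <- rowSums(data$y == 1, na.rm = TRUE) > 0
  # naive warm start: logistic regression of the detected-once indicator,
  # detection intercept at the logit of the per-survey hit rate among
  # detected hosts
  warm <- rep(0, k1 + k2)
  fit <- tryCatch(
    stats::glm.fit(design_matrix(data$records, spec$psi_terms),
                   as.numeric(detected), family = stats::binomial()),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$coefficients))) {
    warm[seq_len(k1)] <- fit$coefficients
  }
  hits <- sum(data$y[detected, ] == 1, na.rm = TRUE)
  trials <- sum(!is.na(data$y[detected, ]))
  if (trials > 0 && hits > 0 && hits < trials) {
    warm[k1 + 1] <- stats::qlogis(hits / trials)
  }
  up <- dn <- rep(0, k1 + k2)
  up[c(1, k1 + 1)] <- 1
  dn[c(1, k1 + 1)] <- -1
  list(zeros = rep(0, k1 + k2), up = up, down = dn, warm = warm,
       warm_flat = c(warm[seq_len(k1)], rep(0, k2)))
}

#' Fit an occupancy model by maximum likelihood
#'
#' Minimizes the negative detection-history log-likelihood over the
#' unconstrained logit-scale coefficients with quasi-Newton (BFGS)
#' iterations from a deterministic list of starting points (zeros, unit
#' intercepts of either sign, and a warm start from a naive logistic
#' regression of the detected-at-least-once indicator), keeping the best
#' optimum. The variance matrix is the inverse of the numerically
#' differenced observed information at the optimum; when the optimizer
#' fails or the information matrix is singular (typically boundary
#' estimates), the fit is returned with `converged = FALSE` and its
#' confidence intervals are suppressed, never an exception.
#'
#' @param data a [survey_dataset()].
#' @param spec an [occu_spec()].
#' @param starts optional list/matrix of additional start vectors; by
#'   default the deterministic five-start list.
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 1000, reltol = 1e-12)`.
#' @return An object of class `occu_fit` with elements `spec`,
#'   `beta_psi`, `beta_p`, `vcov`, `neg2_loglik`, `K`, `aicc`,
#'   `converged`, `n_sites`.
#' @export
fit_occu <- function(data, spec, starts = NULL,
                     control = list(maxit = 1000, reltol = 1e-12)) {
  stopifnot(inherits(data, "survey_dataset"), inherits(spec, "occu_spec"))
  if (data$n_sites == 0) stop("validation error: empty dataset", call. = FALSE)
  k1 <- 1L + length(spec$psi_terms)
  k2 <- 1L + length(spec$p_terms)
  K <- k1 + k2
  if (data$n_sites <= K + 1) {
    stop("validation error: need more than K + 1 = ", K + 1,
         " sites for AICc", call. = FALSE)
  }
  xpsi <- design_matrix(data$records, spec$psi_terms)
  xp <- design_matrix(data$records, spec$p_terms)
  cnt <- history_counts(data)
  obj <- function(th) nll_theta(th, xpsi, xp, cnt$d, cnt$q)
  grd <- function(th) nll_grad(th, xpsi, xp, cnt$d, cnt$q)

  if (is.null(starts)) starts <- default_starts(data, spec, k1, k2)
  best <- NULL
  opt_ok <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, grd, method = "BFGS", control = control),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      opt_ok <- fit$convergence == 0
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every starting point", call. = FALSE)
  }
  theta <- best$par

  vcov <- matrix(NA_real_, K, K)
  info_ok <- FALSE
  H <- tryCatch(pracma::hessian(obj, theta), error = function(e) NULL)
  if (!is.null(H) && all(is.finite(H))) {
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vi) && all(is.finite(Vi)) && all(diag(Vi) >= 0)) {
      vcov <- (Vi + t(Vi)) / 2
      info_ok <- TRUE
    }
  }
  names(theta) <- c(paste0("psi_", colnames(xpsi)), paste0("p_", colnames(xp)))
  dimnames(vcov) <- list(names(theta), names(theta))
  neg2 <- 2 * best$value
  structure(list(
    spec = spec,
    beta_psi = theta[seq_len(k1)],
    beta_p = theta[-seq_len(k1)],
    vcov = vcov,
    neg2_loglik = neg2,
    K = K,
    aicc = aicc(neg2, K, data$n_sites),
    converged = opt_ok && info_ok,
    n_sites = data$n_sites,
    p_fixed = NULL
  ), class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("Occupancy model:", format(x$spec),
      if (!is.null(x$p_fixed)) sprintf("[p fixed at %g]", x$p_fixed), "\n")
  est <- c(x$beta_psi, x$beta_p)
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = est, se = se), 4))
  cat(sprintf("-2l = %.2f, K = %d, AICc = %.2f, n = %d, converged: %s\n",
              x$neg2_loglik, x$K, x$aicc, x$n_sites, x$converged))
  invisible(x)
}

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(-object$neg2_loglik / 2, df = object$K, class = "logLik")
}

#' Predict occupancy and detectability at covariate profiles
#'
#' Point estimates are the inverse-logit of the fitted linear
#' predictors. 95% confidence intervals are Wald intervals on the logit
#' scale (linear-combination variance from the coefficient variance
#' matrix) back-transformed, so they always lie inside [0, 1]. When the
#' fit did not converge (singular information), intervals are `NA`.
#'
#' @param object an `occu_fit`.
#' @param newdata data frame of covariate profiles; must contain every
#'   covariate the model uses.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return `newdata` augmented with `psi`, `psi_lower`, `psi_upper`,
#'   `p`, `p_lower`, `p_upper`.
#' @export
predict.occu_fit <- function(object, newdata, level = 0.95, ...) {
  needed <- unique(c(object$spec$psi_terms, object$spec$p_terms))
  missing_cov <- setdiff(needed, names(newdata))
  if (length(missing_cov) > 0) {
    stop("validation error: profile lacks covariate(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  newdata <- as.data.frame(newdata)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  k1 <- length(object$beta_psi)
  one_term <- function(x, beta, vblock) {
    eta <- drop(x %*% beta)
    se <- if (all(is.finite(vblock))) sqrt(rowSums((x %*% vblock) * x)) else NA_real_
    list(est = stats::plogis(eta),
         lower = stats::plogis(eta - zq * se),
         upper = stats::plogis(eta + zq * se))
  }
  xpsi <- design_matrix(newdata, object$spec$psi_terms)
  psi <- one_term(xpsi, object$beta_psi,
                  object$vcov[seq_len(k1), seq_len(k1), drop = FALSE])
  out <- cbind(newdata,
               psi = psi$est, psi_lower = psi$lower, psi_upper = psi$upper)
  if (is.null(object$p_fixed)) {
    xp <- design_matrix(newdata, object$spec$p_terms)
    p <- one_term(xp, object$beta_p,
                  object$vcov[-seq_len(k1), -seq_len(k1), drop = FALSE])
    out <- cbind(out, p = p$est, p_lower = p$lower, p_upper = p$upper)
  } else {
    out <- cbind(out, p = object$p_fixed, p_lower = object$p_fixed,
                 p_upper = object$p_fixed)
  }
  out
}
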
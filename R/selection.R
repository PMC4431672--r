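#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2l + 2K + 2K(K+1)/(n - K - 1)`, with `n` the number of
#' sites. With 130 host trees and five or six parameters the correction
#' term is about half a unit, enough to reorder closely ranked models.
#'
#' @param neg2_loglik `-2` times the maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n number of sites.
#' @return The AICc value.
#' @examples
#' aicc(307.35, K = 6, n = 130)  # 320.03
#' @export
aicc <- function(neg2_loglik, K, n) {
  if (any(n <= K + 1)) {
    stop("domain error: AICc requires n > K + 1", call. = FALSE)
  }
  neg2_loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_k exp(-delta_k / 2)` with
#' `delta_i = AICc_i - min(AICc)`. Weights are invariant to adding a
#' constant to every AICc value.
#'
#' @param aicc_values vector of AICc values.
#' @return Vector of weights summing to one.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0 || any(is.nan(aicc_values)) ||
      any(is.na(aicc_values))) {
    stop("domain error: AICc values must be non-empty and non-NaN", call. = FALSE)
  }
  w <- exp(-(aicc_values - min(aicc_values)) / 2)
  w / sum(w)
}

# All subsets of `covariates` containing no complete excluded pair,
# ordered by subset size then by position of members in `covariates`.
allowed_subsets <- function(covariates, exclusion) {
  subsets <- list(character())
  for (k in seq_along(covariates)) {
    idx <- utils::combn(seq_along(covariates), k, simplify = FALSE)
    subsets <- c(subsets, lapply(idx, function(i) covariates[i]))
  }
  keep <- vapply(subsets, function(s) {
    !any(vapply(exclusion, function(pair) all(pair %in% s), logical(1)))
  }, logical(1))
  subsets[keep]
}

#' Enumerate a candidate model set
#'
#' Builds the Cartesian product of allowed covariate subsets for the
#' occupancy and detectability terms. A subset is allowed if it contains
#' no excluded covariate pair; by default `size` and `infection` may not
#' share a term. With the three survey covariates and that exclusion
#' each term has 6 allowed subsets, giving the 36-model candidate set;
#' with no exclusion, 64 models.
#'
#' @param covariates covariate names (default the three site covariates).
#' @param exclusion list of character pairs that may not co-occur in one
#'   term; `list()` disables exclusions.
#' @return List of [occu_spec()] objects in deterministic canonical
#'   order (occupancy term varying slowest).
#' @examples
#' length(enumerate_models())                    # 36
#' length(enumerate_models(exclusion = list()))  # 64
#' @export
enumerate_models <- function(covariates = c("size", "neighbor", "infection"),
                             exclusion = list(c("size", "infection"))) {
  if (anyDuplicated(covariates)) {
    stop("validation error: covariate names must be unique", call. = FALSE)
  }
  for (pair in exclusion) {
    if (!all(pair %in% covariates)) {
      stop("validation error: exclusion references unknown covariate: ",
           paste(setdiff(pair, covariates), collapse = ", "), call. = FALSE)
    }
  }
  subsets <- allowed_subsets(covariates, exclusion)
  out <- vector("list", length(subsets)^2)
  i <- 0
  for (psi in subsets) {
    for (p in subsets) {
      i <- i + 1
      out[[i]] <- occu_spec(psi, p, allow_collinear = TRUE)
    }
  }
  out
}

#' Fit and rank a candidate model set
#'
#' Fits every model with [fit_occu()], ranks by AICc and computes Akaike
#' weights over the converged fits (a fit that failed to converge is
#' reported with `NA` weight and excluded from the weight
#' normalization). Ties in AICc are broken by smaller `K`, then by the
#' candidate list's canonical order.
#'
#' @param data a [survey_dataset()].
#' @param models list of [occu_spec()]; default [enumerate_models()].
#' @param ... passed to [fit_occu()].
#' @return An object of class `occu_selection`: a data frame `table`
#'   with columns `model`, `aicc`, `delta_aicc`, `weight`,
#'   `neg2_loglik`, `K`, `converged`, plus the list of fits in table
#'   order.
#' @export
run_selection <- function(data, models = enumerate_models(), ...) {
  if (length(models) == 0) stop("validation error: empty model list", call. = FALSE)
  fits <- vector("list", length(models))
  for (i in seq_along(models)) {
    fits[[i]] <- tryCatch(fit_occu(data, models[[i]], ...),
                          error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("selection error: every model fit failed", call. = FALSE)
  fits <- fits[ok]
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), character(1)),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    neg2_loglik = vapply(fits, `[[`, numeric(1), "neg2_loglik"),
    K = vapply(fits, `[[`, integer(1), "K"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aicc, tab$K, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- NA_real_
  if (any(tab$converged)) {
    tab$weight[tab$converged] <- akaike_weights(tab$aicc[tab$converged])
  }
  rownames(tab) <- NULL
  tab <- tab[, c("model", "aicc", "delta_aicc", "weight",
                 "neg2_loglik", "K", "converged")]
  structure(list(table = tab, fits = fits, n_sites = data$n_sites),
            class = "occu_selection")
}

#' @export
print.occu_selection <- function(x, digits = 2, ...) {
  tab <- x$table
  tab$aicc <- round(tab$aicc, digits)
  tab$delta_aicc <- round(tab$delta_aicc, digits)
  tab$weight <- round(tab$weight, 3)
  tab$neg2_loglik <- round(tab$neg2_loglik, digits)
  cat(sprintf("Model selection over %d candidates, n = %d sites\n",
              nrow(tab), x$n_sites))
  print(utils::head(tab, 10))
  if (nrow(tab) > 10) cat("... (", nrow(tab) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Best-supported model of a selection
#'
#' @param selection an `occu_selection`.
#' @param converged_only restrict to converged fits (default `TRUE`).
#' @return The top-ranked `occu_fit`.
#' @export
best_model <- function(selection, converged_only = TRUE) {
  stopifnot(inherits(selection, "occu_selection"))
  idx <- if (converged_only && any(selection$table$converged)) {
    which(selection$table$converged)[1]
  } else 1L
  selection$fits[[idx]]
}

#' Model-averaged occupancy and detectability predictions
#'
#' Averages real-scale predictions across models with their Akaike
#' weights. The averaging set is either all converged models or the
#' `delta AICc <= 2` confidence set, with weights renormalized over the
#' chosen set.
#'
#' @param selection an `occu_selection`.
#' @param profiles data frame of covariate profiles.
#' @param avg_set `"all"` or `"delta2"`.
#' @return `profiles` augmented with weight-averaged `psi` and `p`.
#' @export
model_average_predictions <- function(selection, profiles,
                                      avg_set = c("all", "delta2")) {
  stopifnot(inherits(selection, "occu_selection"))
  avg_set <- match.arg(avg_set)
  tab <- selection$table
  use <- tab$converged
  if (avg_set == "delta2") use <- use & tab$delta_aicc <= 2
  if (!any(use)) stop("selection error: empty averaging set", call. = FALSE)
  w <- akaike_weights(tab$aicc[use])
  idx <- which(use)
  psi <- p <- 0
  for (k in seq_along(idx)) {
    pred <- predict(selection$fits[[idx[k]]], profiles)
    psi <- psi + w[k] * pred$psi
    p <- p + w[k] * pred$p
  }
  cbind(as.data.frame(profiles), psi = psi, p = p)
}
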
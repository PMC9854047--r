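#' Summarize band selection from posterior draws
#'
#' Posterior inclusion probabilities `pip_j = mean(gamma_j)` over the kept
#' draws, the threshold-selected band set, and the most probable submodel
#' (`avgmod`): the gamma configuration with the highest exact-match
#' frequency among the draws.  Frequency ties are broken in favour of the
#' smaller model (fewer included bands), then lexicographically.
#'
#' @param samples a `posterior_samples` object (or any list with a `gamma`
#'   draws-by-bands matrix).
#' @param threshold PIP threshold for selection (default 0.6).
#' @return A `selection_summary`: list with `pip`, `selected_threshold`
#'   (band indices with `pip >= threshold`), `avgmod` (0/1 vector),
#'   `avgmod_frequency`, and `threshold`.
#' @export
selection_summary <- function(samples, threshold = 0.6) {
  G <- samples$gamma
  stopifnot(is.matrix(G), nrow(G) >= 1)
  pip <- colMeans(G)
  keys <- apply(G, 1, paste, collapse = "")
  tab <- table(keys)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1) {
    sizes <- vapply(best, function(k)
      sum(as.integer(strsplit(k, "")[[1]])), integer(1))
    best <- best[sizes == min(sizes)]
    best <- sort(best)[1]
  }
  avgmod <- as.integer(strsplit(best, "")[[1]])
  names(pip) <- colnames(G)
  structure(list(pip = pip,
                 selected_threshold = which(pip >= threshold),
                 avgmod = avgmod,
                 avgmod_frequency = max(tab) / nrow(G),
                 threshold = threshold),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("selection_summary:", length(x$selected_threshold), "of", length(x$pip),
      "bands with PIP >=", x$threshold, "; avgmod has", sum(x$avgmod),
      "bands (posterior frequency", round(x$avgmod_frequency, 3), ")\n")
  invisible(x)
}

#' Deviance information criterion
#'
#' `DIC = Dbar + p_D` with `Dbar` the posterior mean deviance and
#' `p_D = Dbar - D(theta_bar)` the effective number of parameters,
#' equivalently `DIC = 2 Dbar - D(theta_bar)`.  Lower is better.
#'
#' @param deviance_draws per-draw deviance values (>= 2 draws).
#' @param deviance_at_posterior_mean deviance evaluated at the posterior
#'   means of the parameters.
#' @param point_estimates optional list of posterior means to carry along.
#' @return A `fit_summary`: list with `dic`, `dbar`, `p_d`,
#'   `point_estimates`.
#' @export
compute_dic <- function(deviance_draws, deviance_at_posterior_mean,
                        point_estimates = NULL) {
  if (length(deviance_draws) < 2) stop("need at least 2 deviance draws")
  if (!all(is.finite(deviance_draws)) ||
      !is.finite(deviance_at_posterior_mean))
    stop("non-finite deviance")
  dbar <- mean(deviance_draws)
  p_d <- dbar - deviance_at_posterior_mean
  structure(list(dic = dbar + p_d, dbar = dbar, p_d = p_d,
                 point_estimates = point_estimates),
            class = "fit_summary")
}

#' DIC summary of a fitted model
#'
#' Convenience wrapper applying [compute_dic()] to the stored per-draw
#' deviances and the plug-in deviance of a [fit_model()] result.
#'
#' @param samples a `posterior_samples` object.
#' @return A `fit_summary`.
#' @export
fit_summary <- function(samples) {
  compute_dic(samples$deviance, samples$deviance_at_mean,
              point_estimates = samples$post_mean)
}

#' @export
print.fit_summary <- function(x, ...) {
  cat("DIC =", round(x$dic, 2), "( Dbar =", round(x$dbar, 2),
      ", p_D =", round(x$p_d, 2), ")\n")
  invisible(x)
}
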
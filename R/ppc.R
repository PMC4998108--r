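#' Sum-of-squares discrepancy between choices and predicted probabilities
#'
#' \eqn{T(D; \theta, M) = \sum_i (d_i - p_i)^2}. Chosen over the Pearson
#' chi-square discrepancy because predicted probabilities are routinely
#' within machine precision of 0 or 1.
#'
#' @param choices Binary vector.
#' @param probabilities Predicted probabilities, aligned with
#'   \code{choices}.
#' @return Nonnegative discrepancy.
#' @export
discrepancy <- function(choices, probabilities) {
  if (length(choices) != length(probabilities))
    stopf("choices not aligned with probabilities")
  sum((choices - probabilities)^2)
}

#' Posterior-predictive Bayesian p-value
#'
#' The probability that data replicated from the model are more discrepant
#' than the observed data, \eqn{p\{T(D^{rep}) > T(D) \mid D, M\}},
#' approximated over the same prior-draw stream used for the marginal
#' likelihood: for each prior draw one replicate dataset is simulated from
#' the (unclamped) predicted probabilities, and draws with
#' \eqn{T(D^{rep}) > T(D)} contribute their importance weight
#' \eqn{p(D\mid\theta,M) / p(D \mid M)} (self-normalized). The random
#' baseline without dominance detection has
#' \eqn{T(D) = T(D^{rep}) = m/4} always, hence a p-value of exactly zero.
#'
#' @inheritParams marginal_likelihood
#' @return List with \code{p} (the Bayesian p-value), \code{log_ml},
#'   \code{n_draws}, \code{seed}.
#' @export
bayesian_p_value <- function(family, pairs, choices, n_draws = 1e4,
                             seed = NULL, fixed = list(), adjust = TRUE) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  if (length(pairs) != length(choices))
    stopf("choices not aligned with pairs")
  m <- length(choices)
  draws <- sample_prior(family, n_draws, seed, fixed, adjust)
  tab <- .family_table(pairs, family, adjust)
  P <- .prob_matrix(tab, draws, adjust)
  ll <- drop(.loglik_matrix(P, as.numeric(choices)))
  lse <- logsumexp(ll)
  if (!is.finite(lse)) stopf("zero marginal likelihood; cannot weight replicates")
  x <- as.numeric(choices)
  T_obs <- rowSums(sweep(P, 2, x, "-")^2)
  # replicate uniforms are attached to pairs in canonical id order, so the
  # p-value is exactly invariant to permuting the choice-pair order
  ids <- vapply(pairs, function(p) p$id, "")
  U <- matrix(stats::runif(n_draws * m), n_draws, m)[, rank(ids,
        ties.method = "first"), drop = FALSE]
  rep_mat <- (U < P) * 1
  T_rep <- rowSums((rep_mat - P)^2)
  w <- exp(ll - lse)
  list(p = sum(w[T_rep > T_obs]),
       log_ml = lse - log(n_draws),
       n_draws = as.integer(n_draws), seed = seed, family = family)
}

#' Posterior-predictive check across a cohort
#'
#' Computes a Bayesian p-value for each participant under each requested
#' candidate, and summarizes the fraction of p-values below 0.05 per
#' candidate.
#'
#' @param choices Participant-by-pair binary matrix.
#' @param pairs List of \code{\link{choice_pair}}s (or \code{seq_fixture}).
#' @param candidates Data frame with columns \code{model} and
#'   \code{adjust}; defaults to the parallel-contest candidate set.
#' @param n_draws,seed As in \code{\link{bayesian_p_value}}.
#' @return Data frame \code{participant_id}, \code{model}, \code{variant},
#'   \code{bayesian_p}; the per-candidate misfit summary is attached as
#'   attribute \code{"misfit"}.
#' @export
ppc_cohort <- function(choices, pairs, candidates = NULL, n_draws = 1e4,
                       seed = NULL) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  X <- .align_choices(choices, pairs)
  if (is.null(candidates)) candidates <- .contest_candidates("parallel")
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    fam <- candidates$model[i]; adj <- candidates$adjust[i]
    lab <- paste0(fam, if (adj) "+dom" else "")
    for (j in seq_len(nrow(X))) {
      sd_ij <- if (is.null(seed)) NULL else
        substream_seed(seed, paste0(lab, "#", j))
      r <- bayesian_p_value(fam, pairs, X[j, ], n_draws, sd_ij, adjust = adj)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[j],
        model = fam,
        variant = if (adj) "dominance_adjusted" else "plain",
        bayesian_p = r$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  mis <- stats::aggregate(bayesian_p ~ model + variant, out,
                          function(p) mean(p < 0.05))
  names(mis)[3] <- "fraction_p_below_05"
  attr(out, "misfit") <- mis
  out
}
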
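#' Wald 95\% confidence interval for a proportion, on the percentage scale
#'
#' \eqn{\hat p \pm 1.96 \sqrt{\hat p (1-\hat p)/n}}, reported in percent.
#'
#' @param k Number of successes (0..n).
#' @param n Sample size (>= 1).
#' @return List with \code{estimate}, \code{lower}, \code{upper} (percent)
#'   and \code{n}.
#' @examples
#' proportion_ci(154, 356)  # about (38.11, 48.40) around 43.26
#' @export
proportion_ci <- function(k, n) {
  if (n < 1) stopf("n must be at least 1")
  if (k < 0 || k > n) stopf("k must lie in 0..n")
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  structure(list(estimate = 100 * p, lower = 100 * (p - half),
                 upper = 100 * (p + half), n = as.integer(n)),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.2f%% [%.2f, %.2f] (n = %d)\n",
              x$estimate, x$lower, x$upper, x$n))
  invisible(x)
}

# Wald CI on a difference of two independent group means.
.diff_ci <- function(a, b) {
  d <- mean(a) - mean(b)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  c(diff = d, lower = d - 1.96 * se, upper = d + 1.96 * se)
}

#' Asymmetry of the hidden-zero effect
#'
#' Compares average patience (proportion of larger-later choices) across
#' the three between-participant framing conditions. Reports the contrasts
#' \eqn{p_L - p_N}, \eqn{p_S - p_N} and \eqn{p_L - p_S} with unpooled Wald
#' 95\% confidence intervals, and a strict-asymmetry verdict: the
#' later-zero contrast excludes zero from above while the sooner-zero
#' contrast covers zero.
#'
#' @param patience Data frame with columns \code{condition} (one of
#'   \code{"none"}, \code{"sooner_zero"}, \code{"later_zero"}) and
#'   \code{patience} (per-participant proportion), e.g. from
#'   \code{\link{simulate_hidden_zero_cohort}}.
#' @return List with the per-condition means, the contrast table, and
#'   \code{strict_asymmetry}.
#' @export
hidden_zero_asymmetry <- function(patience) {
  need <- c("none", "sooner_zero", "later_zero")
  split_ <- lapply(need, function(cn) patience$patience[patience$condition == cn])
  names(split_) <- need
  sizes <- vapply(split_, length, 0L)
  if (any(sizes < 2))
    stopf("each condition needs at least 2 participants (got %s)",
          paste(need[sizes < 2], collapse = ", "))
  contrasts <- rbind(
    later_vs_none = .diff_ci(split_$later_zero, split_$none),
    sooner_vs_none = .diff_ci(split_$sooner_zero, split_$none),
    later_vs_sooner = .diff_ci(split_$later_zero, split_$sooner_zero))
  contrasts <- as.data.frame(contrasts)
  strict <- contrasts["later_vs_none", "lower"] > 0 &&
    contrasts["sooner_vs_none", "lower"] <= 0 &&
    contrasts["sooner_vs_none", "upper"] >= 0
  list(means = vapply(split_, mean, 0), n = sizes, contrasts = contrasts,
       strict_asymmetry = strict)
}

#' Observed versus model-predicted high-NPV choice proportions
#'
#' For each candidate model's supporters (contest winners with at least
#' anecdotal support), tabulates the observed proportion choosing the
#' high-NPV option per pair against the model's average predicted
#' probability. Predictions are likelihood-weighted averages of the choice
#' probability over prior draws (the posterior-mean prediction for each
#' participant), then averaged over supporters; individual point estimates
#' are avoided because individual posteriors are broad.
#'
#' @param choices Participant-by-pair binary matrix.
#' @param pairs List of \code{\link{choice_pair}}s (or \code{seq_fixture}).
#' @param contest A \code{"seq_contest"} fitted on the same data.
#' @param n_draws Prior draws per participant-model prediction.
#' @param seed Integer seed.
#' @return Data frame with one row per (model, pair): \code{model},
#'   \code{pair_id}, \code{dominance}, \code{n_supporters},
#'   \code{observed}, \code{predicted}. Models with no supporters are
#'   omitted.
#' @export
observed_vs_predicted <- function(choices, pairs, contest, n_draws = 1e4,
                                  seed = NULL) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  X <- .align_choices(choices, pairs)
  ids <- vapply(pairs, function(p) p$id, "")
  dom <- vapply(pairs, function(p) p$dominance, TRUE)
  out <- list()
  for (i in seq_len(nrow(contest$candidates))) {
    lab <- contest$candidates$label[i]
    fam <- contest$candidates$model[i]
    adj <- contest$candidates$adjust[i]
    sup <- which(contest$winner == lab & contest$tier != "none")
    if (!length(sup)) next
    sd_i <- if (is.null(seed)) NULL else substream_seed(seed, paste0("ovp_", lab))
    nd <- if (fam == "RM" && !adj) 1L else n_draws
    draws <- sample_prior(fam, nd, sd_i, adjust = adj)
    tab <- .family_table(pairs, fam, adj)
    P <- .prob_matrix(tab, draws, adj)
    ll <- .loglik_matrix(P, t(X[sup, , drop = FALSE]))
    pred <- sapply(seq_along(sup), function(j) {
      w <- exp(ll[, j] - logsumexp(ll[, j]))
      colSums(P * w)
    })
    out[[lab]] <- data.frame(
      model = lab, pair_id = ids, dominance = dom,
      n_supporters = length(sup),
      observed = colMeans(X[sup, , drop = FALSE]),
      predicted = rowMeans(as.matrix(pred)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write contest results to CSV
#'
#' One row per participant-candidate (see
#' \code{\link{as.data.frame.seq_contest}}), with run metadata (seed and
#' draw count) recorded in a comment-style header line alongside.
#'
#' @param contest A \code{"seq_contest"}.
#' @param path Output CSV path.
#' @export
write_contest <- function(contest, path) {
  utils::write.csv(as.data.frame(contest), path, row.names = FALSE)
  meta <- sprintf("contest=%s n_draws=%g seed=%s candidates=%s",
                  contest$contest, contest$n_draws,
                  contest$seed %||% "NULL",
                  paste(contest$candidates$label, collapse = "|"))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
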
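#' Uniform prior bounds for a model family
#'
#' Every parameter carries an independent uniform prior over its entire
#' range: curvature \eqn{\gamma \in [0, 5]}; discount factor \eqn{\delta}
#' and dominance detection \eqn{\vartheta} in \eqn{[0, 1]}; sensitivity
#' \eqn{\epsilon} and impatience \eqn{\kappa} in \eqn{[0, 100]};
#' improvement \eqn{\beta} and spreading \eqn{\sigma} in \eqn{[-100, 100]}.
#'
#' @param family One of the \code{\link{model_families}}.
#' @param adjust Include the dominance-detection parameter \eqn{\vartheta}.
#' @return Data frame with columns \code{parameter}, \code{lower},
#'   \code{upper}.
#' @export
prior_spec <- function(family, adjust = TRUE) {
  bounds <- list(gamma = c(0, 5), kappa = c(0, 100), delta = c(0, 1),
                 beta = c(-100, 100), sigma = c(-100, 100),
                 epsilon = c(0, 100), theta = c(0, 1))
  pars <- family_parameters(family, adjust)
  data.frame(parameter = pars,
             lower = vapply(pars, function(p) bounds[[p]][1], 0),
             upper = vapply(pars, function(p) bounds[[p]][2], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Draw parameter sets from a family's prior
#'
#' Independent uniform draws within the bounds of \code{\link{prior_spec}}.
#' Individual parameters can be pinned to fixed values (reduced models),
#' in which case they are returned as constant columns and not drawn.
#'
#' @inheritParams prior_spec
#' @param n_draws Number of parameter sets.
#' @param seed Optional integer seed; same seed, same draw stream.
#' @param fixed Named list of parameters to hold fixed.
#' @return A named list of numeric vectors of length \code{n_draws}
#'   (class \code{"param_draws"}).
#' @export
sample_prior <- function(family, n_draws, seed = NULL, fixed = list(),
                         adjust = TRUE) {
  if (n_draws < 1) stopf("n_draws must be at least 1")
  spec <- prior_spec(family, adjust)
  if (!is.null(seed)) set.seed(seed)
  draws <- list()
  for (i in seq_len(nrow(spec))) {
    p <- spec$parameter[i]
    draws[[p]] <- if (p %in% names(fixed)) rep(fixed[[p]], n_draws)
                  else stats::runif(n_draws, spec$lower[i], spec$upper[i])
  }
  structure(draws, n_draws = as.integer(n_draws), class = "param_draws")
}

#' Monte-Carlo marginal likelihood of a participant's choices
#'
#' Approximates \eqn{p(D \mid M) = \int p(D \mid M, \theta)
#' p(\theta \mid M) d\theta} by the prior-sample average
#' \eqn{(1/n) \sum_j p(D \mid M, \theta_j)}, computed through log-sum-exp.
#' The random baseline without dominance detection has constant likelihood
#' and returns exactly \eqn{0.5^m} for \eqn{m} choices.
#'
#' @inheritParams sample_prior
#' @param pairs List of \code{\link{choice_pair}}s.
#' @param choices Binary vector (1 = high-NPV option chosen).
#' @return Object of class \code{"seq_ml"}: list with \code{ml},
#'   \code{log_ml}, Monte-Carlo standard error \code{se}, \code{n_draws},
#'   and the per-draw log-likelihood stream (for reuse by the
#'   posterior-predictive check).
#' @export
marginal_likelihood <- function(family, pairs, choices, n_draws = 1e5,
                                seed = NULL, fixed = list(), adjust = TRUE) {
  if (length(pairs) != length(choices))
    stopf("choices not aligned with pairs")
  if (family == "RM" && (!adjust || identical(fixed$theta, 0))) {
    # constant likelihood: the Monte-Carlo mean is exact
    m <- length(choices)
    return(structure(list(ml = 0.5^m, log_ml = m * log(0.5), se = 0,
                          n_draws = as.integer(n_draws), family = family,
                          draws = NULL, ll = rep(m * log(0.5), n_draws)),
                     class = "seq_ml"))
  }
  draws <- sample_prior(family, n_draws, seed, fixed, adjust)
  tab <- .family_table(pairs, family, adjust)
  P <- .prob_matrix(tab, draws, adjust)
  ll <- drop(.loglik_matrix(P, as.numeric(choices)))
  log_ml <- logsumexp(ll) - log(length(ll))
  rel <- exp(ll - log_ml)
  se <- exp(log_ml) * stats::sd(rel) / sqrt(length(ll))
  structure(list(ml = exp(log_ml), log_ml = log_ml, se = se,
                 n_draws = as.integer(n_draws), family = family,
                 draws = draws, ll = ll),
            class = "seq_ml")
}

#' @export
print.seq_ml <- function(x, ...) {
  cat(sprintf("<seq_ml %s> marginal likelihood %.4g (log %.3f, MC se %.2g, %d draws)\n",
              x$family, x$ml, x$log_ml, x$se, x$n_draws))
  invisible(x)
}

.as_ml <- function(x) if (inherits(x, "seq_ml")) x$ml else as.numeric(x)

#' Bayes factor between two marginal likelihoods
#'
#' @param ml1,ml2 Marginal likelihoods (numbers or \code{"seq_ml"} objects).
#' @return The ratio \eqn{p(D|M_1) / p(D|M_2)}.
#' @export
bayes_factor <- function(ml1, ml2) {
  a <- .as_ml(ml1); b <- .as_ml(ml2)
  if (b <= 0) stopf("zero denominator marginal likelihood")
  a / b
}

#' Posterior model probabilities under equal model priors
#'
#' Normalizes marginal likelihoods to a probability simplex; invariant to
#' common scaling.
#'
#' @param mls Named collection of marginal likelihoods (numbers or
#'   \code{"seq_ml"} objects).
#' @return Named numeric vector summing to 1.
#' @export
posterior_model_probabilities <- function(mls) {
  if (!length(mls)) stopf("no marginal likelihoods supplied")
  lg <- vapply(mls, function(x)
    if (inherits(x, "seq_ml")) x$log_ml else log(as.numeric(x)), 0)
  p <- exp(lg - logsumexp(lg))
  p / sum(p)
}

SUPPORT_TIERS <- c("none", "anecdotal", "substantial", "strong",
                   "very_strong", "decisive")
.TIER_THRESHOLDS <- c(anecdotal = 1, substantial = 3, strong = 10,
                      very_strong = 30, decisive = 100)

#' Support tier from Bayes factors against all competitors
#'
#' A participant lends a model anecdotal / substantial / strong /
#' very strong / decisive support when all pairwise Bayes factors against
#' every other candidate exceed 1 / 3 / 10 / 30 / 100.
#'
#' @param bfs Bayes factors of the focal model against each competitor.
#' @return One of \code{"none"}, \code{"anecdotal"}, \code{"substantial"},
#'   \code{"strong"}, \code{"very_strong"}, \code{"decisive"}.
#' @export
support_tier <- function(bfs) {
  if (!length(bfs)) stopf("no Bayes factors supplied")
  tier <- "none"
  for (nm in names(.TIER_THRESHOLDS))
    if (all(bfs > .TIER_THRESHOLDS[[nm]])) tier <- nm
  tier
}

.contest_candidates <- function(contest) {
  if (contest == "main") {
    data.frame(model = c("TM", "DIUM", "SMNZ", "SMZ"),
               adjust = TRUE,
               label = c("TM", "DIUM", "SMNZ", "SMZ"),
               stringsAsFactors = FALSE)
  } else {
    fam <- rep(MODEL_FAMILIES, each = 2)
    adj <- rep(c(TRUE, FALSE), times = length(MODEL_FAMILIES))
    data.frame(model = fam, adjust = adj,
               label = paste0(fam, ifelse(adj, "+dom", "")),
               stringsAsFactors = FALSE)
  }
}

# Coerce a choices input (matrix with pair-id columns, or long data frame
# participant_id/pair_id/choice_high) into an N x npairs matrix aligned
# with `pairs`; pairs absent from the fixture (e.g. hidden-zero tasks) are
# excluded with a notice.
.align_choices <- function(choices, pairs) {
  ids <- vapply(pairs, function(p) p$id, "")
  if (is.data.frame(choices) && all(c("participant_id", "pair_id") %in%
                                    names(choices))) {
    ppl <- unique(choices$participant_id)
    X <- matrix(NA_real_, length(ppl), length(ids),
                dimnames = list(ppl, ids))
    keep <- choices$pair_id %in% ids
    if (any(!keep))
      message(sprintf("excluding %d choices on %d tasks outside the fixture (e.g. hidden-zero tasks)",
                      sum(!keep), length(unique(choices$pair_id[!keep]))))
    ch <- choices[keep, ]
    X[cbind(match(ch$participant_id, ppl), match(ch$pair_id, ids))] <-
      ch$choice_high
    if (anyNA(X)) stopf("incomplete choice data: every participant needs all %d fixture pairs", length(ids))
    return(X)
  }
  X <- as.matrix(choices)
  if (!is.null(colnames(X))) {
    extra <- setdiff(colnames(X), ids)
    if (length(extra)) {
      message(sprintf("excluding %d tasks outside the fixture: %s",
                      length(extra), paste(utils::head(extra, 4), collapse = ", ")))
      X <- X[, intersect(colnames(X), ids), drop = FALSE]
    }
    X <- X[, ids, drop = FALSE]
  }
  if (ncol(X) != length(ids)) stopf("choice matrix has %d columns; fixture has %d pairs", ncol(X), length(ids))
  X
}

#' Run an individual-level Bayesian model contest
#'
#' Scores every candidate model for every participant by Monte-Carlo
#' marginal likelihood, converts to posterior model probabilities under
#' equal model priors, and labels each participant's winning model and
#' support tier (all pairwise Bayes factors against the thresholds 1 / 3 /
#' 10 / 30 / 100). The \emph{main} contest pits the four substantive models
#' with dominance detection (TM, DIUM, SMNZ, SMZ); the \emph{parallel}
#' contest adds the random baseline and the no-dominance-detection variant
#' of every model (sensitivity-zero reductions coincide with the random
#' baseline and are not duplicated). For the parallel contest the result
#' also cross-tabulates main-contest winners (derived from the four
#' adjusted substantive candidates) against parallel-contest winners.
#'
#' One prior-draw stream per candidate is shared across participants, which
#' makes whole-cohort scoring a single vectorized pass; independent seeds
#' give independent streams for stability checks.
#'
#' @param choices Participant-by-pair binary matrix (columns named by pair
#'   id) or long data frame with \code{participant_id}, \code{pair_id},
#'   \code{choice_high}. Tasks not in \code{pairs} (hidden-zero tasks) are
#'   excluded with a notice.
#' @param pairs A \code{seq_fixture} or list of \code{\link{choice_pair}}s.
#' @param contest \code{"main"} or \code{"parallel"}.
#' @param n_draws Prior draws per candidate model.
#' @param seed Integer seed governing all draw streams.
#' @return Object of class \code{"seq_contest"}.
#' @export
run_contest <- function(choices, pairs, contest = c("main", "parallel"),
                        n_draws = 1e5, seed = NULL) {
  contest <- match.arg(contest)
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  X <- .align_choices(choices, pairs)
  cand <- .contest_candidates(contest)
  N <- nrow(X)
  log_ml <- matrix(NA_real_, N, nrow(cand),
                   dimnames = list(rownames(X), cand$label))
  for (i in seq_len(nrow(cand))) {
    fam <- cand$model[i]; adj <- cand$adjust[i]
    sd_i <- if (is.null(seed)) NULL else substream_seed(seed, cand$label[i])
    nd <- if (fam == "RM" && !adj) 1L else n_draws
    draws <- sample_prior(fam, nd, sd_i, adjust = adj)
    tab <- .family_table(pairs, fam, adj)
    P <- .prob_matrix(tab, draws, adj)
    ll <- .loglik_matrix(P, t(X))
    log_ml[, i] <- .col_logsumexp(ll) - log(nd)
  }
  post <- exp(log_ml - apply(log_ml, 1, logsumexp))
  win_idx <- max.col(log_ml, ties.method = "first")
  winner <- cand$label[win_idx]
  tier <- vapply(seq_len(N), function(j) {
    bf <- exp(log_ml[j, win_idx[j]] - log_ml[j, -win_idx[j]])
    support_tier(bf)
  }, "")
  res <- list(contest = contest, candidates = cand, log_ml = log_ml,
              posterior = post, winner = winner, tier = tier,
              cohort_posterior = colMeans(post),
              n_draws = n_draws, seed = seed, n_participants = N)
  if (contest == "parallel") {
    main_lab <- c("TM+dom", "DIUM+dom", "SMNZ+dom", "SMZ+dom")
    sub <- log_ml[, main_lab, drop = FALSE]
    mw <- c("TM", "DIUM", "SMNZ", "SMZ")[max.col(sub, ties.method = "first")]
    res$main_winner <- mw
    res$crosstab <- table(main = mw, parallel = winner)
  }
  structure(res, class = "seq_contest")
}

#' @export
print.seq_contest <- function(x, ...) {
  cat(sprintf("<seq_contest %s> %d participants, %d candidates, %g draws/model\n",
              x$contest, x$n_participants, nrow(x$candidates), x$n_draws))
  cat("cohort-average posterior model probabilities:\n")
  print(round(x$cohort_posterior, 3))
  invisible(x)
}

#' @export
summary.seq_contest <- function(object, ...) {
  wt <- table(factor(object$winner, levels = object$candidates$label))
  out <- list(contest = object$contest,
              cohort_posterior = object$cohort_posterior,
              winners = wt,
              tiers = table(factor(object$tier, levels = SUPPORT_TIERS)),
              crosstab = object$crosstab)
  class(out) <- "summary.seq_contest"
  out
}

#' @export
print.summary.seq_contest <- function(x, ...) {
  cat(sprintf("Bayesian model contest (%s)\n", x$contest))
  cat("\nCohort-average posterior probabilities:\n")
  print(round(x$cohort_posterior, 3))
  cat("\nWinning-model counts:\n"); print(x$winners)
  cat("\nSupport tiers of winners:\n"); print(x$tiers)
  if (!is.null(x$crosstab)) {
    cat("\nMain-contest vs parallel-contest winners:\n"); print(x$crosstab)
  }
  invisible(x)
}

#' Per-participant contest results as a data frame
#'
#' One row per participant-candidate with the marginal log-likelihood,
#' posterior probability, winner flag and the winner's support tier;
#' suitable for CSV export.
#'
#' @param x A \code{"seq_contest"}.
#' @param ... Unused.
#' @export
as.data.frame.seq_contest <- function(x, ...) {
  N <- x$n_participants; K <- nrow(x$candidates)
  ids <- rownames(x$log_ml) %||% as.character(seq_len(N))
  data.frame(
    participant_id = rep(ids, each = K),
    model = rep(x$candidates$model, times = N),
    variant = rep(ifelse(x$candidates$adjust, "dominance_adjusted", "plain"),
                  times = N),
    marginal_log_likelihood = as.vector(t(x$log_ml)),
    posterior_probability = as.vector(t(x$posterior)),
    winner_flag = rep(x$candidates$label, times = N) ==
      rep(x$winner, each = K),
    support_tier = rep(x$tier, each = K),
    stringsAsFactors = FALSE)
}

#' Two-seed stability of the Monte-Carlo model contest
#'
#' Runs the same contest under two independent seeds and reports the
#' fraction of participants with the same winning model and the mean
#' absolute deviation in posterior model probability across participants
#' and models.
#'
#' @inheritParams run_contest
#' @param seed1,seed2 Two seeds (identical seeds reproduce exactly).
#' @return List with \code{agreement}, \code{mean_abs_deviation}, and the
#'   two contest objects.
#' @export
stability_check <- function(choices, pairs, contest = "main",
                            n_draws = 1e5, seed1 = 1L, seed2 = 2L) {
  c1 <- run_contest(choices, pairs, contest, n_draws, seed1)
  c2 <- run_contest(choices, pairs, contest, n_draws, seed2)
  list(agreement = mean(c1$winner == c2$winner),
       mean_abs_deviation = mean(abs(c1$posterior - c2$posterior)),
       run1 = c1, run2 = c2)
}
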
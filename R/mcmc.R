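#' Highest density interval of a sample
#'
#' The single shortest contiguous interval containing at least
#' \code{mass} of the sample: over the sorted values, the window of
#' \eqn{\lceil mass \cdot N \rceil} points with the smallest width.
#'
#' @param samples Numeric vector (at least 20 values).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stopf("mass must lie strictly in (0,1)")
  n <- length(samples)
  if (n < 20) stopf("need at least 20 samples for an HDI")
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]    # windows of exactly m points
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Group-level posterior sampling by adaptive Metropolis-Hastings
#'
#' Samples the posterior over a family's parameters given the pooled
#' choices of a supporter group (choices of all group members are treated
#' as independent draws from one group-level parameter set). The target is
#' the uniform prior times the pooled Bernoulli likelihood; proposals
#' outside prior support are rejected, preserving detailed balance for the
#' truncated target. During burn-in the Gaussian proposal covariance is
#' recalibrated every \code{adapt_every} states to \eqn{2.38^2/d} times the
#' sample covariance of the most recent \code{adapt_window} states, plus a
#' small additive diagonal (a fraction of the squared prior range) so the
#' covariance cannot collapse, and a global step-size multiplier is nudged
#' toward a 23\% acceptance rate; after burn-in the proposal is frozen, so
#' retained samples carry no adaptation bias.
#'
#' By default the start state is the best-scoring of a modest sample of
#' prior draws rather than a single prior draw: with pooled group data the
#' likelihood surface is extremely peaked, and a chain started in a flat
#' far-away region can spend a whole desk-scale budget crawling toward the
#' mode (million-state chains absorb this; 1e5-state chains may not). Set
#' \code{n_init = 1} for a plain prior-draw start.
#'
#' @param family One of the \code{\link{model_families}}.
#' @param pairs List of \code{\link{choice_pair}}s (or a
#'   \code{seq_fixture}).
#' @param choices Group choice data: participant-by-pair binary matrix, or
#'   a list with per-pair success counts \code{k} and group size \code{n}.
#' @param n_states Total chain length (default 1e5; the headline analyses
#'   use 1e6 with half discarded).
#' @param burn Fraction of initial states discarded (default 0.5);
#'   adaptation happens only inside this window.
#' @param seed Integer seed.
#' @param adjust Include the dominance-detection parameter.
#' @param adapt_every,adapt_window,jitter Adaptation schedule knobs. By
#'   default the proposal is recalibrated every
#'   \code{min(5000, n_burn/20)} states over a window of four such spans
#'   (i.e. 5000/20000 for million-state chains, proportionally tighter for
#'   short desk-scale chains, so the start-up transient washes out of the
#'   covariance estimate).
#' @param n_init Number of prior draws scored to pick the start state.
#' @param fixed Named list of parameters pinned to fixed values (reduced
#'   models); pinned parameters are not sampled.
#' @return Object of class \code{"seq_chain"}: retained states matrix plus
#'   metadata (acceptance rate, seed, schedule).
#' @export
mh_sample <- function(family, pairs, choices, n_states = 1e5, burn = 0.5,
                      seed = NULL, adjust = TRUE,
                      adapt_every = NULL, adapt_window = NULL,
                      jitter = 1e-6, n_init = 256, fixed = list()) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  if (is.list(choices) && !is.data.frame(choices) &&
      all(c("k", "n") %in% names(choices))) {
    k <- choices$k; Ng <- choices$n
  } else {
    X <- .align_choices(choices, pairs)
    if (nrow(X) == 0L) stopf("empty supporter group")
    k <- colSums(X); Ng <- nrow(X)
  }
  if (length(k) != length(pairs)) stopf("pooled counts not aligned with pairs")
  spec <- prior_spec(family, adjust)
  bad_fixed <- setdiff(names(fixed), spec$parameter)
  if (length(bad_fixed))
    stopf("fixed parameter(s) not in family %s: %s", family,
          paste(bad_fixed, collapse = ", "))
  free <- !(spec$parameter %in% names(fixed))
  d <- sum(free)
  if (d == 0L) stopf("family %s has no free parameters to sample", family)
  lo <- spec$lower[free]; hi <- spec$upper[free]; rng <- hi - lo
  free_names <- spec$parameter[free]
  fixed_vec <- unlist(fixed[spec$parameter[!free]])
  pf <- .make_prob_fun(pairs, family, adjust)
  loglik <- function(par_free) {
    names(par_free) <- free_names
    p <- clamp_p(pf(c(par_free, fixed_vec)))
    sum(k * log(p) + (Ng - k) * log1p(-p))
  }
  if (!is.null(seed)) set.seed(seed)
  n_init <- max(1L, as.integer(n_init))
  inits <- matrix(stats::runif(n_init * d, lo, hi), n_init, d, byrow = TRUE)
  init_ll <- apply(inits, 1, loglik)
  cur <- inits[which.max(init_ll), ]
  cur_ll <- max(init_ll)
  states <- matrix(NA_real_, n_states, d, dimnames = list(NULL, free_names))
  scale <- 2.38^2 / d
  lambda <- 1
  L <- diag(0.05 * rng, d)          # initial proposal chol (sd = 5% of range)
  n_burn <- floor(burn * n_states)
  if (is.null(adapt_every))
    adapt_every <- max(250L, min(5000L, floor(n_burn / 20)))
  if (is.null(adapt_window)) adapt_window <- 4L * adapt_every
  acc_post <- 0L
  acc_win <- 0L
  for (s in seq_len(n_states)) {
    prop <- cur + as.vector(L %*% stats::rnorm(d))
    if (all(prop >= lo & prop <= hi)) {
      prop_ll <- loglik(prop)
      if (log(stats::runif(1)) < prop_ll - cur_ll) {
        cur <- prop; cur_ll <- prop_ll
        acc_win <- acc_win + 1L
        if (s > n_burn) acc_post <- acc_post + 1L
      }
    }
    states[s, ] <- cur
    if (s <= n_burn && s %% adapt_every == 0L) {
      win <- states[max(1L, s - adapt_window + 1L):s, , drop = FALSE]
      lambda <- min(1e3, max(1e-3,
        lambda * exp(2 * (acc_win / adapt_every - 0.234))))
      S <- lambda * (scale * stats::cov(win) + diag(jitter * rng^2, d))
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(ch)) L <- t(ch)
      acc_win <- 0L
    }
  }
  retained <- states[(n_burn + 1L):n_states, , drop = FALSE]
  structure(list(states = retained, family = family,
                 parameters = free_names, fixed = fixed,
                 n_states = n_states, burn = burn,
                 acceptance = acc_post / (n_states - n_burn),
                 seed = seed, group_size = Ng,
                 adapt = list(every = adapt_every, window = adapt_window,
                              scale = scale, jitter = jitter,
                              lambda = lambda, n_init = n_init)),
            class = "seq_chain")
}

#' @export
print.seq_chain <- function(x, ...) {
  cat(sprintf("<seq_chain %s> %d retained states (%d total, %.0f%% burn-in), acceptance %.2f\n",
              x$family, nrow(x$states), x$n_states, 100 * x$burn,
              x$acceptance))
  print(summary(x))
  invisible(x)
}

#' @export
summary.seq_chain <- function(object, mass = 0.95, ...) {
  S <- object$states
  out <- data.frame(
    parameter = colnames(S),
    median = apply(S, 2, stats::median),
    hdi_low = apply(S, 2, function(v) hdi(v, mass)[1]),
    hdi_high = apply(S, 2, function(v) hdi(v, mass)[2]),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' @export
coef.seq_chain <- function(object, ...) {
  stats::setNames(apply(object$states, 2, stats::median),
                  colnames(object$states))
}

#' Group-level posterior summaries per winning model
#'
#' Splits participants by the model that won their individual contest,
#' pools each group's choices, and estimates that model's group-level
#' posterior by \code{\link{mh_sample}}, summarizing each parameter by its
#' median and 95\% highest density interval. Empty groups are omitted with
#' a notice.
#'
#' @param choices Participant-by-pair binary matrix.
#' @param pairs List of \code{\link{choice_pair}}s (or \code{seq_fixture}).
#' @param winners Character vector of winning families per participant
#'   (e.g. \code{run_contest(...)$winner}); labels may carry a
#'   \code{"+dom"} suffix, which is stripped.
#' @param n_states,seed,adjust,... Passed to \code{\link{mh_sample}}.
#' @return Data frame with columns \code{model}, \code{parameter},
#'   \code{median}, \code{hdi_low}, \code{hdi_high}; the fitted chains are
#'   attached as attribute \code{"chains"}.
#' @export
summarize_group_posteriors <- function(choices, pairs, winners,
                                       n_states = 1e5, seed = NULL,
                                       adjust = TRUE, ...) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  X <- .align_choices(choices, pairs)
  fam <- sub("\\+dom$", "", winners)
  out <- list(); chains <- list()
  for (f in intersect(MODEL_FAMILIES, unique(fam))) {
    idx <- which(fam == f)
    if (!length(idx)) next
    if (f == "RM" && !adjust) { message("skipping RM group: no free parameters"); next }
    sd_f <- if (is.null(seed)) NULL else substream_seed(seed, f)
    ch <- mh_sample(f, pairs, X[idx, , drop = FALSE], n_states = n_states,
                    seed = sd_f, adjust = adjust, ...)
    sm <- summary(ch)
    sm$model <- f
    out[[f]] <- sm[, c("model", "parameter", "median", "hdi_low", "hdi_high")]
    chains[[f]] <- ch
  }
  missing <- setdiff(c("TM", "DIUM", "SMNZ", "SMZ"), unique(fam))
  if (length(missing))
    message("no supporters for: ", paste(missing, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "chains") <- chains
  res
}
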
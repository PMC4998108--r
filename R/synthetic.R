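# Synthetic participants and cohorts. The data-generating assumption
# mirrors the analysis model: each participant's choices are independent
# Bernoulli draws with probabilities given by one candidate model at
# parameters drawn from (or fixed within) the uniform priors.

#' Simulate one participant's choices
#'
#' Independent Bernoulli draws with \code{\link{choice_probability}} per
#' pair (unclamped probabilities).
#'
#' @param family Generating model family.
#' @param params Named list of generating parameters.
#' @param pairs List of \code{\link{choice_pair}}s (or \code{seq_fixture}).
#' @param seed Integer seed; same seed, same choices.
#' @param adjust Apply dominance detection when \code{params$theta} exists.
#' @return Binary vector (1 = high-NPV option chosen) named by pair id.
#' @export
simulate_participant <- function(family, params, pairs, seed = NULL,
                                 adjust = TRUE) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  p <- vapply(pairs, choice_probability, 0, family = family,
              params = params, adjust = adjust)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbinom(length(p), 1L, p)
  names(x) <- vapply(pairs, function(q) q$id, "")
  x
}

#' Simulate a mixed-model cohort with ground-truth labels
#'
#' Assigns each participant a generating family according to the mixture,
#' draws that family's parameters from its uniform prior (or uses fixed
#' values), and simulates independent Bernoulli choices over the pairs.
#' Truth labels are returned separately and never enter the choice data.
#'
#' @param n_participants Cohort size.
#' @param mixture Named proportions over generating families (normalized
#'   internally).
#' @param pairs List of \code{\link{choice_pair}}s (or \code{seq_fixture}).
#' @param params Either \code{"prior"} (draw each participant's parameters
#'   from the family prior) or a named list mapping family to a fixed
#'   parameter list.
#' @param seed Master seed; all substreams derive from it.
#' @param adjust Include dominance detection in the generating models.
#' @return Object of class \code{"seq_cohort"}: list with \code{choices}
#'   (N x npairs binary matrix, columns named by pair id) and \code{truth}
#'   (data frame of participant, family and generating parameters).
#' @export
simulate_cohort <- function(n_participants, mixture = c(TM = 1), pairs,
                            params = "prior", seed = NULL, adjust = TRUE) {
  if (inherits(pairs, "seq_fixture")) pairs <- pairs$pairs
  if (n_participants < 1) stopf("need at least one participant")
  mixture <- mixture / sum(mixture)
  fams <- names(mixture)
  if (!all(fams %in% MODEL_FAMILIES)) stopf("unknown family in mixture")
  if (!is.null(seed)) set.seed(substream_seed(seed, "assignment"))
  assign <- sample(fams, n_participants, replace = TRUE, prob = mixture)
  ids <- sprintf("p%03d", seq_len(n_participants))
  m <- length(pairs)
  X <- matrix(NA_real_, n_participants, m,
              dimnames = list(ids, vapply(pairs, function(p) p$id, "")))
  truth <- list()
  for (f in unique(assign)) {
    idx <- which(assign == f)
    if (identical(params, "prior")) {
      draws <- sample_prior(f, length(idx),
                            if (is.null(seed)) NULL else
                              substream_seed(seed, paste0("params_", f)),
                            adjust = adjust)
    } else {
      fx <- params[[f]] %||% stopf("no fixed parameters supplied for %s", f)
      draws <- sample_prior(f, length(idx), seed = NULL, fixed = fx,
                            adjust = adjust)
    }
    tab <- .family_table(pairs, f, adjust)
    P <- .prob_matrix(tab, draws, adjust)
    if (!is.null(seed)) set.seed(substream_seed(seed, paste0("choices_", f)))
    X[idx, ] <- (matrix(stats::runif(length(idx) * m), length(idx), m) < P) * 1
    tr <- as.data.frame(draws[family_parameters(f, adjust)])
    if (!ncol(tr)) tr <- data.frame(row.names = seq_along(idx))
    truth[[f]] <- cbind(data.frame(participant_id = ids[idx], family = f,
                                   stringsAsFactors = FALSE), tr)
  }
  truth <- do.call(rbind, lapply(truth, function(d) {
    for (col in c("gamma", "kappa", "delta", "beta", "sigma", "epsilon",
                  "theta"))
      if (is.null(d[[col]])) d[[col]] <- NA_real_
    d[, c("participant_id", "family", "gamma", "kappa", "delta", "beta",
          "sigma", "epsilon", "theta")]
  }))
  truth <- truth[match(ids, truth$participant_id), ]
  rownames(truth) <- NULL
  structure(list(choices = X, truth = truth, seed = seed),
            class = "seq_cohort")
}

#' @export
print.seq_cohort <- function(x, ...) {
  cat(sprintf("<seq_cohort> %d participants x %d pairs; generating mix: %s\n",
              nrow(x$choices), ncol(x$choices),
              paste(names(table(x$truth$family)), table(x$truth$family),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' The three hidden-zero tasks under one framing condition
#'
#' Smaller-sooner amounts of 150/300/450 today versus larger-later amounts
#' of 200/400/600 in one year (a constant 33.33\% interest rate). Framing:
#' \code{"none"} states no zeros, \code{"sooner_zero"} states only the zero
#' today attached to the larger-later option, \code{"later_zero"} states
#' only the zero in one year attached to the smaller-sooner option. The
#' larger-later option sits in the pair's high slot, so a choice of 1 is a
#' patient choice.
#'
#' @param condition One of \code{"none"}, \code{"sooner_zero"},
#'   \code{"later_zero"}.
#' @return List of three \code{\link{choice_pair}}s.
#' @export
hidden_zero_tasks <- function(condition = c("none", "sooner_zero",
                                            "later_zero")) {
  condition <- match.arg(condition)
  fx <- load_fixture("exp3_hidden_zero")
  fx$pairs[grep(paste0("_", condition, "$"), names(fx$pairs))]
}

#' Expected patience on the hidden-zero tasks (no sampling noise)
#'
#' The model-implied probability of choosing the larger-later option,
#' averaged over the three tasks of one framing condition. Used to verify
#' the analytic hidden-zero predictions: the tradeoff model responds to the
#' later zero but not the sooner one; the discounted-utility model responds
#' to neither; the zero-inferring sequences model responds identically to
#' either zero.
#'
#' @inheritParams simulate_participant
#' @param condition Framing condition (see \code{\link{hidden_zero_tasks}}).
#' @return Expected proportion of patient choices in \eqn{(0, 1)}.
#' @export
hidden_zero_expected_patience <- function(family, params, condition) {
  tasks <- hidden_zero_tasks(condition)
  mean(vapply(tasks, choice_probability, 0, family = family,
              params = params, adjust = TRUE))
}

#' Simulate hidden-zero choices for assigned participants
#'
#' Between-participant framing: each participant faces the three tasks of
#' one condition and patience is the fraction of larger-later choices.
#'
#' @param assignments Data frame with columns \code{participant_id},
#'   \code{family}, and parameter columns (as in a cohort's \code{truth}).
#' @param condition Single condition for all, or one per participant.
#' @param seed Master seed.
#' @return Data frame \code{participant_id}, \code{family},
#'   \code{condition}, \code{patience}, \code{n_tasks}.
#' @export
simulate_hidden_zero_cohort <- function(assignments, condition, seed = NULL) {
  n <- nrow(assignments)
  cond <- rep(condition, length.out = n)
  patience <- numeric(n)
  for (i in seq_len(n)) {
    fam <- assignments$family[i]
    par <- as.list(assignments[i, intersect(names(assignments),
                                            c("gamma", "kappa", "delta",
                                              "beta", "sigma", "epsilon",
                                              "theta"))])
    par <- par[!vapply(par, function(v) is.null(v) || is.na(v), TRUE)]
    tasks <- hidden_zero_tasks(cond[i])
    p <- vapply(tasks, choice_probability, 0, family = fam, params = par,
                adjust = TRUE)
    sd_i <- if (is.null(seed)) NULL else
      substream_seed(seed, paste0("hz_", assignments$participant_id[i]))
    if (!is.null(sd_i)) set.seed(sd_i)
    patience[i] <- mean(stats::rbinom(length(p), 1L, p))
  }
  data.frame(participant_id = assignments$participant_id,
             family = assignments$family, condition = cond,
             patience = patience, n_tasks = 3L, stringsAsFactors = FALSE)
}

#' Write / read a cohort's choice data as CSV
#'
#' Long format with columns \code{participant_id}, \code{pair_id},
#' \code{choice_high}; truth labels are written to a separate file and
#' never leak into the choices file.
#'
#' @param cohort A \code{"seq_cohort"} (or bare choices matrix for
#'   \code{write_choices}).
#' @param path Output CSV path.
#' @export
write_choices <- function(cohort, path) {
  X <- if (inherits(cohort, "seq_cohort")) cohort$choices else as.matrix(cohort)
  d <- data.frame(
    participant_id = rep(rownames(X), times = ncol(X)),
    pair_id = rep(colnames(X), each = nrow(X)),
    choice_high = as.integer(as.vector(X)), stringsAsFactors = FALSE)
  d <- d[order(d$participant_id, match(d$pair_id, colnames(X))), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname write_choices
#' @export
write_truth <- function(cohort, path) {
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}
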
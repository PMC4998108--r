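#' Candidate model families
#'
#' Five families describe binary choice between outcome sequences:
#' \describe{
#'   \item{TM}{Tradeoff model: accumulated outcome utility is traded off
#'     against the duration of utility accumulation, a cumulative weighing
#'     of time. Parameters \code{gamma} (utility curvature), \code{kappa}
#'     (impatience), \code{epsilon}, \code{theta}.}
#'   \item{DIUM}{Discounted instantaneous utility model: outcome utilities
#'     discounted by a per-period factor \code{delta} and summed.}
#'   \item{SMNZ}{Sequences model, concealed zeros not inferred: accumulated
#'     utility plus improvement (\code{beta}) and spreading (\code{sigma})
#'     components over stated outcomes only.}
#'   \item{SMZ}{Sequences model, concealed zeros inferred: the same
#'     components computed over the full period grid with blanks as zeros.}
#'   \item{RM}{Random-choice baseline: every choice is a coin toss, except
#'     possibly for dominance detection.}
#' }
#' All families share the logistic choice rule with sensitivity
#' \code{epsilon} and the dominance-detection adjustment \code{theta}.
#' @name model_families
NULL

MODEL_FAMILIES <- c("TM", "DIUM", "SMNZ", "SMZ", "RM")

# Zero policy attached to each family. SMZ evaluates the full grid with
# blanks filled as zeros; all other substantive families use stated cells
# only (so a revealed zero counts, a concealed one does not).
family_policy <- function(family) {
  switch(family, TM = "stated_only", DIUM = "stated_only",
         SMNZ = "stated_only", SMZ = "fill_concealed",
         RM = NA_character_, stopf("unknown model family '%s'", family))
}

family_parameters <- function(family, adjust = TRUE) {
  base <- switch(family,
    TM = c("gamma", "kappa", "epsilon"),
    DIUM = c("gamma", "delta", "epsilon"),
    SMNZ = c("gamma", "beta", "sigma", "epsilon"),
    SMZ = c("gamma", "beta", "sigma", "epsilon"),
    RM = character(0),
    stopf("unknown model family '%s'", family))
  if (adjust) c(base, "theta") else base
}

#' Power utility of a monetary amount
#'
#' \eqn{u(x) = x^\gamma} with the stipulation \eqn{u(0) = 0} for every
#' \eqn{\gamma}, including \eqn{\gamma = 0} (avoiding \eqn{0^0}).
#'
#' @param amount Nonnegative amount(s).
#' @param gamma Curvature exponent in \eqn{[0, 5]}; \eqn{\gamma < 1} is
#'   diminishing sensitivity, \eqn{\gamma = 1} linear utility.
#' @return Utility value(s).
#' @export
utility <- function(amount, gamma) {
  if (any(amount < 0)) stopf("negative amounts are out of scope (gain domain)")
  ifelse(amount == 0, 0, amount^gamma)
}

# Resolve an option to the cells a family-style zero policy includes.
# For fill_concealed with a companion option on a different grid, the
# companion's stated-zero reveals trigger inference of the complementary
# zero: the option is extended over the union grid with zero amounts.
.policy_cells <- function(option, zero_policy, companion = NULL) {
  if (zero_policy == "fill_concealed" && !is.null(companion) &&
      !identical(option$delay, companion$delay)) {
    any_revealed <- any(option$status == "stated" & option$amount == 0) ||
      any(companion$status == "stated" & companion$amount == 0)
    if (any_revealed) {
      grid <- sort(unique(c(option$delay, companion$delay)))
      amt <- numeric(length(grid))
      amt[match(option$delay, grid)] <- option$amount
      return(list(amount = amt, delay = grid))
    }
    return(option_cells(option, "stated_only"))
  }
  option_cells(option, zero_policy)
}

#' Duration of utility accumulation of an option
#'
#' The duration \eqn{\hat t} is a weighted average of the included delays,
#' \eqn{\hat t = \sum_j a_j t_j}. Under the default cumulative-utility
#' weighting each delay is weighted by the utility accumulated up to its
#' period, normalized over all periods:
#' \eqn{a_j = \sum_{k \le j} u(x_k) / \sum_i \sum_{k \le i} u(x_k)}.
#' The duration always lies between the first and last included delay; a
#' single dated outcome has duration equal to its delay. A revealed zero
#' occupies a period and therefore shifts the weighting even though its own
#' utility is zero.
#'
#' @param option A \code{\link{seq_option}}.
#' @param gamma Utility curvature (see \code{\link{utility}}).
#' @param zero_policy \code{"stated_only"} (blanks dropped, revealed zeros
#'   kept) or \code{"fill_concealed"} (blanks counted as zeros).
#' @param weighting \code{"cumulative_utility"} (default), \code{"uniform"}
#'   (\eqn{a_j = 1/n}), or \code{"outcome_proportional"}
#'   (\eqn{a_j = x_j / \sum x_i}); the alternatives are extension hooks.
#' @return Duration in the option's time unit.
#' @examples
#' duration(seq_option(c(500, 500), c(1, 3)), 1)        # 7/3
#' duration(seq_option(c(100, 0), c(0, 1)), 1)          # 1/2
#' duration(seq_option(c(0, 150), c(0, 1)), 1)          # 1
#' @export
duration <- function(option, gamma,
                     zero_policy = c("stated_only", "fill_concealed"),
                     weighting = c("cumulative_utility", "uniform",
                                   "outcome_proportional")) {
  zero_policy <- match.arg(zero_policy)
  weighting <- match.arg(weighting)
  cells <- option_cells(option, zero_policy)
  u <- utility(cells$amount, gamma)
  w <- switch(weighting,
    cumulative_utility = cumsum(u),
    uniform = rep(1, length(u)),
    outcome_proportional = cells$amount)
  if (sum(w) == 0)
    stopf("degenerate stimulus: zero total weight, duration undefined")
  sum(w * cells$delay) / sum(w)
}

#' Discounted instantaneous utility of an option
#'
#' \eqn{\sum_i \delta^{t_i} u(x_i)} over stated cells. Zero outcomes have
#' zero utility, so revealed and concealed zeros are equivalent here.
#'
#' @param option A \code{\link{seq_option}}.
#' @param gamma Utility curvature.
#' @param delta Per-period discount factor in \eqn{[0, 1]}.
#' @return Discounted utility.
#' @export
dium_value <- function(option, gamma, delta) {
  if (delta < 0 || delta > 1) stopf("delta must lie in [0,1]")
  cells <- option_cells(option, "stated_only")
  u <- utility(cells$amount, gamma)
  sum(ifelse(u == 0, 0, delta^cells$delay * u))
}

#' Deviation scores of a sequence from a uniform utility distribution
#'
#' For included cells re-indexed \eqn{1..n} in temporal order,
#' \eqn{d_i = (i/n)\sum_j u(x_j) - \sum_{j \le i} u(x_j)}: the gap between
#' the utility that would have accumulated under a flat sequence of the same
#' total and the utility actually accumulated. \eqn{d_n = 0} always. The sum
#' of the \eqn{d_i} is the improvement score; the sum of their absolute
#' values is the spreading score.
#'
#' @inheritParams duration
#' @return Numeric vector \eqn{d_1, ..., d_n}.
#' @examples
#' deviation_scores(seq_option(c(100, 200, 300), 1:3), 1)  # 100 100 0
#' @export
deviation_scores <- function(option, gamma,
                             zero_policy = c("stated_only", "fill_concealed")) {
  zero_policy <- match.arg(zero_policy)
  cells <- option_cells(option, zero_policy)
  u <- utility(cells$amount, gamma)
  n <- length(u)
  (seq_len(n) / n) * sum(u) - cumsum(u)
}

#' Sequences-model value of an option (relative-weighted)
#'
#' Accumulated utility plus weighted improvement and spreading components,
#' with the weights expressed in relative form:
#' \eqn{\sum u / (1+|\beta|+|\sigma|) + \beta^* \sum d_i -
#' \sigma^* \sum |d_i|}, where \eqn{\beta^* = \beta/(1+|\beta|+|\sigma|)}
#' and \eqn{\sigma^* = \sigma/(1+|\beta|+|\sigma|)}.
#'
#' @inheritParams duration
#' @param beta Improvement weight (positive = desire for improvement).
#' @param sigma Spreading weight (positive = desire for spreading, i.e.
#'   value decreases with departure from a uniform distribution).
#' @return Value in (relative-weighted) utility units.
#' @export
sm_value <- function(option, gamma, beta, sigma,
                     zero_policy = c("stated_only", "fill_concealed")) {
  zero_policy <- match.arg(zero_policy)
  d <- deviation_scores(option, gamma, zero_policy)
  cells <- option_cells(option, zero_policy)
  u <- utility(cells$amount, gamma)
  w <- 1 + abs(beta) + abs(sigma)
  (sum(u) + beta * sum(d) - sigma * sum(abs(d))) / w
}

#' Relative weights and the impatience/sensitivity tradeoff
#'
#' The weighting parameters of the tradeoff and sequences models are
#' reported as relative weights: \eqn{\kappa^* = \kappa/(1+\kappa)},
#' \eqn{\beta^* = \beta/(1+|\beta|+|\sigma|)},
#' \eqn{\sigma^* = \sigma/(1+|\beta|+|\sigma|)}. When utility differences
#' vanish (no curvature leverage), the tradeoff-model choice probabilities
#' depend on \eqn{\kappa} and \eqn{\epsilon} only through the product
#' \eqn{\epsilon \kappa^*}; \code{compensating_epsilon} returns the
#' sensitivity that leaves that product unchanged after moving \eqn{\kappa}.
#'
#' @param kappa,beta,sigma Raw weighting parameters.
#' @param epsilon Choice sensitivity paired with \code{kappa_from}.
#' @param kappa_from,kappa_to Impatience values between which to compensate.
#' @return A relative weight in \eqn{(-1, 1)}, or a compensating epsilon.
#' @export
kappa_star <- function(kappa) kappa / (1 + kappa)

#' @rdname kappa_star
#' @export
beta_star <- function(beta, sigma) beta / (1 + abs(beta) + abs(sigma))

#' @rdname kappa_star
#' @export
sigma_star <- function(beta, sigma) sigma / (1 + abs(beta) + abs(sigma))

#' @rdname kappa_star
#' @export
compensating_epsilon <- function(epsilon, kappa_from, kappa_to)
  epsilon * kappa_star(kappa_from) / kappa_star(kappa_to)

# Check that a dominance-flagged pair has its dominant option in the high
# slot; packaged fixtures guarantee this, arbitrary pairs may not.
.check_dominance_orientation <- function(pair) {
  if (pair$dominance && identical(pair$high$delay, pair$low$delay) &&
      !dominates(pair$high, pair$low))
    stopf("pair %s: dominance flag set but the high-NPV option is not the dominant one",
          pair$id)
  invisible(TRUE)
}

#' Model value difference between the options of a pair
#'
#' Returns the valuation advantage of the designated high-NPV option under a
#' model family: for TM,
#' \eqn{(\sum u_H - \sum u_L)/(1+\kappa) - \kappa^* (\hat t_H - \hat t_L)}
#' (time-weighing function \eqn{w} = identity); for DIUM and the sequences
#' models, the difference of option values under their zero policies.
#'
#' @param pair A \code{\link{choice_pair}}.
#' @param family One of \code{"TM"}, \code{"DIUM"}, \code{"SMNZ"},
#'   \code{"SMZ"} (the random baseline has no value difference).
#' @param params Named list of parameters (see \code{\link{model_families}}).
#' @return Numeric value difference (high minus low).
#' @examples
#' p <- choice_pair("x", seq_option(c(400, NA, 400), 1:3),
#'                  seq_option(c(NA, 800, NA), 1:3))
#' value_difference(p, "TM", list(gamma = 1, kappa = 1))  # -1/6
#' @export
value_difference <- function(pair, family, params) {
  if (!family %in% setdiff(MODEL_FAMILIES, "RM"))
    stopf("no value difference for family '%s'", family)
  pol <- family_policy(family)
  ch <- .policy_cells(pair$high, pol, pair$low)
  cl <- .policy_cells(pair$low, pol, pair$high)
  oh <- seq_option(ch$amount, ch$delay, pair$high$unit)
  ol <- seq_option(cl$amount, cl$delay, pair$low$unit)
  g <- params$gamma
  switch(family,
    TM = {
      su <- sum(utility(ch$amount, g)) - sum(utility(cl$amount, g))
      dt <- duration(oh, g, "stated_only") - duration(ol, g, "stated_only")
      (su - params$kappa * dt) / (1 + params$kappa)
    },
    DIUM = dium_value(oh, g, params$delta) - dium_value(ol, g, params$delta),
    SMNZ = sm_value(oh, g, params$beta, params$sigma, "stated_only") -
           sm_value(ol, g, params$beta, params$sigma, "stated_only"),
    SMZ = sm_value(oh, g, params$beta, params$sigma, "stated_only") -
          sm_value(ol, g, params$beta, params$sigma, "stated_only"))
}

#' Probability of choosing the high-NPV option
#'
#' Logistic choice rule \eqn{\hat P = 1/(1+\exp(-\epsilon \Delta))} with
#' \eqn{\Delta} the model value difference (high minus low); the random
#' baseline has \eqn{\hat P = 1/2}. On dominance pairs, when the family
#' includes dominance detection, the probability of the dominant (= high)
#' option becomes \eqn{\vartheta + (1-\vartheta)\hat P}.
#'
#' @inheritParams value_difference
#' @param family One of the five \code{\link{model_families}}.
#' @param adjust Apply the dominance-detection adjustment when the pair has a
#'   dominance relation and \code{params$theta} is present.
#' @return Probability in \eqn{(0, 1)} (unclamped; clamping happens inside
#'   log-likelihood terms only).
#' @export
choice_probability <- function(pair, family, params, adjust = TRUE) {
  p <- if (family == "RM") 0.5 else {
    eps <- params$epsilon %||% stopf("params$epsilon is required")
    stats::plogis(eps * value_difference(pair, family, params))
  }
  if (adjust && pair$dominance && !is.null(params$theta)) {
    .check_dominance_orientation(pair)
    p <- params$theta + (1 - params$theta) * p
  }
  p
}

#' Bernoulli log-likelihood of a choice vector under a model
#'
#' \eqn{\sum_i [x_i \log \hat P_i + (1-x_i)\log(1-\hat P_i)]}, with
#' \eqn{x_i = 1} when the high-NPV option was chosen from pair \eqn{i}.
#' Probabilities are clamped away from 0 and 1 inside the log terms so the
#' result is always finite.
#'
#' @inheritParams choice_probability
#' @param pairs List of \code{\link{choice_pair}}s.
#' @param choices Binary vector aligned with \code{pairs}.
#' @return Log-likelihood (nonpositive).
#' @export
choice_log_likelihood <- function(family, params, pairs, choices,
                                  adjust = TRUE) {
  if (length(pairs) != length(choices))
    stopf("choices (%d) not aligned with pairs (%d)",
          length(choices), length(pairs))
  p <- clamp_p(vapply(pairs, choice_probability, 0,
                      family = family, params = params, adjust = adjust))
  sum(choices * log(p) + (1 - choices) * log1p(-p))
}
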
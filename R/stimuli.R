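#' Construct an outcome option (a dated outcome or an outcome sequence)
#'
#' An option is an ordered collection of outcome cells on a period grid.
#' Each cell carries a delay, a monetary amount, and a status: \code{"stated"}
#' for an amount printed in the stimulus (possibly a stated zero), or
#' \code{"blank"} for an empty slot in a delay-by-payoff matrix (a concealed
#' zero). Blank cells carry amount 0 by convention; stated cells may carry a
#' genuine zero (a revealed zero), which some models treat differently from
#' a blank.
#'
#' @param amounts Numeric vector of amounts, one per grid period. Use
#'   \code{NA} for a blank (concealed-zero) slot; use \code{0} for a stated
#'   (revealed) zero.
#' @param delays Numeric vector of strictly increasing, nonnegative delays.
#' @param unit Time-unit label (e.g. \code{"years"}, \code{"months"},
#'   \code{"days"}). Purely descriptive; no cross-unit conversion is done.
#' @return An object of class \code{"seq_option"}.
#' @examples
#' seq_option(c(500, NA, 500), c(1, 2, 3))        # blank middle period
#' seq_option(c(300, 0, 300), c(1, 2, 3))         # revealed middle zero
#' seq_option(1000, 2)                            # single dated outcome
#' @export
seq_option <- function(amounts, delays, unit = "years") {
  if (length(amounts) != length(delays))
    stopf("amounts and delays must have equal length")
  if (length(amounts) == 0L) stopf("malformed stimulus: option has no cells")
  if (any(delays < 0)) stopf("delays must be nonnegative")
  if (is.unsorted(delays, strictly = TRUE))
    stopf("delays must be strictly increasing")
  status <- ifelse(is.na(amounts), "blank", "stated")
  amounts[is.na(amounts)] <- 0
  if (any(amounts < 0)) stopf("negative amounts are not supported")
  if (!any(status == "stated"))
    stopf("malformed stimulus: option has no stated cell")
  structure(
    list(delay = as.numeric(delays), amount = as.numeric(amounts),
         status = status, unit = unit),
    class = "seq_option")
}

#' @export
print.seq_option <- function(x, ...) {
  shown <- ifelse(x$status == "blank", ".", format(x$amount))
  cat("<seq_option> {", paste0(shown, "@", x$delay, collapse = ", "),
      "} [", x$unit, "]\n", sep = "")
  invisible(x)
}

# Cells included under a model's zero policy.
#   stated_only:    stated cells (incl. revealed zeros); blanks dropped.
#   fill_concealed: every grid cell, blanks counted as zeros.
option_cells <- function(option, zero_policy = c("stated_only", "fill_concealed")) {
  zero_policy <- match.arg(zero_policy)
  keep <- if (zero_policy == "stated_only") option$status == "stated"
          else rep(TRUE, length(option$amount))
  list(amount = option$amount[keep], delay = option$delay[keep])
}

n_stated <- function(option) sum(option$status == "stated")
option_total <- function(option) sum(option$amount[option$status == "stated"])
is_sequence <- function(option) n_stated(option) >= 2L

#' Cumulative monetary totals of an option per grid period
#'
#' Entry \eqn{i} is the sum of amounts received in periods \eqn{1..i}; blank
#' cells contribute 0. The final entry equals the option total. Cumulative
#' totals define outcome dominance between equal-grid options.
#'
#' @param option A \code{\link{seq_option}}.
#' @return Numeric vector of running totals, one per grid period.
#' @examples
#' cumulative_amounts(seq_option(c(800, NA, 800), 1:3))  # 800 800 1600
#' @export
cumulative_amounts <- function(option) {
  if (!inherits(option, "seq_option")) stopf("not a seq_option")
  cumsum(option$amount)
}

#' Outcome dominance between two options on a shared grid
#'
#' \code{x} dominates \code{y} when the cumulative monetary total of \code{x}
#' is never below that of \code{y} in any period and strictly above it in at
#' least one period. Dominance is evaluated on money with blanks as zeros,
#' independently of any model's zero policy.
#'
#' @param x,y Options (\code{\link{seq_option}}) on the same period grid.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
dominates <- function(x, y) {
  if (!identical(x$delay, y$delay) || !identical(x$unit, y$unit))
    stopf("dominance requires a shared period grid and unit")
  cx <- cumulative_amounts(x); cy <- cumulative_amounts(y)
  all(cx >= cy) && any(cx > cy)
}

#' Net present value of an option
#'
#' Discounts each stated amount at a constant per-period interest rate
#' \code{rate} and sums: \eqn{\sum_i x_i / (1+r)^{t_i}}. A zero rate returns
#' the plain total.
#'
#' @param option A \code{\link{seq_option}}.
#' @param rate Per-period interest rate, greater than \eqn{-1}.
#' @return Monetary value.
#' @examples
#' npv(seq_option(c(500, 500), c(1, 3)), 0.1)  # ~830.20
#' @export
npv <- function(option, rate) {
  if (rate <= -1) stopf("interest rate must exceed -1")
  cells <- option_cells(option, "stated_only")
  sum(cells$amount / (1 + rate)^cells$delay)
}

# NPV written with a per-period discount factor delta = 1/(1+r).
npv_factor <- function(option, delta) {
  cells <- option_cells(option, "stated_only")
  vapply(delta, function(d) sum(cells$amount * d^cells$delay), 0)
}

# Linear-utility duration on stated outcomes; used by the stimulus screen.
outcome_duration <- function(option) {
  cells <- option_cells(option, "stated_only")
  cw <- cumsum(cells$amount)
  if (sum(cw) == 0) stopf("degenerate stimulus: all outcomes zero")
  sum(cw * cells$delay) / sum(cw)
}

#' Construct a choice pair
#'
#' A pair of options on a shared period grid, one of which is designated the
#' high-NPV option (the option preferred by net present value at every
#' positive interest rate). When both options live on the same grid, the
#' dominance flag is computed from cumulative monetary totals; otherwise it
#' defaults to \code{FALSE}.
#'
#' @param id Identifier string.
#' @param high,low The designated high-NPV and low-NPV options.
#' @param dominance Optional logical override for the dominance flag.
#' @return An object of class \code{"choice_pair"}.
#' @export
choice_pair <- function(id, high, low, dominance = NULL) {
  if (!inherits(high, "seq_option") || !inherits(low, "seq_option"))
    stopf("high and low must be seq_option objects")
  if (!identical(high$unit, low$unit)) stopf("options must share a time unit")
  same_grid <- identical(high$delay, low$delay)
  if (is.null(dominance))
    dominance <- if (same_grid) dominates(high, low) else FALSE
  structure(
    list(id = as.character(id), high = high, low = low,
         dominance = isTRUE(dominance),
         equal_totals = isTRUE(all.equal(option_total(high), option_total(low)))),
    class = "choice_pair")
}

#' @export
print.choice_pair <- function(x, ...) {
  fmt <- function(o) paste0(ifelse(o$status == "blank", ".", format(o$amount)),
                            collapse = ",")
  cat(sprintf("<choice_pair %s> H={%s} vs L={%s}%s%s\n", x$id,
              fmt(x$high), fmt(x$low),
              if (x$dominance) " [dominance]" else "",
              if (x$equal_totals) " [equal totals]" else ""))
  invisible(x)
}

#' Screen a candidate choice pair on NPV and duration criteria
#'
#' Implements the two-stage stimulus screen for equal-total pairs. A pair is
#' discarded when the sign of the NPV difference between its options changes
#' across a grid of per-period discount factors (so that NPV could yield
#' either preference order depending on the rate); otherwise the NPV-preferred
#' option is designated high-NPV. A pair is additionally discarded when
#' linear-outcome duration strictly favors the same option as NPV (so that the
#' two principles agree); pairs with equal durations are kept.
#'
#' @param pair A \code{\link{choice_pair}} with equal totals.
#' @param discount_grid Per-period discount factors in (0,1) over which the
#'   NPV ordering must be constant. The default spans positive interest rates
#'   only, \eqn{\delta \in \{0.01, ..., 0.99\}}.
#' @return A list with elements \code{keep} (logical), \code{reason}
#'   (character), and, when kept, \code{pair}: the input pair re-oriented so
#'   that its \code{high} slot holds the NPV-preferred option.
#' @export
screen_pair <- function(pair, discount_grid = seq(0.01, 0.99, by = 0.01)) {
  if (!inherits(pair, "choice_pair")) stopf("not a choice_pair")
  if (!length(discount_grid)) stopf("discount grid is empty")
  if (any(discount_grid <= 0 | discount_grid >= 1))
    stopf("discount factors must lie in (0,1)")
  if (!pair$equal_totals)
    stopf("screening is defined for equal-total pairs only")
  d <- npv_factor(pair$high, discount_grid) - npv_factor(pair$low, discount_grid)
  s <- unique(sign(d))
  if (length(s) > 1L || any(s == 0))
    return(list(keep = FALSE, reason = "npv_sign_changes"))
  oriented <- if (s > 0) pair else
    choice_pair(pair$id, pair$low, pair$high)
  dur_h <- outcome_duration(oriented$high)
  dur_l <- outcome_duration(oriented$low)
  if (dur_h < dur_l)
    return(list(keep = FALSE, reason = "npv_agrees_with_duration"))
  list(keep = TRUE, reason = "keep", pair = oriented)
}

#' Enumerate and screen candidate choice pairs
#'
#' Spans the full two-option by \code{n_periods}-period stimulus space, each
#' slot holding one of \code{amounts} or a blank, applies the prior criteria
#' (distinct options, at least one sequence, every period covered by a
#' nonzero outcome in some option, at least one blank overall, no common
#' consequences unless relaxed, equal totals) and the NPV/duration screen of
#' \code{\link{screen_pair}}, and partitions the surviving pairs by
#' dominance. Enumeration is exhaustive and deterministic; when
#' \code{n_sample} is given, that many screened pairs are drawn reproducibly
#' under \code{seed}.
#'
#' @param amounts Candidate slot amounts (the blank slot is always added).
#' @param n_periods Number of grid periods.
#' @param delays Delays attached to the periods.
#' @param unit Time-unit label.
#' @param require_no_common_consequence Drop pairs in which both options
#'   yield an identical stated outcome in some period. The dominance-relation
#'   search relaxes this criterion.
#' @param discount_grid Passed to \code{\link{screen_pair}}.
#' @param n_sample,seed Optional reproducible subsample of the screened set.
#' @return List with elements \code{dominance} and \code{nondominance}, each
#'   a list of oriented \code{\link{choice_pair}} objects.
#' @export
search_pairs <- function(amounts = c(200, 400, 600, 800), n_periods = 3,
                         delays = seq_len(n_periods), unit = "years",
                         require_no_common_consequence = TRUE,
                         discount_grid = seq(0.01, 0.99, by = 0.01),
                         n_sample = NULL, seed = NULL) {
  slots <- c(NA, sort(amounts))
  grid <- as.matrix(expand.grid(rep(list(slots), n_periods)))
  keep_opt <- rowSums(!is.na(grid) & grid > 0) >= 1L
  grid <- grid[keep_opt, , drop = FALSE]
  m <- nrow(grid)
  tot <- rowSums(grid, na.rm = TRUE)
  kept <- list(); k <- 0L
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    a <- grid[i, ]; b <- grid[j, ]
    if (tot[i] != tot[j]) next
    sa <- sum(!is.na(a)); sb <- sum(!is.na(b))
    if (max(sa, sb) < 2L) next                       # at least one sequence
    if (!any(is.na(c(a, b)))) next                   # at least one blank
    az <- ifelse(is.na(a), 0, a); bz <- ifelse(is.na(b), 0, b)
    if (any(az == 0 & bz == 0)) next                 # each period covered
    if (require_no_common_consequence && any(az == bz)) next
    pr <- choice_pair(sprintf("cand_%d_%d", i, j),
                      seq_option(a, delays, unit), seq_option(b, delays, unit))
    sc <- screen_pair(pr, discount_grid)
    if (!sc$keep) next
    k <- k + 1L
    kept[[k]] <- sc$pair
  }
  if (!is.null(n_sample) && k > n_sample) {
    if (!is.null(seed)) set.seed(seed)
    kept <- kept[sort(sample.int(k, n_sample))]
  }
  dom <- vapply(kept, function(p) p$dominance, TRUE)
  list(dominance = kept[dom], nondominance = kept[!dom])
}
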
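# Shared objects for the test suite; everything is built in code.

tbl3 <- load_fixture("table3_exp2")

opt <- function(amounts, delays, unit = "years") seq_option(amounts, delays, unit)

pair_of <- function(h_amt, l_amt, delays = seq_along(h_amt), unit = "years",
                    id = "t") {
  choice_pair(id, seq_option(h_amt, delays, unit),
              seq_option(l_amt, delays, unit))
}

# Canonical parameter sets inside prior support.
par_tm <- function(...) modifyList(
  list(gamma = 1, kappa = 5, epsilon = 2, theta = 0.2), list(...))
par_dium <- function(...) modifyList(
  list(gamma = 0.7, delta = 0.6, epsilon = 1, theta = 0.1), list(...))
par_sm <- function(...) modifyList(
  list(gamma = 0.8, beta = -10, sigma = 20, epsilon = 0.5, theta = 0.2),
  list(...))

random_option <- function(max_cells = 4) {
  n <- sample(2:max_cells, 1)
  amounts <- sample(c(0, 100, 200, 400, 600, 800), n, replace = TRUE)
  if (all(amounts == 0)) amounts[1] <- 200
  blank <- runif(n) < 0.3 & amounts == 0
  amounts[blank] <- NA
  if (all(is.na(amounts))) amounts[1] <- 200
  delays <- sort(sample(0:9, n))
  seq_option(amounts, delays)
}
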
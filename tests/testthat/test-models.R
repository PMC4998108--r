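test_that("power utility satisfies u(0) = 0 for every curvature", {
  for (g in c(0, 0.5, 1, 5)) expect_identical(utility(0, g), 0)
  expect_equal(utility(7, 1), 7)
  expect_equal(utility(4, 0.5), 2)
  expect_error(utility(-1, 1), "negative")
})

test_that("duration reproduces the worked closed forms", {
  expect_equal(duration(opt(c(500, 500), c(1, 3)), 1), 7 / 3)
  expect_equal(duration(opt(c(100, 0), c(0, 1)), 1), 0.5)
  expect_equal(duration(opt(c(0, 150), c(0, 1)), 1), 1)
  expect_equal(duration(opt(c(300, 0, 300), 1:3), 1), 2.25)
  # revealed zeros shift durations regardless of curvature
  for (g in c(0, 0.4, 1, 3)) {
    expect_equal(duration(opt(c(100, 0), c(0, 1)), g), 0.5)
    expect_equal(duration(opt(c(0, 150), c(0, 1)), g), 1)
  }
  # token options, in days
  expect_equal(duration(opt(c(50, 200), c(1, 7), "days"), 1), 6)
  expect_equal(round(duration(opt(c(50, 400), c(1, 365), "days"), 1)), 329)
  expect_equal(round(duration(opt(c(5000, 200), c(1, 7), "days"), 1)), 4)
  expect_equal(round(duration(opt(c(5000, 400), c(1, 365), "days"), 1)), 190)
  # single dated outcome: duration is its delay
  expect_equal(duration(opt(800, 2), 1.7), 2)
  expect_error(duration(opt(c(0, 0), 1:2), 1), "degenerate")
})

test_that("duration lies between the first and last included delay", {
  set.seed(41)
  for (i in 1:60) {
    o <- random_option()
    g <- runif(1, 0, 5)
    d <- tryCatch(duration(o, g), error = function(e) NULL)
    if (is.null(d)) next
    cells <- o$delay[o$status == "stated"]
    expect_gte(d, min(cells) - 1e-12)
    expect_lte(d, max(cells) + 1e-12)
  }
})

test_that("revealing zeros lengthens low-NPV durations and shortens high-NPV ones", {
  nz <- load_fixture("table2_exp1_nozero")$pairs
  z <- load_fixture("table2_exp1_zero")$pairs
  for (i in 1:4) {
    expect_lt(duration(z[[i]]$high, 1), duration(nz[[i]]$high, 1))
    expect_gt(duration(z[[i]]$low, 1), duration(nz[[i]]$low, 1))
  }
})

test_that("discounted instantaneous utility ignores zeros and matches by hand", {
  o <- opt(c(500, 500), c(1, 3))
  expect_equal(dium_value(o, 1, 1), 1000)             # no discounting
  expect_equal(dium_value(o, 1, 0.9), 450 + 500 * 0.9^3)
  # a stated zero anywhere leaves the value unchanged
  oz <- opt(c(500, 0, 500), 1:3)
  expect_equal(dium_value(oz, 0.8, 0.7), dium_value(o, 0.8, 0.7))
})

test_that("deviation scores match the worked example and closed forms", {
  expect_equal(deviation_scores(opt(c(100, 200, 300), 1:3), 1), c(100, 100, 0))
  expect_equal(deviation_scores(opt(c(300, 200, 100), 1:3), 1), c(-100, -100, 0))
  expect_equal(deviation_scores(opt(c(250, 250, 250), 1:3), 1), c(0, 0, 0))
  set.seed(7)
  for (i in 1:40) {
    x <- sample(c(0, 100, 200, 400, 800), 3, replace = TRUE)
    if (all(x == 0)) x[2] <- 400
    g <- runif(1, 0, 3)
    u <- utility(x, g)
    d <- deviation_scores(opt(x, 1:3), g)
    expect_equal(d[3], 0)
    expect_equal(sum(d), u[3] - u[1])
    expect_equal(sum(abs(d)),
                 (abs(u[3] + u[2] - 2 * u[1]) + abs(2 * u[3] - u[2] - u[1])) / 3)
  }
})

test_that("sequences-model value uses relative weights", {
  o <- opt(c(100, 200, 300), 1:3)
  expect_equal(sm_value(o, 1, 1, 1), 600 / 3 + 200 / 3 - 200 / 3)
  flat <- opt(c(200, 200, 200), 1:3)
  for (b in c(-3, 0, 2)) for (s in c(-1, 0, 4))
    expect_equal(sm_value(flat, 1, b, s), 600 / (1 + abs(b) + abs(s)))
  # improvement equals spreading for an all-positive-deviation sequence
  d <- deviation_scores(o, 1)
  expect_equal(sum(d), sum(abs(d)))
})

test_that("relative-weight arithmetic matches the printed transforms", {
  expect_equal(round(kappa_star(18.73), 4), 0.9493)
  expect_equal(round(kappa_star(100), 4), 0.9901)
  expect_equal(compensating_epsilon(4.2350, 18.73, 100), 4.0605,
               tolerance = 2e-4)
  expect_equal(beta_star(1, 1), 1 / 3)
  expect_equal(sigma_star(-2, -2), -0.4)
})

test_that("value differences match hand calculations and symmetry", {
  p <- pair_of(c(400, NA, 400), c(NA, 800, NA))
  expect_equal(value_difference(p, "TM", list(gamma = 1, kappa = 1)), -1 / 6)
  same <- pair_of(c(400, NA, 400), c(400, NA, 400))
  for (fam in c("TM", "DIUM", "SMNZ", "SMZ")) {
    par <- switch(fam, TM = par_tm(), DIUM = par_dium(), par_sm())
    expect_equal(value_difference(same, fam, par), 0)
  }
  # DIUM at delta = 1 on an equal-total pair reduces to the utility difference
  p2 <- tbl3$pairs[[7]]
  g <- 0.6
  expect_equal(value_difference(p2, "DIUM", list(gamma = g, delta = 1)),
               sum(utility(p2$high$amount, g)) - sum(utility(p2$low$amount, g)))
})

test_that("TM and SMNZ ignore blanks; SMZ and DIUM ignore stated-vs-blank status", {
  with_blank <- opt(c(400, NA, 400), 1:3)
  no_blank <- opt(c(400, 400), c(1, 3))
  as_zero <- opt(c(400, 0, 400), 1:3)
  expect_equal(duration(with_blank, 0.8), duration(no_blank, 0.8))
  expect_equal(sm_value(with_blank, 0.8, 2, 3), sm_value(no_blank, 0.8, 2, 3))
  expect_equal(sm_value(with_blank, 0.8, 2, 3, "fill_concealed"),
               sm_value(as_zero, 0.8, 2, 3, "stated_only"))
  expect_equal(dium_value(with_blank, 0.8, 0.5), dium_value(as_zero, 0.8, 0.5))
  # TM does see the revealed zero
  expect_false(isTRUE(all.equal(duration(as_zero, 0.8),
                                duration(with_blank, 0.8))))
})

test_that("choice probabilities follow the logistic rule with dominance adjustment", {
  p11 <- tbl3$pairs[[11]]
  expect_equal(choice_probability(p11, "TM", par_tm(epsilon = 0)), 0.5)
  expect_equal(choice_probability(p11, "RM", list()), 0.5)
  p3 <- tbl3$pairs[[3]]
  expect_equal(choice_probability(p3, "RM", list(theta = 1)), 1)
  expect_equal(choice_probability(p3, "RM", list(theta = 0.5)), 0.75)
  # theta + (1-theta) p arithmetic at base p = 0.6
  base <- choice_probability(p3, "TM", par_tm(theta = NULL), adjust = FALSE)
  adj <- choice_probability(p3, "TM", par_tm(theta = 0.5))
  expect_equal(adj, 0.5 + 0.5 * base)
  # strictly increasing in sensitivity when the high option is ahead,
  # and complementary under option exchange without adjustment
  pr_eps <- sapply(c(0.5, 1, 2, 4), function(e)
    choice_probability(p3, "TM", par_tm(epsilon = e, theta = NULL),
                       adjust = FALSE))
  expect_true(all(diff(pr_eps) > 0))
  pr <- choice_probability(p11, "TM", par_tm(theta = NULL), adjust = FALSE)
  flipped <- choice_pair("flip", p11$low, p11$high)
  pr2 <- choice_probability(flipped, "TM", par_tm(theta = NULL), adjust = FALSE)
  expect_equal(pr + pr2, 1)
  # a dominance flag on a misoriented pair errors rather than reorienting
  bad <- choice_pair("bad", tbl3$pairs[[3]]$low, tbl3$pairs[[3]]$high,
                     dominance = TRUE)
  expect_error(choice_probability(bad, "TM", par_tm()), "dominant")
})

test_that("choice log-likelihood sums Bernoulli terms and stays finite", {
  pairs <- tbl3$pairs
  x <- rep(0L, 26)
  expect_equal(choice_log_likelihood("RM", list(), pairs, x), 26 * log(0.5))
  p11 <- pairs[[11]]
  ll <- choice_log_likelihood("TM", list(gamma = 1, kappa = 1, epsilon = 1,
                                         theta = 0), list(p11), 0)
  expect_equal(ll, log(1 / (1 + exp(-1 / 6))))
  # extreme sensitivity would give p within machine precision of 0/1
  far <- choice_log_likelihood("TM", par_tm(epsilon = 100, kappa = 100),
                               pairs, rep(1L, 26))
  expect_true(is.finite(far))
  expect_error(choice_log_likelihood("RM", list(), pairs, c(0, 1)), "aligned")
})
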
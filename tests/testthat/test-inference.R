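test_that("prior draws respect bounds, the uniform mean, and the seed contract", {
  for (fam in c("TM", "DIUM", "SMNZ", "SMZ")) {
    spec <- prior_spec(fam)
    dr <- sample_prior(fam, 500, seed = 3)
    for (i in seq_len(nrow(spec))) {
      v <- dr[[spec$parameter[i]]]
      expect_true(all(v >= spec$lower[i] & v <= spec$upper[i]))
    }
  }
  big <- sample_prior("TM", 2e5, seed = 8)
  expect_equal(mean(big$gamma), 2.5, tolerance = 0.02)
  expect_identical(sample_prior("SMZ", 50, seed = 4),
                   sample_prior("SMZ", 50, seed = 4))
  fx <- sample_prior("TM", 10, seed = 1, fixed = list(gamma = 1, theta = 0))
  expect_equal(fx$gamma, rep(1, 10))
  expect_equal(fx$theta, rep(0, 10))
})

test_that("the random baseline's marginal likelihood is exactly 0.5^m", {
  x <- simulate_participant("RM", list(), tbl3, seed = 1)
  ml <- marginal_likelihood("RM", tbl3$pairs, x, n_draws = 50, seed = 2,
                            adjust = FALSE)
  expect_identical(ml$ml, 0.5^26)
  ml2 <- marginal_likelihood("RM", tbl3$pairs, x, n_draws = 500, seed = 9,
                             adjust = FALSE)
  expect_identical(ml2$ml, ml$ml)
})

test_that("Monte-Carlo marginal likelihood agrees with grid quadrature on a 2-parameter reduction", {
  pairs <- tbl3$pairs
  x <- simulate_participant("TM", list(gamma = 1, kappa = 5, epsilon = 2,
                                       theta = 0), pairs, seed = 33)
  ml <- marginal_likelihood("TM", pairs, x, n_draws = 5e4, seed = 7,
                            fixed = list(gamma = 1, theta = 0))
  pf <- seqchoice:::.make_prob_fun(pairs, "TM", adjust = FALSE)
  lik <- function(kap, eps) {
    p <- seqchoice:::clamp_p(pf(c(gamma = 1, kappa = kap, epsilon = eps)))
    exp(sum(x * log(p) + (1 - x) * log1p(-p)))
  }
  np <- 201
  gr <- seq(0, 100, length.out = np)
  wts <- rep(1, np); wts[c(1, np)] <- 0.5
  L <- outer(gr, gr, Vectorize(lik))
  quad <- sum((wts %o% wts) * L) * (100 / (np - 1))^2 / 1e4
  expect_lt(abs(ml$ml - quad), 3 * ml$se)
})

test_that("marginal likelihood is an unbiased estimate across seeds", {
  pairs <- tbl3$pairs[1:10]
  x <- simulate_participant("DIUM", par_dium(), pairs, seed = 5)
  mls <- sapply(1:12, function(s)
    marginal_likelihood("DIUM", pairs, x, n_draws = 4e3, seed = s,
                        fixed = list(gamma = 0.7, theta = 0))$ml)
  pf <- seqchoice:::.make_prob_fun(pairs, "DIUM", adjust = FALSE)
  lik <- function(del, eps) {
    p <- seqchoice:::clamp_p(pf(c(gamma = 0.7, delta = del, epsilon = eps)))
    exp(sum(x * log(p) + (1 - x) * log1p(-p)))
  }
  gd <- seq(0, 1, length.out = 201); ge <- seq(0, 100, length.out = 201)
  wd <- rep(1, 201); wd[c(1, 201)] <- 0.5
  L <- outer(gd, ge, Vectorize(lik))
  quad <- sum((wd %o% wd) * L) * (1 / 200) * (100 / 200) / 100
  se_mean <- sd(mls) / sqrt(length(mls))
  expect_lt(abs(mean(mls) - quad), 3 * se_mean)
})

test_that("Bayes factors and posterior model probabilities behave algebraically", {
  expect_equal(bayes_factor(0.5^26, 0.5^27), 2)
  expect_equal(bayes_factor(3e-8, 3e-8), 1)
  expect_equal(bayes_factor(2e-9, 7e-8) * bayes_factor(7e-8, 2e-9), 1)
  expect_error(bayes_factor(1e-5, 0), "denominator")
  expect_equal(posterior_model_probabilities(c(a = 1, b = 1)),
               c(a = 0.5, b = 0.5))
  p <- posterior_model_probabilities(c(m1 = 2, m2 = 1, m3 = 1, m4 = 1))
  expect_equal(unname(p), c(0.4, 0.2, 0.2, 0.2))
  expect_equal(posterior_model_probabilities(c(a = 2e-9, b = 6e-9)),
               posterior_model_probabilities(c(a = 2e-3, b = 6e-3)))
  expect_error(posterior_model_probabilities(numeric(0)), "no marginal")
})

test_that("support tiers follow the all-Bayes-factor thresholds", {
  expect_equal(support_tier(c(4, 5, 6)), "substantial")
  expect_equal(support_tier(c(0.9, 5, 5)), "none")
  expect_equal(support_tier(c(150, 101, 200)), "decisive")
  expect_equal(support_tier(c(11, 29, 40)), "strong")
  expect_equal(support_tier(2), "anecdotal")
  expect_error(support_tier(numeric(0)), "no Bayes factors")
})

test_that("an RM-generated cohort is mostly won by random-baseline variants", {
  co <- simulate_cohort(40, c(RM = 1), tbl3, seed = 21)
  ct <- run_contest(co$choices, tbl3$pairs, "parallel", n_draws = 5e3,
                    seed = 13)
  expect_gt(mean(ct$winner %in% c("RM", "RM+dom")), 0.5)
  expect_equal(unname(rowSums(ct$posterior)), rep(1, 40))
  expect_equal(sum(ct$cohort_posterior), 1)
  expect_s3_class(summary(ct), "summary.seq_contest")
  expect_true(!is.null(ct$crosstab))
  df <- as.data.frame(ct)
  expect_equal(nrow(df), 40 * 10)
  expect_equal(sum(df$winner_flag), 40)
})

test_that("identical seeds reproduce a contest exactly; stability metrics are sane", {
  co <- simulate_cohort(12, c(TM = 0.5, DIUM = 0.5), tbl3, seed = 2)
  st <- stability_check(co$choices, tbl3$pairs, "main", n_draws = 3e3,
                        seed1 = 5, seed2 = 5)
  expect_equal(st$agreement, 1)
  expect_equal(st$mean_abs_deviation, 0)
  st2 <- stability_check(co$choices, tbl3$pairs, "main", n_draws = 3e3,
                         seed1 = 5, seed2 = 6)
  expect_gte(st2$agreement, 0)
  expect_gte(st2$mean_abs_deviation, 0)
})

test_that("hidden-zero tasks mixed into a dataset are excluded with a notice", {
  co <- simulate_cohort(5, c(TM = 1), tbl3, seed = 3)
  hz <- matrix(0, 5, 3, dimnames = list(rownames(co$choices),
                                        c("hz1_none", "hz2_none", "hz3_none")))
  both <- cbind(co$choices, hz)
  expect_message(ct <- run_contest(both, tbl3$pairs, "main", n_draws = 500,
                                   seed = 1), "excluding")
  expect_equal(ncol(ct$log_ml), 4)
})
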
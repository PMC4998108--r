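# Internal flattened representation of a pair set under a family's zero
# policy, plus vectorized evaluation of choice probabilities for many
# parameter draws at once. All contest-scale computation funnels through
# this file; the exported per-option functions in models.R define the
# semantics and the test suite cross-checks the two paths.

.family_table <- function(pairs, family, adjust = TRUE) {
  npairs <- length(pairs)
  dom <- vapply(pairs, function(p) p$dominance, TRUE)
  for (p in pairs) if (p$dominance) .check_dominance_orientation(p)
  if (family == "RM")
    return(list(family = family, npairs = npairs, dom = dom))
  pol <- family_policy(family)
  a <- numeric(0); tt <- numeric(0); o <- integer(0); wfrac <- numeric(0)
  opt_start <- integer(0); opt_end <- integer(0)
  oi <- 0L
  for (p in pairs) {
    for (side in c("high", "low")) {
      comp <- if (side == "high") p$low else p$high
      cells <- .policy_cells(p[[side]], pol, comp)
      n <- length(cells$amount)
      if (n == 0L || (all(cells$amount == 0) && family == "TM"))
        stopf("pair %s: degenerate option under policy %s", p$id, pol)
      oi <- oi + 1L
      opt_start <- c(opt_start, length(a) + 1L)
      a <- c(a, cells$amount); tt <- c(tt, cells$delay)
      o <- c(o, rep(oi, n)); wfrac <- c(wfrac, seq_len(n) / n)
      opt_end <- c(opt_end, length(a))
    }
  }
  nopts <- oi
  vals <- sort(unique(a[a > 0]))
  aidx <- ifelse(a > 0, match(a, vals), 0L)
  tv <- sort(unique(tt))
  tidx <- match(tt, tv)
  M <- matrix(0, nopts, length(a))
  M[cbind(o, seq_along(a))] <- 1
  list(family = family, npairs = npairs, dom = dom,
       a = a, t = tt, o = o, wfrac = wfrac,
       opt_start = opt_start, opt_end = opt_end, nopts = nopts,
       vals = vals, aidx = aidx, tv = tv, tidx = tidx, M = M,
       hi = seq(1L, nopts, by = 2L), lo = seq(2L, nopts, by = 2L))
}

# Choice-probability matrix for a batch of parameter draws.
# draws: named list of equal-length vectors; returns n_draws x npairs.
.prob_matrix <- function(tab, draws, adjust = TRUE) {
  n <- attr(draws, "n_draws") %||% length(draws[[1]])
  if (tab$family == "RM") {
    P <- matrix(0.5, n, tab$npairs)
  } else {
    g <- draws$gamma
    n <- length(g)
    ncells <- length(tab$a)
    PW <- matrix(tab$vals, n, length(tab$vals), byrow = TRUE)^g
    U <- matrix(0, n, ncells)
    for (j in seq_len(ncells))
      if (tab$aidx[j] > 0L) U[, j] <- PW[, tab$aidx[j]]
    C <- U
    for (j in seq_len(ncells))
      if (tab$opt_start[tab$o[j]] != j) C[, j] <- C[, j - 1L] + U[, j]
    SU <- C[, tab$opt_end, drop = FALSE]
    D <- switch(tab$family,
      TM = {
        num <- matrix(0, n, tab$nopts); den <- matrix(0, n, tab$nopts)
        for (j in seq_len(ncells)) {
          oj <- tab$o[j]
          num[, oj] <- num[, oj] + C[, j] * tab$t[j]
          den[, oj] <- den[, oj] + C[, j]
        }
        Th <- num / den
        ((SU[, tab$hi] - SU[, tab$lo]) -
           draws$kappa * (Th[, tab$hi] - Th[, tab$lo])) / (1 + draws$kappa)
      },
      DIUM = {
        DT <- outer(draws$delta, tab$tv, `^`)
        V <- matrix(0, n, tab$nopts)
        for (j in seq_len(ncells)) {
          oj <- tab$o[j]
          V[, oj] <- V[, oj] + U[, j] * DT[, tab$tidx[j]]
        }
        V[, tab$hi] - V[, tab$lo]
      },
      {
        SD <- matrix(0, n, tab$nopts); SAD <- matrix(0, n, tab$nopts)
        for (j in seq_len(ncells)) {
          oj <- tab$o[j]
          d <- tab$wfrac[j] * SU[, oj] - C[, j]
          SD[, oj] <- SD[, oj] + d
          SAD[, oj] <- SAD[, oj] + abs(d)
        }
        w <- 1 + abs(draws$beta) + abs(draws$sigma)
        ((SU[, tab$hi] - SU[, tab$lo]) +
           draws$beta * (SD[, tab$hi] - SD[, tab$lo]) -
           draws$sigma * (SAD[, tab$hi] - SAD[, tab$lo])) / w
      })
    P <- stats::plogis(draws$epsilon * D)
  }
  if (adjust && !is.null(draws$theta) && any(tab$dom)) {
    th <- draws$theta
    for (j in which(tab$dom)) P[, j] <- th + (1 - th) * P[, j]
  }
  P
}

# Per-draw log-likelihoods for one or many participants.
# X: binary matrix npairs x N (or vector); returns n_draws x N.
.loglik_matrix <- function(P, X) {
  X <- as.matrix(X)
  Pc <- clamp_p(P)
  log(Pc) %*% X + log1p(-Pc) %*% (1 - X)
}

.col_logsumexp <- function(M) {
  mx <- apply(M, 2, max)
  log(colSums(exp(sweep(M, 2, mx, "-")))) + mx
}

# Single-parameter-vector choice probabilities; a light closure used by the
# Metropolis-Hastings sampler where evaluation is sequential.
.make_prob_fun <- function(pairs, family, adjust = TRUE) {
  tab <- .family_table(pairs, family, adjust)
  if (family == "RM") {
    return(function(par) {
      p <- rep(0.5, tab$npairs)
      if (adjust && !is.null(par[["theta"]]) && any(tab$dom))
        p[tab$dom] <- par[["theta"]] + (1 - par[["theta"]]) * p[tab$dom]
      p
    })
  }
  prev <- tab$opt_start[tab$o]          # cell index preceding each option run
  function(par) {
    g <- par[["gamma"]]
    u <- numeric(length(tab$a))
    pos <- tab$aidx > 0L
    u[pos] <- tab$a[pos]^g
    cs <- cumsum(u)
    base <- c(0, cs)[prev]
    C <- cs - base
    SU <- C[tab$opt_end]
    D <- switch(tab$family,
      TM = {
        num <- as.vector(tab$M %*% (C * tab$t))
        den <- as.vector(tab$M %*% C)
        th <- num / den
        ((SU[tab$hi] - SU[tab$lo]) -
           par[["kappa"]] * (th[tab$hi] - th[tab$lo])) / (1 + par[["kappa"]])
      },
      DIUM = {
        v <- as.vector(tab$M %*% (u * par[["delta"]]^tab$t))
        v[tab$hi] - v[tab$lo]
      },
      {
        d <- tab$wfrac * SU[tab$o] - C
        sd_ <- as.vector(tab$M %*% d)
        sad <- as.vector(tab$M %*% abs(d))
        w <- 1 + abs(par[["beta"]]) + abs(par[["sigma"]])
        ((SU[tab$hi] - SU[tab$lo]) + par[["beta"]] * (sd_[tab$hi] - sd_[tab$lo]) -
           par[["sigma"]] * (sad[tab$hi] - sad[tab$lo])) / w
      })
    p <- stats::plogis(par[["epsilon"]] * D)
    if (adjust && !is.null(par[["theta"]]) && any(tab$dom))
      p[tab$dom] <- par[["theta"]] + (1 - par[["theta"]]) * p[tab$dom]
    p
  }
}
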
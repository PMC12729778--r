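# Independent brute-force oracles used across the suite. These re-derive
# each statistic from its definition (enumeration, closed form) and never
# call the package functions they check.

# Exact two-sided rank-sum p by enumeration of all assignments of the pooled
# values to the first group.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# BH step-up from its definition: after ascending sort,
# q(i) = min_{j >= i} m * p(j) / j, capped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Upper hypergeometric tail by direct summation of the pmf.
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- max(k, 0):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Two-group log-rank chi2 from the per-event-time O/E/V table.
oracle_logrank_chi2 <- function(times, events, groups) {
  lev <- sort(unique(groups))
  stopifnot(length(lev) == 2L)
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & groups == lev[1L])
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & groups == lev[1L])
    o_minus_e <- o_minus_e + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n_t - d_t) / (n_t - 1) * n1_t * (n_t - n1_t) / n_t^2
    }
  }
  o_minus_e^2 / v
}

# Kaplan-Meier survival by the product-limit definition at each event time.
oracle_km_surv <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events == 1)
    s <- s * (1 - d_t / n_t)
    out[i] <- s
  }
  list(time = ev_times, surv = out)
}
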
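# Independent oracles used to freeze expected values. Each is a brute-force
# or quadrature re-derivation, deliberately sharing no code with the package
# implementation it checks.

# JZS Bayes factor by dense-grid trapezoid quadrature, substituting
# u = g / (1 + g) to map (0, Inf) to (0, 1).
oracle_jzs <- function(t, n, r = sqrt(2) / 2, n_grid = 40001) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  f <- (1 + n * g)^(-0.5) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g)) * jac
  num <- sum((f[-1] + f[-n_grid]) / 2 * diff(u))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# One-way within-subjects F by explicit sums of squares on an n x k matrix
# (rows = participants).
oracle_rm_oneway <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_err <- sum((Y - gm)^2) - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(f = f, df1 = k - 1, df2 = (k - 1) * (n - 1),
       ms_err = ss_err / ((k - 1) * (n - 1)))
}

# Two-factor fully-within F values by explicit sums of squares on an
# n x a x b array (participant, factor A, factor B).
oracle_rm_3x3 <- function(Y) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  gm <- mean(Y)
  m_p <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_pa <- apply(Y, c(1, 2), mean); m_pb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  dev_pa <- m_pa - outer(m_p, rep(1, a)) - outer(rep(1, n), m_a) + gm
  ss_pa <- b * sum(dev_pa^2)
  dev_pb <- m_pb - outer(m_p, rep(1, b)) - outer(rep(1, n), m_b) + gm
  ss_pb <- a * sum(dev_pb^2)
  dev_ab <- m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + gm
  ss_ab <- n * sum(dev_ab^2)
  resid <- Y
  for (i in 1:n) for (j in 1:a) for (l in 1:b) {
    resid[i, j, l] <- Y[i, j, l] - m_pa[i, j] - m_pb[i, l] - m_ab[j, l] +
      m_p[i] + m_a[j] + m_b[l] - gm
  }
  ss_pab <- sum(resid^2)
  list(
    f_a = (ss_a / (a - 1)) / (ss_pa / ((a - 1) * (n - 1))),
    f_b = (ss_b / (b - 1)) / (ss_pb / ((b - 1) * (n - 1))),
    f_ab = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_pab / ((a - 1) * (b - 1) * (n - 1)))
  )
}

# Upper-tail p of the studentized range by direct double quadrature:
# P(Q > q) with k groups and df error degrees of freedom. The inner
# integral is the range probability at fixed scale, the outer integrates
# over the chi-distributed scale estimate.
oracle_tukey_p <- function(q, k, df) {
  range_cdf <- function(w) {
    if (w <= 0) return(0)
    stats::integrate(function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  s_density <- function(s) {
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  }
  cdf <- stats::integrate(
    function(s) {
      vapply(s, function(si) s_density(si) * range_cdf(q * si), numeric(1))
    }, 0, Inf, rel.tol = 1e-8
  )$value
  1 - cdf
}

# Tiny canonical trial tibble for descriptive-statistics unit tests:
# counts and responses are fully controlled.
make_manual_trials <- function(rows) {
  defaults <- tibble::tibble(
    participant_id = "P01", experiment = 1L, block = 1L,
    trial_index = seq_len(nrow(rows)), practice_flag = FALSE,
    relevant_dimension = "orientation", family = "rightward",
    irrelevant_probe_class = NA_character_,
    irrelevant_dist_from_mean = NA_integer_,
    irrelevant_dist_from_old = NA_integer_
  )
  dplyr::bind_cols(defaults[setdiff(names(defaults), names(rows))], rows)
}
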
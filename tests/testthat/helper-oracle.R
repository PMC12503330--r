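# Independent oracles, kept deliberately naive: these never touch the
# package's own matrix-exponential or likelihood code paths.

# Truncated power-series matrix exponential: sum_{k=0}^{n} (tQ)^k / k!
series_expm <- function(Q, t, n_terms = 30) {
  A <- Q * t
  acc <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(n_terms)) {
    term <- term %*% A / k
    acc <- acc + term
  }
  acc
}

# Brute-force panel log-likelihood: loop over rows, no count reduction.
brute_loglik <- function(panel, Q_by_region) {
  panel <- panel[order(panel$country, panel$week), ]
  ll <- 0
  for (subj in unique(panel$country)) {
    x <- panel[panel$country == subj, ]
    Q <- Q_by_region[[x$region[1]]]
    for (j in seq_len(nrow(x) - 1)) {
      dt <- x$week[j + 1] - x$week[j]
      P <- series_expm(Q, dt)
      ll <- ll + log(P[x$state[j], x$state[j + 1]])
    }
  }
  ll
}

# Random valid 3-state intensity matrix with moderate rates.
random_Q <- function(rate_range = c(0.02, 0.8)) {
  Q <- matrix(0, 3, 3)
  off <- row(Q) != col(Q)
  Q[off] <- stats::runif(6, rate_range[1], rate_range[2])
  diag(Q) <- -rowSums(Q)
  Q
}

# Random small panel drawn from the weekly chain P(1) of a random Q.
random_panel <- function(Q_by_region, n_subjects, n_weeks) {
  regions <- names(Q_by_region)
  out <- list()
  for (i in seq_len(n_subjects)) {
    g <- sample(regions, 1)
    P <- series_expm(Q_by_region[[g]], 1)
    s <- integer(n_weeks)
    s[1] <- sample.int(3, 1)
    for (j in seq_len(n_weeks - 1)) {
      s[j + 1] <- sample.int(3, 1, prob = P[s[j], ])
    }
    out[[i]] <- tibble::tibble(country = sprintf("s%02d", i), region = g,
                               week = seq_len(n_weeks), state = s)
  }
  dplyr::bind_rows(out)
}
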
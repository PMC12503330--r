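#' All six off-diagonal transitions of the three-state model
#'
#' The default transition structure: every state communicates with every
#' other (no absorbing state), so drastic jumps such as Good to Very
#' Unhealthy carry their own intensity rather than being structurally zero.
#'
#' @return A tibble with integer columns `from` and `to`.
#' @export
all_transitions <- function() {
  tidyr::expand_grid(from = 1:3, to = 1:3) |>
    dplyr::filter(.data$from != .data$to)
}

transition_label <- function(from, to) {
  labs <- aqi_state_labels()
  paste0(labs[from], "-", labs[to])
}

#' Build a transition intensity matrix
#'
#' Off-diagonal entries are `exp(log_baseline + beta %*% z)` for allowed
#' transitions and 0 otherwise; each diagonal entry is minus its row sum,
#' so rows sum to zero.
#'
#' @param log_baseline Numeric vector, one log-intensity per allowed
#'   transition (at the reference covariate pattern).
#' @param beta Optional matrix of covariate coefficients, one row per
#'   allowed transition, one column per covariate.
#' @param z Covariate vector (length `ncol(beta)`); the reference pattern is
#'   the zero vector.
#' @param transitions Tibble of allowed transitions (`from`, `to`), in the
#'   order `log_baseline` is given; defaults to [all_transitions()].
#' @return A 3×3 intensity matrix.
#' @examples
#' build_Q(log(c(0.1, 0.01, 0.2, 0.05, 0.02, 0.3)))
#' @export
build_Q <- function(log_baseline, beta = NULL, z = NULL,
                    transitions = all_transitions()) {
  k <- nrow(transitions)
  stopifnot(length(log_baseline) == k)
  eta <- log_baseline
  if (!is.null(beta) && !is.null(z) && length(z) > 0L) {
    beta <- matrix(beta, nrow = k)
    eta <- eta + drop(beta %*% z)
  }
  Q <- matrix(0, 3L, 3L,
              dimnames = list(aqi_state_labels(), aqi_state_labels()))
  Q[cbind(transitions$from, transitions$to)] <- exp(eta)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over an elapsed time
#'
#' Computes `P(t) = expm(t * Q)` by scaling-and-squaring Padé approximation.
#' Rows of the result sum to 1 and entries lie in `[0, 1]` up to numerical
#' tolerance.
#'
#' @param Q A valid intensity matrix (non-negative off-diagonal, rows
#'   summing to zero).
#' @param t Elapsed time in weeks, `t >= 0`.
#' @return A 3×3 (or `nrow(Q)`-square) stochastic matrix.
#' @examples
#' Q <- build_Q(log(c(0.1, 0.01, 0.2, 0.05, 0.02, 0.3)))
#' transition_probability(Q, 4)
#' @export
transition_probability <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("elapsed time t must be a single non-negative number", call. = FALSE)
  }
  if (t == 0) {
    return(diag(nrow(Q)) |> `dimnames<-`(dimnames(Q)))
  }
  P <- as.matrix(Matrix::expm(Q * t))
  # clip the Padé roundoff so probabilities are proper
  P[P < 0 & P > -1e-12] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Reduce a panel to transition-count matrices grouped by (region, dt).
# Returns a tibble: region, dt, counts (list of 3x3 matrices).
panel_count_groups <- function(panel, allow_gaps = FALSE) {
  panel <- validate_panel(panel, allow_gaps = allow_gaps)
  pairs <- transition_pairs(panel)
  if (any(pairs$dt <= 0)) stop("non-positive week gaps in panel", call. = FALSE)
  if (allow_gaps) pairs <- pairs  # gapped pairs keep their true dt
  pairs |>
    dplyr::group_by(.data$region, .data$dt) |>
    dplyr::summarise(counts = {
      m <- matrix(0, 3L, 3L)
      for (k in seq_along(.data$from)) {
        m[.data$from[k], .data$to[k]] <- m[.data$from[k], .data$to[k]] + 1
      }
      list(m)
    }, .groups = "drop")
}

# Log-likelihood from count groups given a named list of Q matrices.
loglik_from_groups <- function(groups, Q_by_region) {
  ll <- 0
  for (i in seq_len(nrow(groups))) {
    Q <- Q_by_region[[groups$region[i]]]
    P <- transition_probability(Q, groups$dt[i])
    # guard against matrix-exponential overflow at extreme rates: a result
    # that is not a proper stochastic matrix invalidates the parameters
    if (any(!is.finite(P)) || any(P < -1e-8) || any(P > 1 + 1e-8) ||
        max(abs(rowSums(P) - 1)) > 1e-6) {
      return(-Inf)
    }
    N <- groups$counts[[i]]
    pos <- N > 0
    if (any(P[pos] <= 0)) return(-Inf)
    ll <- ll + sum(N[pos] * log(P[pos]))
  }
  ll
}

#' Panel log-likelihood under given intensity matrices
#'
#' The likelihood of a panel-observed Markov chain is a product over
#' consecutive within-subject observation pairs of matrix-exponential
#' entries: each pair `(state_j, state_{j+1})` a week apart contributes
#' `log P(dt)[state_j, state_{j+1}]` with `P(dt) = expm(dt * Q)` for the
#' subject's region.
#'
#' @inheritParams validate_panel
#' @param intensities A single intensity matrix (applied to every subject),
#'   or a named list of intensity matrices keyed by region.
#' @return The log-likelihood; `-Inf` (with a warning) when an observed
#'   pair is impossible under the supplied structure.
#' @export
msm_loglik <- function(panel, intensities, allow_gaps = FALSE) {
  groups <- panel_count_groups(panel, allow_gaps = allow_gaps)
  if (is.matrix(intensities)) {
    intensities <- stats::setNames(
      rep(list(intensities), length(unique(groups$region))),
      unique(groups$region)
    )
  }
  missing_regions <- setdiff(unique(groups$region), names(intensities))
  if (length(missing_regions) > 0L) {
    stop("no intensity matrix for region(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  ll <- loglik_from_groups(groups, intensities)
  if (!is.finite(ll)) {
    warning("panel contains transitions impossible under the supplied ",
            "intensity structure; log-likelihood is -Inf", call. = FALSE)
  }
  ll
}
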
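# Fixtures and independent oracles shared across the test files.

# A fixed 20-row, 4-condition table used for the interaction-screen checks.
# Constructed so that some pairs/triples pass a 1% screen and others do not.
toy_screen_table <- function() {
  m <- matrix(c(
    # a  b  c  d
    1, 1, 0, 0,
    1, 1, 1, 0,
    1, 0, 1, 0,
    0, 1, 1, 0,
    1, 1, 1, 1,
    0, 0, 0, 0,
    1, 0, 0, 0,
    0, 1, 0, 0,
    0, 0, 1, 1,
    1, 1, 0, 1,
    0, 0, 0, 0,
    1, 0, 0, 0,
    0, 0, 0, 0,
    1, 1, 0, 0,
    0, 0, 0, 1,
    0, 0, 0, 0,
    1, 0, 1, 0,
    0, 1, 0, 0,
    0, 0, 0, 0,
    1, 1, 1, 0
  ), ncol = 4, byrow = TRUE, dimnames = list(NULL, c("a", "b", "c", "d")))
  m
}

# Independent brute-force oracle for the prevalence screen: enumerate every
# pair and triple by explicit loops and weighted averaging.
brute_force_screen <- function(m, w = NULL, min_prev = 0.01,
                               max_order = 3) {
  if (is.null(w)) w <- rep(1, nrow(m))
  nms <- sort(colnames(m))
  found <- character()
  for (ord in 2:max_order) {
    cmb <- utils::combn(nms, ord, simplify = FALSE)
    for (cc in cmb) {
      joint <- rep(1, nrow(m))
      for (p in cc) joint <- joint * m[, p]
      if (sum(w * joint) / sum(w) >= min_prev) {
        found <- c(found, paste(cc, collapse = ":"))
      }
    }
  }
  found
}

# Compact generator configuration: 6 conditions, group + deprivation in the
# threshold equation, and group shares balanced enough that every group's
# threshold coefficients are identified at a few thousand rows. Small enough
# that dozens of fits run quickly.
compact_config <- function(n, seed, ...) {
  synth_config(
    n = n, seed = seed,
    prevalence = c(arthritis = 0.107, asthma = 0.106, diabetes = 0.066,
                   hbp = 0.167, back = 0.096, mental = 0.053),
    group_shares = c(white = 0.70, asian = 0.15, black = 0.08,
                     mixed = 0.04, other_eth = 0.03),
    true_lambda = c(0.3, -0.5, -0.6, -0.7),
    include_agesex = FALSE, include_healthcare = FALSE, n_waves = 1,
    ...
  )
}

# Central finite differences of the log-likelihood, the oracle for the
# analytic score.
fd_score <- function(par, X, Z, y, w, h = 1e-5) {
  p <- ncol(X); q <- ncol(Z)
  as_params <- function(v) {
    u <- reportshift:::unpack_params(v, p, q)
    hopit_params(u$beta, u$lambda, u$gamma)
  }
  vapply(seq_along(par), function(i) {
    up <- par; up[i] <- up[i] + h
    lo <- par; lo[i] <- lo[i] - h
    (hopit_loglik(as_params(up), X, Z, y, w) -
       hopit_loglik(as_params(lo), X, Z, y, w)) / (2 * h)
  }, numeric(1))
}

# Random feasible parameter set conforming to p latent and q threshold
# columns (kept in a range where no clipping or underflow occurs).
random_params <- function(p, q) {
  hopit_params(
    beta = stats::runif(p, -0.6, 0.6),
    lambda = c(stats::runif(1, -0.5, 1), stats::runif(3, -0.8, 0.4)),
    gamma = matrix(stats::runif(4 * q, -0.3, 0.3), q, 4)
  )
}
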
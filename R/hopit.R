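# Survey-weighted hierarchical ordered probit (HOPIT).
#
# Latent index:   h*_i = beta' x_i + e_i,  e_i ~ N(0, 1)
# Thresholds:     tau_1 = lambda_1 + gamma_1' z_i
#                 tau_j = tau_{j-1} + exp(lambda_j + gamma_j' z_i), j = 2..4
#                 tau_0 = -Inf, tau_5 = +Inf
# Observed level: y_i = j  iff  tau_{j-1} <= h*_i < tau_j
#
# Identification: the error scale is fixed at 1 and the latent equation has
# no intercept (absorbed into lambda_1); no covariate may enter both x and z.
# The exponentiated increments keep tau_1 < tau_2 < tau_3 < tau_4 for every
# parameter value, which is the point of this parametrization.

EXP_CLIP <- 30

as_design_matrix <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (inherits(x, c("latent_design", "threshold_design"))) return(x$matrix)
  m <- as.matrix(x)
  if (ncol(m) > 0 && is.null(colnames(m))) {
    colnames(m) <- paste0(what, seq_len(ncol(m)))
  }
  storage.mode(m) <- "double"
  m
}

#' Construct a HOPIT parameter set
#'
#' @param beta latent-equation coefficients (length p, may be length 0).
#' @param lambda the 4 threshold intercepts.
#' @param gamma threshold-equation coefficients: a q x 4 matrix (one column
#'   per threshold), a list of 4 length-q vectors, or NULL for an empty
#'   threshold design.
#' @return An object of class `"hopit_params"`.
#' @export
hopit_params <- function(beta, lambda, gamma = NULL) {
  beta_names <- names(beta)
  beta <- as.numeric(beta)
  names(beta) <- beta_names
  lambda <- as.numeric(lambda)
  if (length(lambda) != 4) stop("lambda must have length 4", call. = FALSE)
  if (is.null(gamma)) gamma <- matrix(0, 0, 4)
  if (is.list(gamma)) {
    if (length(gamma) != 4) stop("gamma must have 4 components",
                                 call. = FALSE)
    gamma <- do.call(cbind, lapply(gamma, as.numeric))
  }
  gamma <- as.matrix(gamma)
  if (ncol(gamma) != 4) stop("gamma must have one column per threshold",
                             call. = FALSE)
  if (!all(is.finite(c(beta, lambda, gamma)))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  structure(list(beta = beta, lambda = lambda, gamma = gamma),
            class = "hopit_params")
}

get_params <- function(object) {
  if (inherits(object, "hopit")) return(object$params)
  if (inherits(object, "hopit_params")) return(object)
  stop("expected a 'hopit' fit or 'hopit_params' object", call. = FALSE)
}

pack_params <- function(params) {
  c(params$beta, params$lambda, as.numeric(params$gamma))
}

unpack_params <- function(par, p, q) {
  list(beta = par[seq_len(p)],
       lambda = par[p + 1:4],
       gamma = matrix(par[p + 4 + seq_len(4 * q)], q, 4))
}

param_names <- function(xnames, znames) {
  c(xnames, paste0("lambda", 1:4),
    if (length(znames)) {
      as.vector(vapply(1:4, function(j) paste0("gamma", j, ".", znames),
                       character(length(znames))))
    })
}

#' Deterministic part of the latent health index
#'
#' Returns beta' x_i per respondent.
#'
#' @param params a `"hopit_params"` object or a fitted `"hopit"` model.
#' @param latent a `"latent_design"` or design matrix.
#' @return Numeric vector, one value per row.
#' @export
latent_index <- function(params, latent) {
  params <- get_params(params)
  X <- as_design_matrix(latent, "x")
  if (ncol(X) != length(params$beta)) {
    stop("latent design has ", ncol(X), " columns but beta has length ",
         length(params$beta), call. = FALSE)
  }
  if (length(params$beta) == 0) return(rep(0, nrow(X)))
  drop(X %*% params$beta)
}

compute_tau <- function(lambda, gamma, Z, clip = TRUE) {
  n <- nrow(Z)
  A <- matrix(lambda, n, 4, byrow = TRUE)
  if (ncol(Z) > 0) A <- A + Z %*% gamma
  inc_arg <- A[, 2:4, drop = FALSE]
  if (clip) {
    out_of_range <- any(abs(inc_arg) > EXP_CLIP)
    inc_arg <- pmin(pmax(inc_arg, -EXP_CLIP), EXP_CLIP)
    attr_clip <- out_of_range
  } else {
    attr_clip <- FALSE
  }
  E <- exp(inc_arg)
  tau <- cbind(A[, 1], A[, 1] + E[, 1], A[, 1] + E[, 1] + E[, 2],
               A[, 1] + E[, 1] + E[, 2] + E[, 3])
  list(tau = tau, E = E, clipped = attr_clip)
}

#' Per-respondent category thresholds
#'
#' Evaluates tau_1..tau_4 for each row of the threshold design. The implicit
#' outer thresholds are tau_0 = -Inf and tau_5 = +Inf. By construction the
#' four finite thresholds are strictly increasing for any parameter values.
#'
#' @inheritParams latent_index
#' @param threshold a `"threshold_design"`, design matrix, or NULL / a
#'   zero-column matrix for the reduction to a plain ordered probit.
#' @param n number of rows when `threshold` is NULL.
#' @return An n x 4 numeric matrix of thresholds.
#' @export
hopit_thresholds <- function(params, threshold = NULL, n = NULL) {
  params <- get_params(params)
  Z <- as_design_matrix(threshold, "z")
  if (is.null(Z)) {
    if (is.null(n)) stop("supply a threshold design or n", call. = FALSE)
    Z <- matrix(0, n, 0)
  }
  if (ncol(Z) != nrow(params$gamma)) {
    stop("threshold design has ", ncol(Z), " columns but gamma has ",
         nrow(params$gamma), " rows", call. = FALSE)
  }
  res <- compute_tau(params$lambda, params$gamma, Z)
  if (res$clipped) {
    warning("threshold exponent arguments beyond +/-", EXP_CLIP,
            " were clipped", call. = FALSE)
  }
  colnames(res$tau) <- paste0("tau", 1:4)
  res$tau
}

category_probs <- function(params, X, Z) {
  eta <- if (length(params$beta)) drop(X %*% params$beta) else rep(0, nrow(Z))
  tau <- compute_tau(params$lambda, params$gamma, Z)$tau
  cum <- cbind(0, stats::pnorm(tau - eta), 1)
  P <- cum[, 2:6, drop = FALSE] - cum[, 1:5, drop = FALSE]
  colnames(P) <- paste0("level", 1:5)
  P
}

# Joint log-likelihood and analytic score. Returns both so the optimizer can
# share one evaluation; the per-row score matrix feeds the sandwich vcov.
loglik_and_score <- function(par, X, Z, y, w, want_score = TRUE,
                             by_row = FALSE) {
  p <- ncol(X); q <- ncol(Z); n <- length(y)
  th <- unpack_params(par, p, q)
  res <- compute_tau(th$lambda, th$gamma, Z)
  tau <- res$tau; E <- res$E
  eta <- if (p) drop(X %*% th$beta) else rep(0, n)
  idx <- seq_len(n)
  au <- ifelse(y == 5L, Inf, tau[cbind(idx, pmin(y, 4L))] - eta)
  al <- ifelse(y == 1L, -Inf, tau[cbind(idx, pmax(y - 1L, 1L))] - eta)
  pr <- pmax(stats::pnorm(au) - stats::pnorm(al), 1e-300)
  ll <- sum(w * log(pr))
  if (!want_score) return(list(loglik = ll))

  phi_u <- ifelse(is.finite(au), stats::dnorm(au), 0)
  phi_l <- ifelse(is.finite(al), stats::dnorm(al), 0)
  su <- w * phi_u / pr       # d ll / d tau_y        (0 when y = 5)
  sl <- -w * phi_l / pr      # d ll / d tau_{y-1}    (0 when y = 1)
  s <- su + sl
  # multipliers m_j = d ll / d (lambda_j + gamma_j' z) per row
  M <- matrix(0, n, 4)
  M[, 1] <- s
  for (j in 2:4) {
    M[, j] <- E[, j - 1] *
      (su * (j <= y) + sl * (j <= (y - 1L)))
  }
  if (by_row) {
    S <- matrix(0, n, p + 4 + 4 * q)
    if (p) S[, seq_len(p)] <- (-s) * X
    S[, p + 1:4] <- M
    if (q) {
      for (j in 1:4) S[, p + 4 + (j - 1) * q + seq_len(q)] <- M[, j] * Z
    }
    return(list(loglik = ll, score = colSums(S), score_matrix = S))
  }
  g <- numeric(p + 4 + 4 * q)
  if (p) g[seq_len(p)] <- -colSums(s * X)
  g[p + 1:4] <- colSums(M)
  if (q) {
    for (j in 1:4) g[p + 4 + (j - 1) * q + seq_len(q)] <- colSums(M[, j] * Z)
  }
  list(loglik = ll, score = g)
}

#' Weighted HOPIT log-likelihood
#'
#' Sum over respondents of w_i times the log probability of the observed
#' level, with category probabilities from the normal CDF between adjacent
#' thresholds. Probabilities are floored at 1e-300 before the log so extreme
#' parameter values never produce -Inf.
#'
#' @inheritParams latent_index
#' @param threshold a `"threshold_design"`, matrix, or NULL (plain ordered
#'   probit).
#' @param outcome integer vector of levels in 1..5.
#' @param weights non-negative survey weights (default all 1).
#' @return The weighted log-likelihood (a single number).
#' @export
hopit_loglik <- function(params, latent, threshold, outcome, weights = NULL) {
  d <- prepare_inputs(params, latent, threshold, outcome, weights)
  loglik_and_score(d$par, d$X, d$Z, d$y, d$w, want_score = FALSE)$loglik
}

#' Analytic score of the weighted log-likelihood
#'
#' Gradient over the stacked parameter vector (beta, lambda_1..4,
#' gamma_1..4), obtained by the chain rule through the exponentiated
#' threshold increments.
#'
#' @inheritParams hopit_loglik
#' @param by_row also return the n x npar matrix of per-row (weighted) score
#'   contributions.
#' @return Named numeric gradient; with `by_row = TRUE`, a list with
#'   `score` and `score_matrix`.
#' @export
hopit_score <- function(params, latent, threshold, outcome, weights = NULL,
                        by_row = FALSE) {
  d <- prepare_inputs(params, latent, threshold, outcome, weights)
  res <- loglik_and_score(d$par, d$X, d$Z, d$y, d$w, by_row = by_row)
  nm <- param_names(colnames(d$X), colnames(d$Z))
  names(res$score) <- nm
  if (by_row) {
    colnames(res$score_matrix) <- nm
    return(res[c("score", "score_matrix")])
  }
  res$score
}

prepare_inputs <- function(params, latent, threshold, outcome, weights) {
  params <- get_params(params)
  X <- as_design_matrix(latent, "x")
  Z <- as_design_matrix(threshold, "z")
  y <- check_outcome(outcome)
  if (is.null(Z)) Z <- matrix(0, length(y), 0)
  if (is.null(X)) X <- matrix(0, length(y), 0)
  w <- check_weights(weights, length(y))
  if (all(w == 0)) stop("all weights are zero", call. = FALSE)
  if (ncol(X) != length(params$beta) || ncol(Z) != nrow(params$gamma)) {
    stop("parameter dimensions do not conform to the designs", call. = FALSE)
  }
  list(par = pack_params(params), X = X, Z = Z, y = y, w = w)
}

#' Optimization settings for [hopit()]
#'
#' @param maxit BFGS iteration cap.
#' @param reltol BFGS relative log-likelihood tolerance.
#' @param grad_tol max-norm gradient tolerance declaring convergence.
#' @param newton_maxit Newton polishing iteration cap after BFGS.
#' @return A list of control settings.
#' @export
hopit_control <- function(maxit = 1000, reltol = 1e-12, grad_tol = 1e-5,
                          newton_maxit = 25) {
  list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
       newton_maxit = newton_maxit)
}

start_values <- function(y, w, p, q) {
  # lambda chosen so the baseline thresholds reproduce the weighted
  # cumulative outcome distribution through the probit link; beta = gamma = 0
  cw <- vapply(1:4, function(j) sum(w[y <= j]), 0) / sum(w)
  cw <- pmin(pmax(cw, 1e-6), 1 - 1e-6)
  cw <- cummax(cw + (1:4) * 1e-8)
  cpt <- stats::qnorm(cw)
  lambda <- c(cpt[1], log(pmax(diff(cpt), 1e-4)))
  c(rep(0, p), lambda, rep(0, 4 * q))
}

#' Fit a hierarchical ordered probit model
#'
#' Maximizes the survey-weighted log-likelihood by BFGS with the analytic
#' score, then polishes with Newton steps using a numerically differentiated
#' Hessian. The covariance matrix is the inverse observed information at the
#' optimum (or a design-based sandwich). An intercept-only weighted ordered
#' probit is fitted alongside to provide the null log-likelihood used by the
#' fit metrics.
#'
#' @param outcome integer vector of reported levels in 1..5.
#' @param latent a [build_latent_design()] result or binary design matrix
#'   for the latent-health equation; NULL or zero columns for an
#'   intercept-only model.
#' @param threshold a [build_threshold_design()] result or matrix for the
#'   reporting-behaviour equation; NULL or zero columns reduces the model to
#'   a standard ordered probit.
#' @param weights non-negative survey weights; default all 1.
#' @param dimension optional label (e.g. `"Mobility"`) carried into reports.
#' @param start optional starting parameter vector.
#' @param control see [hopit_control()].
#' @param vcov_type `"observed"` (inverse observed information) or
#'   `"sandwich"` (information-sandwich using per-row weighted scores, which
#'   does not take the weighted information as a model-based quantity).
#' @param keep_data retain the designs, outcome and weights in the object
#'   (needed by [count_r2()], [standardize_coefficients()],
#'   [threshold_contrasts()] and the predict/simulate methods).
#' @return An object of class `"hopit"`.
#' @examples
#' set.seed(1)
#' n <- 500
#' x <- cbind(cond = rbinom(n, 1, 0.3))
#' z <- cbind(grp = rbinom(n, 1, 0.2))
#' tr <- hopit_params(0.5, c(0.3, -0.3, -0.3, -0.3), matrix(c(0.3, 0, 0, 0), 1))
#' h <- drop(x %*% tr$beta) + rnorm(n)
#' tau <- hopit_thresholds(tr, z)
#' y <- 1L + rowSums(h >= tau)
#' fit <- hopit(y, x, z)
#' coef(fit)
#' @export
hopit <- function(outcome, latent = NULL, threshold = NULL, weights = NULL,
                  dimension = NULL, start = NULL,
                  control = hopit_control(),
                  vcov_type = c("observed", "sandwich"),
                  keep_data = TRUE) {
  vcov_type <- match.arg(vcov_type)
  y <- check_outcome(outcome)
  n <- length(y)
  X <- as_design_matrix(latent, "x")
  Z <- as_design_matrix(threshold, "z")
  if (is.null(X)) X <- matrix(0, n, 0)
  if (is.null(Z)) Z <- matrix(0, n, 0)
  if (nrow(X) != n || nrow(Z) != n) {
    stop("designs and outcome have different row counts", call. = FALSE)
  }
  overlap <- intersect(colnames(X), colnames(Z))
  if (length(overlap)) {
    stop("column(s) ", paste(overlap, collapse = ", "),
         " appear in both equations; the two sets must be disjoint",
         call. = FALSE)
  }
  w <- check_weights(weights, n)
  p <- ncol(X); q <- ncol(Z)
  empty_levels <- setdiff(1:5, unique(y))
  if (length(empty_levels)) {
    warning("outcome level(s) ", paste(empty_levels, collapse = ", "),
            " unobserved: the adjacent threshold region is not identified",
            call. = FALSE)
  }

  opt <- maximize_loglik(X, Z, y, w,
                         start = if (is.null(start)) start_values(y, w, p, q)
                                 else start,
                         control = control)

  # null model: intercept-only ordered probit on the same outcome/weights
  if (p == 0 && q == 0) {
    loglik_null <- opt$loglik
  } else {
    null_opt <- maximize_loglik(matrix(0, n, 0), matrix(0, n, 0), y, w,
                                start = start_values(y, w, 0, 0),
                                control = control)
    loglik_null <- null_opt$loglik
  }

  vc <- fit_vcov(opt, X, Z, y, w, vcov_type)
  nm <- param_names(colnames(X), colnames(Z))
  coefs <- stats::setNames(opt$par, nm)
  dimnames(vc) <- list(nm, nm)
  th <- unpack_params(opt$par, p, q)
  names(th$beta) <- colnames(X)
  rownames(th$gamma) <- colnames(Z)

  structure(list(
    coefficients = coefs,
    params = hopit_params(th$beta, th$lambda, th$gamma),
    vcov = vc,
    loglik = opt$loglik,
    loglik_null = loglik_null,
    n_obs = n,
    sum_weights = sum(w),
    npar = p + 4 + 4 * q,
    converged = opt$converged,
    grad_norm = opt$grad_norm,
    iterations = opt$iterations,
    empty_levels = empty_levels,
    dimension = dimension,
    vcov_type = vcov_type,
    group_block = if (inherits(threshold, "threshold_design"))
      threshold$group_block else character(),
    latent_columns = if (inherits(latent, "latent_design"))
      latent$columns else NULL,
    data = if (keep_data) list(X = X, Z = Z, y = y, w = w) else NULL,
    call = match.call()
  ), class = "hopit")
}

maximize_loglik <- function(X, Z, y, w, start, control) {
  nll <- function(par) -loglik_and_score(par, X, Z, y, w,
                                         want_score = FALSE)$loglik
  ngr <- function(par) -loglik_and_score(par, X, Z, y, w)$score

  opt <- stats::optim(start, nll, ngr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  par <- opt$par
  f <- opt$value
  iters <- opt$counts[["function"]]

  # Newton polish: BFGS stalls well above the gradient tolerance on large
  # weighted samples; a few damped Newton steps close the gap quadratically.
  for (it in seq_len(control$newton_maxit)) {
    g <- ngr(par)
    if (max(abs(g)) < control$grad_tol) break
    H <- stats::optimHess(par, nll, ngr)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-8 * max(abs(diag(H)), 1)
      step <- tryCatch(solve(H + diag(ridge, nrow(H)), g),
                       error = function(e) NULL)
      if (is.null(step)) break
    }
    damp <- 1
    improved <- FALSE
    for (k in 1:30) {
      cand <- par - damp * step
      fc <- nll(cand)
      if (is.finite(fc) && fc <= f + 1e-12 * abs(f)) {
        par <- cand; f <- fc; improved <- TRUE; break
      }
      damp <- damp / 2
    }
    iters <- iters + 1L
    if (!improved) break
  }
  g <- ngr(par)
  grad_norm <- max(abs(g))
  list(par = par, loglik = -f, grad_norm = grad_norm,
       converged = grad_norm < control$grad_tol, iterations = iters,
       nll = nll, ngr = ngr)
}

fit_vcov <- function(opt, X, Z, y, w, vcov_type) {
  H <- stats::optimHess(opt$par, opt$nll, opt$ngr)
  H <- (H + t(H)) / 2
  Ainv <- tryCatch(chol2inv(chol(H)), error = function(e) {
    ridge <- 1e-8 * max(abs(diag(H)), 1)
    solve(H + diag(ridge, nrow(H)))
  })
  if (vcov_type == "observed") return((Ainv + t(Ainv)) / 2)
  S <- loglik_and_score(opt$par, X, Z, y, w, by_row = TRUE)$score_matrix
  B <- crossprod(S)
  V <- Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}
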
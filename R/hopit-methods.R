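# S3 methods for fitted "hopit" models.

#' @export
print.hopit <- function(x, ...) {
  cat("Survey-weighted hierarchical ordered probit",
      if (!is.null(x$dimension)) paste0("(", x$dimension, ")"), "\n")
  cat(sprintf("  n = %d, sum of weights = %.1f, parameters = %d\n",
              x$n_obs, x$sum_weights, x$npar))
  cat(sprintf("  log-likelihood = %.4f (null %.4f)\n",
              x$loglik, x$loglik_null))
  cat(sprintf("  converged: %s (max |score| = %.2e)\n",
              x$converged, x$grad_norm))
  invisible(x)
}

#' @export
coef.hopit <- function(object, ...) object$coefficients

#' @export
vcov.hopit <- function(object, ...) object$vcov

#' @export
logLik.hopit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n_obs,
            class = "logLik")
}

#' @export
nobs.hopit <- function(object, ...) object$n_obs

#' @export
summary.hopit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 loglik_null = object$loglik_null, n_obs = object$n_obs,
                 npar = object$npar, converged = object$converged,
                 dimension = object$dimension),
            class = "summary.hopit")
}

#' @export
print.summary.hopit <- function(x, digits = 4, ...) {
  cat("Survey-weighted hierarchical ordered probit",
      if (!is.null(x$dimension)) paste0("(", x$dimension, ")"), "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nlog-likelihood %.3f (null %.3f), AIC %.3f, n = %d\n",
              x$loglik, x$loglik_null, 2 * x$npar - 2 * x$loglik, x$n_obs))
  invisible(x)
}

require_data <- function(object, what) {
  if (is.null(object$data)) {
    stop(what, " needs the fitted designs; refit with keep_data = TRUE ",
         "or pass designs explicitly", call. = FALSE)
  }
  object$data
}

#' Predictions from a fitted HOPIT model
#'
#' @param object a fitted `"hopit"` model.
#' @param latent,threshold optional new designs; defaults to the training
#'   designs stored in the fit.
#' @param type `"class"` for the modal predicted level (ties broken toward
#'   the less severe level), `"probs"` for the n x 5 category probability
#'   matrix, `"index"` for the deterministic latent index beta'x, or
#'   `"thresholds"` for the n x 4 threshold matrix.
#' @param ... unused.
#' @export
predict.hopit <- function(object, latent = NULL, threshold = NULL,
                          type = c("class", "probs", "index", "thresholds"),
                          ...) {
  type <- match.arg(type)
  if (is.null(latent) || is.null(threshold)) {
    d <- require_data(object, "predict()")
    if (is.null(latent)) latent <- d$X
    if (is.null(threshold)) threshold <- d$Z
  }
  X <- as_design_matrix(latent, "x")
  Z <- as_design_matrix(threshold, "z")
  switch(type,
    index = latent_index(object, X),
    thresholds = hopit_thresholds(object, Z),
    probs = category_probs(object$params, X, Z),
    class = {
      P <- category_probs(object$params, X, Z)
      max.col(P, ties.method = "first")
    }
  )
}

#' Generalized residuals of a fitted HOPIT model
#'
#' Returns E\[e_i | y_i\] under the fitted model, the standard generalized
#' residual for probit-type models:
#' (phi(a_lower) - phi(a_upper)) / (Phi(a_upper) - Phi(a_lower)) with
#' a = tau - beta'x at the observed level's bounding thresholds.
#'
#' @param object a fitted `"hopit"` model.
#' @param ... unused.
#' @export
residuals.hopit <- function(object, ...) {
  d <- require_data(object, "residuals()")
  params <- object$params
  eta <- latent_index(params, d$X)
  tau <- compute_tau(params$lambda, params$gamma, d$Z)$tau
  idx <- seq_along(d$y)
  au <- ifelse(d$y == 5L, Inf, tau[cbind(idx, pmin(d$y, 4L))] - eta)
  al <- ifelse(d$y == 1L, -Inf, tau[cbind(idx, pmax(d$y - 1L, 1L))] - eta)
  pr <- pmax(stats::pnorm(au) - stats::pnorm(al), 1e-300)
  (ifelse(is.finite(al), stats::dnorm(al), 0) -
     ifelse(is.finite(au), stats::dnorm(au), 0)) / pr
}

#' Simulate reported levels from a fitted HOPIT model
#'
#' Draws new latent indices beta'x + N(0,1) and classifies them against the
#' fitted per-row thresholds.
#'
#' @param object a fitted `"hopit"` model.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated levels.
#' @export
simulate.hopit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- require_data(object, "simulate()")
  if (!is.null(seed)) set.seed(seed)
  params <- object$params
  eta <- latent_index(params, d$X)
  tau <- compute_tau(params$lambda, params$gamma, d$Z)$tau
  out <- replicate(nsim, {
    h <- eta + stats::rnorm(length(eta))
    1L + rowSums(h >= tau)
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot standardized latent-health coefficients
#'
#' Horizontal bar chart of the main-effect coefficients after rescaling the
#' fitted latent index to span \[0, 1\] (see
#' [standardize_coefficients()]).
#'
#' @param x a fitted `"hopit"` model.
#' @param main_effects_only drop interaction columns from the display.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.hopit <- function(x, main_effects_only = TRUE, ...) {
  sb <- standardize_coefficients(x)
  if (main_effects_only && !is.null(x$latent_columns)) {
    keep <- x$latent_columns$kind %in% c("main", "limitation")
    sb <- sb[keep]
  }
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(sb), horiz = TRUE, las = 1,
                    xlab = "standardized coefficient",
                    main = if (!is.null(x$dimension)) x$dimension else "",
                    ...)
  invisible(x)
}

#' Serialize a fitted HOPIT model to JSON
#'
#' Writes parameter names, estimates, covariance, log-likelihoods and fit
#' metadata in a structured text form suitable for archiving a run.
#'
#' @param fit a fitted `"hopit"` model.
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
hopit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hopit"))
  payload <- list(
    dimension = fit$dimension,
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov,
    loglik = fit$loglik,
    loglik_null = fit$loglik_null,
    n_obs = fit$n_obs,
    sum_weights = fit$sum_weights,
    converged = fit$converged,
    vcov_type = fit$vcov_type,
    group_block = fit$group_block
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
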
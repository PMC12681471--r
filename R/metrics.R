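# Reporting surface for a fitted model: standardized latent-health
# coefficients and the fit battery (log-likelihood, AIC, likelihood-ratio
# index, count R-squared).

#' Standardized latent-health coefficients
#'
#' Rescales the latent-equation coefficients by the range of the fitted
#' latent index over the observed sample, so that after the affine map the
#' worst observed latent health equals 1 and the best equals 0. Sign and
#' ordering of the coefficients are preserved.
#'
#' @param fit a fitted `"hopit"` model (with stored designs) .
#' @param latent optional design overriding the stored one.
#' @return Named numeric vector of rescaled coefficients.
#' @export
standardize_coefficients <- function(fit, latent = NULL) {
  stopifnot(inherits(fit, "hopit"))
  X <- if (is.null(latent)) require_data(fit, "standardize_coefficients()")$X
       else as_design_matrix(latent, "x")
  h <- latent_index(fit, X)
  rng <- max(h) - min(h)
  if (rng <= 0) {
    stop("fitted latent index is degenerate (max equals min); ",
         "coefficients cannot be standardized", call. = FALSE)
  }
  beta <- fit$params$beta
  names(beta) <- colnames(X)
  beta / rng
}

#' Likelihood-ratio (pseudo R-squared) index
#'
#' McFadden's index 1 - lnL_model / lnL_null by default, which lies in
#' \[0, 1) whenever the fitted model improves on the intercept-only ordered
#' probit. The `"as_worded"` variant computes 1 - lnL_null / lnL_model
#' instead; for negative log-likelihoods it is non-positive and is provided
#' for completeness only.
#'
#' @param fit a fitted `"hopit"` model.
#' @param type `"mcfadden"` (default) or `"as_worded"`.
#' @export
likelihood_ratio_index <- function(fit, type = c("mcfadden", "as_worded")) {
  stopifnot(inherits(fit, "hopit"))
  type <- match.arg(type)
  if (fit$loglik_null == 0) {
    stop("null log-likelihood is zero; index undefined", call. = FALSE)
  }
  if (type == "mcfadden") 1 - fit$loglik / fit$loglik_null
  else {
    if (fit$loglik == 0) stop("model log-likelihood is zero", call. = FALSE)
    1 - fit$loglik_null / fit$loglik
  }
}

#' Count R-squared: weighted proportion of levels correctly classified
#'
#' Each respondent's predicted level is the mode of the fitted category
#' distribution (ties broken toward the less severe level); the statistic is
#' the weighted share of respondents whose predicted level equals the
#' observed one.
#'
#' @param fit a fitted `"hopit"` model.
#' @param latent,threshold,outcome,weights optional data overriding the
#'   stored fit data.
#' @export
count_r2 <- function(fit, latent = NULL, threshold = NULL, outcome = NULL,
                     weights = NULL) {
  stopifnot(inherits(fit, "hopit"))
  if (is.null(latent) || is.null(threshold) || is.null(outcome)) {
    d <- require_data(fit, "count_r2()")
    latent <- if (is.null(latent)) d$X else latent
    threshold <- if (is.null(threshold)) d$Z else threshold
    outcome <- if (is.null(outcome)) d$y else outcome
    if (is.null(weights)) weights <- d$w
  }
  X <- as_design_matrix(latent, "x")
  Z <- as_design_matrix(threshold, "z")
  y <- check_outcome(outcome)
  w <- check_weights(weights, length(y))
  P <- category_probs(fit$params, X, Z)
  pred <- max.col(P, ties.method = "first")
  sum(w * (pred == y)) / sum(w)
}

#' Akaike information criterion of a fitted HOPIT model
#'
#' 2k - 2 lnL with k the number of free parameters (latent coefficients plus
#' 4 threshold intercepts plus 4 threshold-coefficient vectors). Identical
#' to `AIC(fit)` via the `logLik` method; exported so the fit report can be
#' assembled without the generic.
#'
#' @param fit a fitted `"hopit"` model.
#' @export
hopit_aic <- function(fit) {
  stopifnot(inherits(fit, "hopit"))
  2 * fit$npar - 2 * fit$loglik
}

#' Assemble the per-dimension fit report
#'
#' Standardized coefficients plus the fit battery for one fitted model.
#'
#' @param fit a fitted `"hopit"` model with stored designs.
#' @return A list of class `"hopit_fit_report"` with `standardized_beta`,
#'   `loglik`, `aic`, `lr_index`, `count_r2` and the dimension label.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "hopit"))
  structure(list(
    dimension = fit$dimension,
    standardized_beta = standardize_coefficients(fit),
    loglik = fit$loglik,
    aic = hopit_aic(fit),
    lr_index = likelihood_ratio_index(fit),
    count_r2 = count_r2(fit)
  ), class = "hopit_fit_report")
}

#' @export
print.hopit_fit_report <- function(x, digits = 3, ...) {
  cat("Fit report", if (!is.null(x$dimension)) paste0("(", x$dimension, ")"),
      "\n")
  cat(sprintf("  log-likelihood %.3f | AIC %.3f | LR index %.3f | Count R2 %.3f\n",
              x$loglik, x$aic, x$lr_index, x$count_r2))
  cat("  standardized coefficients:\n")
  print(round(x$standardized_beta, digits))
  invisible(x)
}

#' Coefficient-and-fit table across dimensions
#'
#' Binds fit reports for several dimensions into one table shaped like a
#' published coefficient table: one row per latent-equation column, one
#' column per dimension, with the fit statistics appended as extra rows.
#'
#' @param reports a named list of [fit_report()] results (names = dimension
#'   labels) or fitted `"hopit"` models.
#' @return A data frame (row names = coefficient / statistic names).
#' @export
report_table <- function(reports) {
  reports <- lapply(reports, function(r) {
    if (inherits(r, "hopit")) fit_report(r) else r
  })
  all_cf <- unique(unlist(lapply(reports, function(r)
    names(r$standardized_beta))))
  cols <- lapply(reports, function(r) {
    v <- r$standardized_beta[all_cf]
    c(v, `Log-likelihood` = r$loglik, AIC = r$aic,
      `Likelihood ratio index` = r$lr_index, `Count R2` = r$count_r2)
  })
  out <- as.data.frame(cols, optional = TRUE, check.names = FALSE)
  rownames(out) <- c(all_cf, "Log-likelihood", "AIC",
                     "Likelihood ratio index", "Count R2")
  out
}
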
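# Threshold contrasts between a focal group and the baseline at
# sample-proportion covariate profiles, with parametric-bootstrap CIs.
#
# The baseline profile z0 sets every reporting covariate to its (weighted)
# sample proportion and every contrast-family dummy to 0; z1 flips exactly
# one group dummy to 1. The contrast is
#   d_1 = gamma_1'(z1 - z0)
#   d_j = d_{j-1} + exp(lambda_j + gamma_j'z1) - exp(lambda_j + gamma_j'z0)
# for j = 2..4, i.e. the elementwise difference of the two threshold sets.
# A positive value means the focal group rates the same latent health less
# severely than the baseline.

#' Build baseline/focal covariate profiles for threshold contrasts
#'
#' @param threshold a `"threshold_design"` with a non-empty group block.
#' @param weights survey weights used for the sample-proportion profile
#'   (default all 1).
#' @param weighted use weighted column means (default) or raw proportions.
#' @return A list of `"contrast_profile"` objects, one per group dummy; each
#'   holds `z0`, `z1` and the group label.
#' @export
build_profiles <- function(threshold, weights = NULL, weighted = TRUE) {
  stopifnot(inherits(threshold, "threshold_design"))
  Z <- threshold$matrix
  gb <- threshold$group_block
  if (!length(gb)) {
    stop("threshold design has an empty contrast-family group block",
         call. = FALSE)
  }
  w <- check_weights(weights, nrow(Z))
  if (!weighted) w <- rep(1, nrow(Z))
  z0 <- drop(crossprod(Z, w)) / sum(w)
  names(z0) <- colnames(Z)
  z0[gb] <- 0
  lapply(gb, function(g) {
    z1 <- z0
    z1[g] <- 1
    structure(list(z0 = z0, z1 = z1, group = g),
              class = "contrast_profile")
  })
}

delta_from_linear <- function(a0, a1) {
  # a0, a1: draws x 4 matrices of lambda_j + gamma_j'z at the two profiles.
  # Exponent arguments are clipped exactly as in the threshold function, so
  # the contrast of two clipped threshold sets stays finite for wild
  # bootstrap draws in weakly identified directions.
  d <- matrix(0, nrow(a0), 4)
  d[, 1] <- a1[, 1] - a0[, 1]
  for (j in 2:4) {
    d[, j] <- d[, j - 1] +
      exp(pmin(pmax(a1[, j], -EXP_CLIP), EXP_CLIP)) -
      exp(pmin(pmax(a0[, j], -EXP_CLIP), EXP_CLIP))
  }
  colnames(d) <- boundary_labels()
  d
}

boundary_labels <- function() c("1|2", "2|3", "3|4", "4|5")

#' Threshold difference between a focal group and the baseline
#'
#' @param params a `"hopit_params"` object or fitted `"hopit"` model.
#' @param profile a `"contrast_profile"` from [build_profiles()].
#' @return Named numeric vector of the four threshold differences
#'   (boundaries 1|2 .. 4|5).
#' @export
delta_tau <- function(params, profile) {
  params <- get_params(params)
  stopifnot(inherits(profile, "contrast_profile"))
  if (length(profile$z0) != nrow(params$gamma)) {
    stop("profile length does not conform to gamma", call. = FALSE)
  }
  a0 <- matrix(params$lambda + drop(crossprod(params$gamma, profile$z0)),
               1, 4)
  a1 <- matrix(params$lambda + drop(crossprod(params$gamma, profile$z1)),
               1, 4)
  stats::setNames(drop(delta_from_linear(a0, a1)), boundary_labels())
}

#' Parametric-bootstrap threshold contrasts
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' estimates with the estimated covariance, recomputes the threshold
#' differences per draw, and forms 95% intervals by both the percentile
#' method and the bootstrap standard error (point estimate +/- 1.96 SE at
#' the default level). A contrast is flagged significant only when both
#' interval types exclude zero.
#'
#' @param fit a fitted `"hopit"` model (with `keep_data = TRUE`, or supply
#'   `profiles`).
#' @param profiles optional list from [build_profiles()]; by default rebuilt
#'   from the stored threshold design and weights.
#' @param n_draws number of coefficient draws (>= 2; percentile intervals
#'   are refused below 40 draws).
#' @param seed integer seed making the draws reproducible.
#' @param level confidence level (default 0.95).
#' @param weighted weighted sample proportions for the default profiles.
#' @return An object of class `"hopit_contrasts"`: one element per group
#'   with the point estimates `delta`, bootstrap `se`, `ci_percentile`,
#'   `ci_se` and `significant` flags.
#' @export
threshold_contrasts <- function(fit, profiles = NULL, n_draws = 1000,
                                seed = NULL, level = 0.95, weighted = TRUE) {
  stopifnot(inherits(fit, "hopit"))
  if (n_draws < 2) stop("n_draws must be at least 2", call. = FALSE)
  if (is.null(profiles)) {
    d <- require_data(fit, "threshold_contrasts()")
    td <- structure(list(matrix = d$Z, group_block = fit$group_block),
                    class = "threshold_design")
    profiles <- build_profiles(td, d$w, weighted = weighted)
  }
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  p <- length(fit$params$beta)
  q <- nrow(fit$params$gamma)
  draws <- draw_mvn(n_draws, fit$coefficients, fit$vcov)
  lam_idx <- p + 1:4
  gam_idx <- lapply(1:4, function(j) p + 4 + (j - 1) * q + seq_len(q))

  percentile_ok <- n_draws >= 40
  if (!percentile_ok) {
    warning("percentile intervals need at least 40 draws; reporting the ",
            "SE-method interval only", call. = FALSE)
  }
  alpha <- 1 - level
  zq <- stats::qnorm(1 - alpha / 2)

  out <- lapply(profiles, function(pr) {
    point <- delta_tau(fit$params, pr)
    lin <- function(z) {
      a <- draws[, lam_idx, drop = FALSE]
      if (q) for (j in 1:4) {
        a[, j] <- a[, j] + drop(draws[, gam_idx[[j]], drop = FALSE] %*% z)
      }
      a
    }
    dmat <- delta_from_linear(lin(pr$z0), lin(pr$z1))
    se <- apply(dmat, 2, stats::sd)
    ci_se <- cbind(lower = point - zq * se, upper = point + zq * se)
    ci_pct <- if (percentile_ok) {
      t(apply(dmat, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE))
    } else {
      matrix(NA_real_, 4, 2)
    }
    dimnames(ci_pct) <- list(boundary_labels(), c("lower", "upper"))
    sig_se <- ci_se[, 1] > 0 | ci_se[, 2] < 0
    sig_pct <- if (percentile_ok) ci_pct[, 1] > 0 | ci_pct[, 2] < 0
               else rep(NA, 4)
    structure(list(
      group = pr$group, delta = point, se = se,
      ci_percentile = ci_pct, ci_se = ci_se,
      significant = if (percentile_ok) sig_se & sig_pct else sig_se,
      n_draws = n_draws, seed = seed
    ), class = "threshold_contrast")
  })
  names(out) <- vapply(profiles, `[[`, "", "group")
  structure(out, class = "hopit_contrasts", level = level,
            dimension = fit$dimension)
}

#' @export
print.hopit_contrasts <- function(x, digits = 3, ...) {
  dim_lab <- attr(x, "dimension")
  cat("Threshold contrasts vs baseline",
      if (!is.null(dim_lab)) paste0("(", dim_lab, ")"), "\n")
  for (ct in x) {
    cells <- sprintf(paste0("%.", digits, "f%s (%.", digits, "f)"),
                     ct$delta, ifelse(isTRUE(ct$significant) |
                                        ct$significant %in% TRUE, "*", " "),
                     ct$se)
    cat(sprintf("  %-12s %s\n", ct$group, paste(cells, collapse = "  ")))
  }
  cat("  boundaries:", paste(boundary_labels(), collapse = "  "),
      " (* both CI methods exclude 0)\n")
  invisible(x)
}

#' Long-format contrast table for faceted bubble plots
#'
#' Flattens one or more sets of contrasts (one per EQ-5D-5L dimension) into
#' a plot-ready table: one row per dimension x group x threshold boundary,
#' with the threshold difference, its bootstrap SE, both interval types, the
#' sign and the joint significance flag.
#'
#' @param contrasts a `"hopit_contrasts"` object or a named list of them
#'   (names = dimension labels).
#' @return A data frame with columns `dimension`, `group`, `boundary`,
#'   `delta`, `se`, `pct_lower`, `pct_upper`, `se_lower`, `se_upper`,
#'   `sign`, `significant`.
#' @export
export_bubble_table <- function(contrasts) {
  if (inherits(contrasts, "hopit_contrasts")) {
    nm <- attr(contrasts, "dimension")
    contrasts <- stats::setNames(list(contrasts),
                                 if (is.null(nm)) "outcome" else nm)
  }
  rows <- list()
  for (dim_lab in names(contrasts)) {
    for (ct in contrasts[[dim_lab]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dim_lab, group = ct$group,
        boundary = boundary_labels(),
        delta = unname(ct$delta), se = unname(ct$se),
        pct_lower = ct$ci_percentile[, 1],
        pct_upper = ct$ci_percentile[, 2],
        se_lower = unname(ct$ci_se[, 1]),
        se_upper = unname(ct$ci_se[, 2]),
        sign = ifelse(ct$delta > 0, "positive",
                      ifelse(ct$delta < 0, "negative", "zero")),
        significant = unname(ct$significant),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(dimension = character(), group = character(),
                      boundary = character(), delta = numeric(),
                      se = numeric(), pct_lower = numeric(),
                      pct_upper = numeric(), se_lower = numeric(),
                      se_upper = numeric(), sign = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Bubble plot of threshold contrasts
#'
#' Base-graphics rendering of the contrast grid: bubble area proportional to
#' |threshold difference|, filled by sign, solid border where both CI
#' methods exclude zero.
#'
#' @param x a `"hopit_contrasts"` object.
#' @param ... unused.
#' @export
plot.hopit_contrasts <- function(x, ...) {
  tab <- export_bubble_table(x)
  groups <- unique(tab$group)
  bnd <- boundary_labels()
  gx <- match(tab$boundary, bnd)
  gy <- match(tab$group, groups)
  graphics::plot(gx, gy, type = "n", xaxt = "n", yaxt = "n",
                 xlab = "threshold boundary", ylab = "",
                 xlim = c(0.5, 4.5), ylim = c(0.5, length(groups) + 0.5),
                 main = attr(x, "dimension"))
  graphics::axis(1, at = 1:4, labels = bnd)
  graphics::axis(2, at = seq_along(groups), labels = groups, las = 1)
  scale <- 4 / max(abs(tab$delta), 1e-9)
  graphics::symbols(gx, gy, circles = sqrt(abs(tab$delta) * scale) / 6,
                    inches = FALSE, add = TRUE,
                    bg = ifelse(tab$delta >= 0, "#d73027", "#4575b4"),
                    fg = ifelse(tab$significant %in% TRUE, "black", NA))
  invisible(x)
}
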
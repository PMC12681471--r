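#' @keywords internal
"_PACKAGE"

# Validation helpers shared across the package. All errors name the offending
# column so schema problems in survey extracts are actionable.

check_binary <- function(x, name) {
  if (is.logical(x)) x <- as.integer(x)
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1))) {
    stop("column '", name, "' must be binary 0/1 with no missing values",
         call. = FALSE)
  }
  as.integer(x)
}

check_binary_matrix <- function(m, what = "conditions") {
  m <- as.matrix(m)
  if (is.null(colnames(m))) {
    stop(what, " matrix must have column names", call. = FALSE)
  }
  for (nm in colnames(m)) m[, nm] <- check_binary(m[, nm], nm)
  storage.mode(m) <- "double"
  m
}

check_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  if (!is.numeric(w) || length(w) != n || anyNA(w) || any(w < 0)) {
    stop("weights must be non-negative, non-missing and conform to rows",
         call. = FALSE)
  }
  if (sum(w) <= 0) stop("weights must have positive sum", call. = FALSE)
  as.numeric(w)
}

check_outcome <- function(y) {
  if (is.factor(y)) y <- as.integer(y)
  if (!is.numeric(y) || anyNA(y) || !all(y %in% 1:5)) {
    stop("outcome levels must be integers in 1..5", call. = FALSE)
  }
  as.integer(y)
}

# One-hot validation for a declared dummy family: every row has exactly one
# level set. Rows failing validation are rejected, not recoded.
check_one_hot <- function(m, family) {
  rs <- rowSums(m)
  bad <- which(rs != 1)
  if (length(bad)) {
    stop("family '", family, "' is not one-hot: row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "",
         " have ", paste(unique(rs[utils::head(bad, 5)]), collapse = "/"),
         " levels set", call. = FALSE)
  }
  invisible(TRUE)
}

# Multivariate-normal draws with a symmetrized covariance and an eigenvalue
# floor at zero, so mild numerical asymmetry in an observed-information
# matrix never aborts a bootstrap.
draw_mvn <- function(n, mean, sigma) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1)) {
    stop("covariance matrix is not positive semi-definite; refit with ",
         "vcov_type = \"sandwich\"", call. = FALSE)
  }
  lam <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  z <- matrix(stats::rnorm(n * length(mean)), n, length(mean))
  sweep(z %*% rt, 2, mean, "+")
}
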
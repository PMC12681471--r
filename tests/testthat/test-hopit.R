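test_that("latent index is the linear predictor beta'x", {
  x <- rbind(c(1, 0, 1), c(0, 1, 1))
  colnames(x) <- c("a", "b", "c")
  p0 <- hopit_params(c(0, 0, 0), c(0, 0, 0, 0), matrix(0, 0, 4))
  expect_equal(latent_index(p0, x), c(0, 0))
  p1 <- hopit_params(c(0.2, 0.5, 0.3), c(0, 0, 0, 0), matrix(0, 0, 4))
  expect_equal(latent_index(p1, x)[1], 0.5)
  p2 <- hopit_params(2 * c(0.2, 0.5, 0.3), c(0, 0, 0, 0), matrix(0, 0, 4))
  expect_equal(latent_index(p2, x), 2 * latent_index(p1, x))
  expect_error(latent_index(p1, x[, 1:2]), "columns")
})

test_that("thresholds follow the linear-plus-exponential recursion", {
  z <- matrix(0, 3, 0)
  p0 <- hopit_params(numeric(0), c(0, 0, 0, 0))
  expect_equal(unname(hopit_thresholds(p0, z)[1, ]), c(0, 1, 2, 3))

  p1 <- hopit_params(numeric(0), c(0.2, -0.1, 0.3, 0))
  tau <- hopit_thresholds(p1, z)[1, ]
  # direct evaluation: 0.2; +exp(-0.1); +exp(0.3); +exp(0)
  expect_equal(unname(tau),
               c(0.2, 1.10483742, 2.45469623, 3.45469623),
               tolerance = 1e-8)

  expect_error(hopit_params(numeric(0), c(0, NA, 0, 0)), "finite")
})

test_that("thresholds are strictly ordered for any parameters (coherence)", {
  set.seed(101)
  for (rep in 1:1000) {
    q <- sample(0:4, 1)
    z <- matrix(rbinom(5 * q, 1, 0.5), 5, q)
    if (q) colnames(z) <- paste0("z", seq_len(q))
    pr <- hopit_params(numeric(0),
                       rnorm(4, 0, 2),
                       matrix(rnorm(4 * q, 0, 2), q, 4))
    tau <- hopit_thresholds(pr, z)
    expect_true(all(tau[, 1] < tau[, 2] & tau[, 2] < tau[, 3] &
                      tau[, 3] < tau[, 4]))
  }
})

test_that("log-likelihood matches closed-form normal probabilities", {
  x <- matrix(0, 1, 0)
  z <- matrix(0, 1, 0)
  pr <- hopit_params(numeric(0), c(0, 0, 0, 0))  # tau = (0, 1, 2, 3)
  expect_equal(hopit_loglik(pr, x, z, 1, 1), log(0.5))
  expect_equal(hopit_loglik(pr, x, z, 5, 1), log(1 - pnorm(3)))
  expect_equal(hopit_loglik(pr, x, z, 5, 1), -6.60772622,
               tolerance = 1e-7)
  expect_equal(hopit_loglik(pr, x, z, 3, 1), log(pnorm(2) - pnorm(1)))
  expect_error(hopit_loglik(pr, x, z, 6, 1), "1..5")
  expect_error(hopit_loglik(pr, x, z, 1, 0), "sum")
})

test_that("weighted likelihood semantics: duplication equals weight two", {
  set.seed(7)
  n <- 60
  X <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3))
  Z <- cbind(g = rbinom(n, 1, 0.2))
  y <- sample(1:5, n, replace = TRUE)
  pr <- random_params(2, 1)

  i <- 13
  ll_dup <- hopit_loglik(pr, rbind(X, X[i, , drop = FALSE]),
                         rbind(Z, Z[i, , drop = FALSE]),
                         c(y, y[i]), rep(1, n + 1))
  w2 <- rep(1, n); w2[i] <- 2
  expect_identical(ll_dup, hopit_loglik(pr, X, Z, y, w2))

  # uniform rescaling multiplies the log-likelihood by the constant
  w <- runif(n, 0.5, 2)
  expect_equal(hopit_loglik(pr, X, Z, y, 3.7 * w),
               3.7 * hopit_loglik(pr, X, Z, y, w))
})

test_that("per-row category probabilities form a proper distribution", {
  set.seed(8)
  n <- 50
  X <- cbind(a = rbinom(n, 1, 0.5))
  Z <- cbind(g = rbinom(n, 1, 0.3), h = rbinom(n, 1, 0.6))
  for (rep in 1:10) {
    pr <- random_params(1, 2)
    P <- reportshift:::category_probs(pr, X, Z)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
  }
})

test_that("analytic score matches central finite differences", {
  set.seed(9)
  n <- 200
  X <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.25),
             c = rbinom(n, 1, 0.1))
  Z <- cbind(g1 = rbinom(n, 1, 0.2), g2 = rbinom(n, 1, 0.5))
  y <- sample(1:5, n, replace = TRUE,
              prob = c(0.5, 0.25, 0.12, 0.08, 0.05))
  w <- runif(n, 0.3, 2.5)
  for (rep in 1:10) {
    pr <- random_params(3, 2)
    g <- hopit_score(pr, X, Z, y, w)
    fd <- fd_score(reportshift:::pack_params(pr), X, Z, y, w)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-4)), 1e-6)
  }
})

test_that("score is exactly zero for an all-zero threshold covariate", {
  set.seed(10)
  n <- 80
  X <- cbind(a = rbinom(n, 1, 0.4))
  Z <- cbind(g = rbinom(n, 1, 0.3), dead = rep(0, n))
  y <- sample(1:5, n, replace = TRUE)
  pr <- random_params(1, 2)
  g <- hopit_score(pr, X, Z, y, NULL)
  expect_identical(unname(g[grepl("dead", names(g))]), rep(0, 4))
})

test_that("with no threshold covariates the MLE matches the polr oracle", {
  skip_if_not_installed("MASS")
  set.seed(11)
  n <- 2000
  x <- cbind(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.45))
  h <- drop(x %*% c(0.5, 0.8)) + rnorm(n)
  tau <- c(0.4, 1.1, 1.8, 2.6)
  y <- 1L + rowSums(outer(h, tau, ">="))
  fit <- hopit(y, x)
  pol <- MASS::polr(factor(y, levels = 1:5) ~ a + b,
                    data = as.data.frame(x), method = "probit")
  expect_lt(max(abs(fit$params$beta - coef(pol))), 1e-3)
  tau_hat <- drop(hopit_thresholds(fit, n = 1))
  expect_lt(max(abs(tau_hat - pol$zeta)), 1e-3)
  expect_lt(abs(fit$loglik - as.numeric(logLik(pol))), 1e-4)
  # gradient at the optimum satisfies the first-order condition
  expect_lt(fit$grad_norm, 1e-5)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("fitting is deterministic and invariant to weight rescaling", {
  set.seed(12)
  cfg <- compact_config(n = 3000, seed = 21)
  tab <- synth_generate(cfg)
  des <- build_designs(tab, screen = FALSE)
  y <- tab$mobility
  ctl <- hopit_control(grad_tol = 1e-8)
  f1 <- hopit(y, des$latent, des$threshold, weights = des$weights,
              control = ctl)
  f2 <- hopit(y, des$latent, des$threshold, weights = des$weights,
              control = ctl)
  expect_identical(f1$coefficients, f2$coefficients)

  f3 <- hopit(y, des$latent, des$threshold, weights = 5.5 * des$weights,
              control = ctl)
  expect_lt(max(abs(f3$coefficients - f1$coefficients)), 1e-8)
  expect_equal(f3$loglik, 5.5 * f1$loglik, tolerance = 1e-10)
})

test_that("empty outcome levels are flagged and the fit proceeds", {
  set.seed(13)
  n <- 300
  x <- cbind(a = rbinom(n, 1, 0.3))
  y <- sample(1:3, n, replace = TRUE)  # levels 4 and 5 unobserved
  expect_warning(fit <- hopit(y, x), "unobserved")
  expect_equal(fit$empty_levels, c(4L, 5L))
  expect_true(is.finite(fit$loglik))
})

test_that("sandwich and observed-information covariances are symmetric PSD", {
  set.seed(14)
  tab <- synth_generate(compact_config(n = 1500, seed = 31))
  des <- build_designs(tab, screen = FALSE)
  for (vt in c("observed", "sandwich")) {
    fit <- hopit(tab$mobility, des$latent, des$threshold,
                 weights = des$weights, vcov_type = vt)
    V <- vcov(fit)
    expect_equal(V, t(V))
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(V)))
  }
})

test_that("model object methods are coherent", {
  set.seed(15)
  tab <- synth_generate(compact_config(n = 1200, seed = 41))
  des <- build_designs(tab, screen = FALSE)
  fit <- hopit(tab$mobility, des$latent, des$threshold,
               weights = des$weights, dimension = "mobility")
  expect_s3_class(fit, "hopit")
  expect_equal(length(coef(fit)), fit$npar)
  expect_equal(dim(vcov(fit)), c(fit$npar, fit$npar))
  expect_equal(attr(logLik(fit), "df"), fit$npar)
  expect_equal(AIC(fit), hopit_aic(fit))
  expect_equal(nobs(fit), nrow(tab))

  P <- predict(fit, type = "probs")
  expect_equal(dim(P), c(nrow(tab), 5L))
  cls <- predict(fit, type = "class")
  expect_true(all(cls %in% 1:5))
  expect_equal(cls, max.col(P, ties.method = "first"))

  r <- residuals(fit)
  expect_length(r, nrow(tab))
  # generalized residuals are centred near zero under a correct model
  expect_lt(abs(mean(r)), 0.1)

  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_equal(dim(sims), c(nrow(tab), 2L))
  expect_true(all(unlist(sims) %in% 1:5))
  expect_identical(simulate(fit, nsim = 2, seed = 99), sims)

  js <- hopit_to_json(fit)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$loglik, fit$loglik)
  expect_equal(length(parsed$coefficients), fit$npar)
})
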
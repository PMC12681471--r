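make_fitted_compact <- function(n = 2500, seed = 61) {
  tab <- synth_generate(compact_config(n = n, seed = seed))
  des <- build_designs(tab, screen = FALSE)
  fit <- hopit(tab$mobility, des$latent, des$threshold,
               weights = des$weights, dimension = "mobility")
  list(tab = tab, des = des, fit = fit)
}

test_that("profiles set group dummies to zero and the rest to weighted means", {
  s <- make_fitted_compact()
  td <- s$des$threshold
  profs <- build_profiles(td, s$des$weights)
  expect_length(profs, 4L)  # one per non-baseline group

  w <- s$des$weights
  wm <- drop(crossprod(td$matrix, w)) / sum(w)
  p1 <- profs[[1]]
  non_group <- setdiff(colnames(td$matrix), td$group_block)
  expect_equal(p1$z0[non_group], wm[non_group])
  expect_equal(unname(p1$z0[td$group_block]), rep(0, 4))
  # z1 - z0 is one-hot at the profile's own group
  d <- p1$z1 - p1$z0
  expect_equal(sum(d), 1)
  expect_equal(unname(d[p1$group]), 1)

  # unweighted switch uses raw proportions
  pu <- build_profiles(td, s$des$weights, weighted = FALSE)[[1]]
  expect_equal(pu$z0[non_group], colMeans(td$matrix)[non_group])
})

test_that("delta_tau identities hold", {
  s <- make_fitted_compact()
  profs <- build_profiles(s$des$threshold, s$des$weights)
  pr <- profs[[2]]

  # z1 = z0 gives an identically zero contrast
  same <- pr
  same$z1 <- same$z0
  expect_identical(unname(delta_tau(s$fit, same)), rep(0, 4))

  # zero gamma rows for the group column give zero contrast
  p0 <- s$fit$params
  g0 <- p0$gamma
  g0[pr$group, ] <- 0
  expect_equal(unname(delta_tau(hopit_params(p0$beta, p0$lambda, g0), pr)),
               rep(0, 4), tolerance = 1e-15)

  # equals the difference of the threshold operation at z1 and z0
  set.seed(71)
  q <- nrow(p0$gamma)
  for (rep in 1:25) {
    rp <- random_params(0, q)
    d1 <- delta_tau(rp, pr)
    tt <- hopit_thresholds(rp, rbind(pr$z1, pr$z0))
    expect_equal(unname(d1), unname(tt[1, ] - tt[2, ]), tolerance = 1e-12)
  }
})

test_that("delta_tau_1 ignores covariates shared between the profiles", {
  set.seed(72)
  q <- 5
  rp <- random_params(0, q)
  z0 <- c(0, 0.3, 0.7, 0.1, 0.9)
  names(z0) <- paste0("z", 1:5)
  z1 <- z0; z1[1] <- 1
  pr <- structure(list(z0 = z0, z1 = z1, group = "z1"),
                  class = "contrast_profile")
  d <- delta_tau(rp, pr)
  # first contrast is exactly the group coefficient, whatever the shared part
  expect_equal(unname(d[1]), rp$gamma[1, 1], tolerance = 1e-12)
  z0b <- z0; z0b[2:5] <- runif(4)
  z1b <- z0b; z1b[1] <- 1
  prb <- structure(list(z0 = z0b, z1 = z1b, group = "z1"),
                   class = "contrast_profile")
  expect_equal(unname(delta_tau(rp, prb)[1]), unname(d[1]),
               tolerance = 1e-12)
})

test_that("bootstrap contrasts are seeded, degenerate at zero vcov, and honest about few draws", {
  s <- make_fitted_compact()
  c1 <- threshold_contrasts(s$fit, n_draws = 300, seed = 5)
  c2 <- threshold_contrasts(s$fit, n_draws = 300, seed = 5)
  expect_identical(c1, c2)
  c3 <- threshold_contrasts(s$fit, n_draws = 300, seed = 6)
  expect_false(identical(c1[[1]]$se, c3[[1]]$se))

  # zero covariance: every draw equals the point estimate
  fit0 <- s$fit
  fit0$vcov <- matrix(0, fit0$npar, fit0$npar,
                      dimnames = dimnames(fit0$vcov))
  c0 <- threshold_contrasts(fit0, n_draws = 100, seed = 1)
  expect_equal(unname(c0[[1]]$se), rep(0, 4))
  expect_equal(unname(c0[[1]]$ci_percentile[, 1]),
               unname(c0[[1]]$delta), tolerance = 1e-12)

  expect_error(threshold_contrasts(s$fit, n_draws = 1), "at least 2")
  expect_warning(cf <- threshold_contrasts(s$fit, n_draws = 10, seed = 2),
                 "40 draws")
  expect_true(all(is.na(cf[[1]]$ci_percentile)))
  expect_true(all(is.finite(cf[[1]]$ci_se)))
})

test_that("percentile intervals contain the median draw and widen with level", {
  s <- make_fitted_compact()
  cts <- threshold_contrasts(s$fit, n_draws = 500, seed = 9)
  for (ct in cts) {
    expect_true(all(ct$ci_percentile[, 1] <= ct$delta + 4 * ct$se))
    expect_true(all(ct$ci_percentile[, 1] < ct$ci_percentile[, 2]))
  }
  wide <- threshold_contrasts(s$fit, n_draws = 500, seed = 9, level = 0.99)
  narrow <- threshold_contrasts(s$fit, n_draws = 500, seed = 9,
                                level = 0.80)
  for (g in names(wide)) {
    expect_true(all(wide[[g]]$ci_percentile[, 1] <=
                      narrow[[g]]$ci_percentile[, 1] + 1e-12))
    expect_true(all(wide[[g]]$ci_percentile[, 2] >=
                      narrow[[g]]$ci_percentile[, 2] - 1e-12))
  }
})

test_that("bootstrap SE stabilizes at many draws", {
  s <- make_fitted_compact(n = 1500, seed = 62)
  a <- threshold_contrasts(s$fit, n_draws = 10000, seed = 100)
  b <- threshold_contrasts(s$fit, n_draws = 10000, seed = 200)
  rel <- abs(a[[1]]$se - b[[1]]$se) / a[[1]]$se
  expect_lt(max(rel), 0.05)
})

test_that("bubble export has one row per dimension, group and boundary", {
  s <- make_fitted_compact()
  cts <- threshold_contrasts(s$fit, n_draws = 100, seed = 3)
  fake <- stats::setNames(rep(list(cts), 5),
                          c("mobility", "selfcare", "usualact", "paindisc",
                            "anxdep"))
  tab <- export_bubble_table(fake)
  expect_equal(nrow(tab), 5 * 4 * 4)
  expect_setequal(unique(tab$boundary), c("1|2", "2|3", "3|4", "4|5"))

  empty <- export_bubble_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("dimension", "group", "boundary", "delta", "se",
                    "significant") %in% names(empty)))

  # values survive a write/read round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$delta, tab$delta, tolerance = 1e-12)
  unlink(f)
})
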
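test_that("interaction screen equals brute-force enumeration on the toy table", {
  m <- toy_screen_table()

  for (cut in c(0.01, 0.1, 0.15, 0.3)) {
    got <- screen_interactions(m, min_prevalence = cut)
    # deterministic ordering: pairs then triples, lexicographic within order
    expect_identical(got$name, got$name[order(got$order, got$name)])
    expect_setequal(got$name, brute_force_screen(m, min_prev = cut))
  }

  # weighted screen with mass concentrated off the (a,b) co-occurrences
  w <- ifelse(m[, "a"] * m[, "b"] == 1, 1e-6, 1)
  got_w <- screen_interactions(m, weights = w, min_prevalence = 0.05)
  expect_setequal(got_w$name, brute_force_screen(m, w, min_prev = 0.05))
  expect_false("a:b" %in% got_w$name)
  # unweighted switch ignores the same weights
  got_u <- screen_interactions(m, weights = w, min_prevalence = 0.05,
                               weighted = FALSE)
  expect_setequal(got_u$name, brute_force_screen(m, min_prev = 0.05))
  expect_true("a:b" %in% got_u$name)
})

test_that("interaction screen handles zero joint prevalence and is monotone", {
  m <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(nrow(screen_interactions(m, min_prevalence = 0.01)), 0L)

  m2 <- toy_screen_table()
  cuts <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  sizes <- vapply(cuts,
                  function(cut) nrow(screen_interactions(m2,
                                                         min_prevalence = cut)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  # tiny threshold keeps everything with at least one joint occurrence
  all_occ <- brute_force_screen(m2, min_prev = 1 / (2 * nrow(m2)))
  expect_setequal(screen_interactions(m2, min_prevalence = 1e-9)$name,
                  all_occ)
  # above the max observed joint prevalence the screen is empty
  expect_equal(nrow(screen_interactions(m2, min_prevalence = 0.999)), 0L)
})

test_that("interaction screen is invariant to row order and weight rescaling", {
  m <- toy_screen_table()
  w <- runif(nrow(m), 0.2, 3)
  base <- screen_interactions(m, w, min_prevalence = 0.08)
  perm <- sample(nrow(m))
  expect_equal(screen_interactions(m[perm, ], w[perm],
                                   min_prevalence = 0.08)$name, base$name)
  expect_equal(screen_interactions(m, w * 17.3,
                                   min_prevalence = 0.08)$prevalence,
               base$prevalence)
})

test_that("interaction screen validates its inputs", {
  m <- toy_screen_table()
  bad <- cbind(m, e = seq_len(nrow(m)))
  expect_error(screen_interactions(bad), "'e'")
  expect_error(screen_interactions(m, min_prevalence = 0), "min_prevalence")
  expect_error(screen_interactions(m, min_prevalence = 1), "min_prevalence")
  expect_error(screen_interactions(m, max_order = 4), "max_order")
})

test_that("latent design assembles mains, limitation dummies and products", {
  tab <- synth_generate(synth_config(n = 300, seed = 2))
  mp <- attr(tab, "mapping")
  ld <- build_latent_design(tab, mp$conditions, limitation = "limitation")
  expect_equal(ncol(ld$matrix), 17L)  # 15 mains + 2 limitation dummies
  expect_true(all(ld$matrix %in% c(0, 1)))
  expect_equal(sum(ld$columns$kind == "limitation"), 2L)

  ints <- list(c("arthritis", "asthma"),
               c("arthritis", "asthma", "diabetes"))
  ld2 <- build_latent_design(tab, mp$conditions, limitation = "limitation",
                             interactions = ints)
  expect_equal(ncol(ld2$matrix), 19L)
  expect_equal(ld2$matrix[, "arthritis:asthma"],
               tab$arthritis * tab$asthma)
  expect_equal(ld2$matrix[, "arthritis:asthma:diabetes"],
               tab$arthritis * tab$asthma * tab$diabetes)

  expect_error(build_latent_design(tab, mp$conditions,
                                   interactions = list(c("arthritis",
                                                         "nope"))),
               "nope")
})

test_that("threshold design drops baselines and records the group block", {
  tab <- synth_generate(synth_config(n = 400, seed = 3))
  mp <- attr(tab, "mapping")
  ld <- build_latent_design(tab, mp$conditions, limitation = "limitation")
  td <- build_threshold_design(tab, mp$families, mp$baselines, "group",
                               singles = mp$singles, latent = ld)
  expect_equal(td$group_block, c("asian", "black", "mixed", "other_eth"))
  # 4 group + 9 agesex + 2 imd + 2 healthcare + 2 wave
  expect_equal(ncol(td$matrix), 19L)
  expect_length(intersect(colnames(td$matrix), colnames(ld$matrix)), 0)

  # age(5) x sex(2) family: 10 cells minus one reference
  expect_equal(sum(colnames(td$matrix) %in% mp$families$agesex), 9L)
})

test_that("threshold design rejects invalid families and overlap", {
  tab <- synth_generate(synth_config(n = 200, seed = 4))
  mp <- attr(tab, "mapping")
  broken <- tab
  broken$asian[1] <- broken$white[1]  # two levels set on row 1
  expect_error(
    build_threshold_design(broken, mp$families, mp$baselines, "group"),
    "one-hot"
  )
  ld <- build_latent_design(tab, mp$conditions)
  tab$not_arthritis <- 1 - tab$arthritis
  expect_error(
    build_threshold_design(tab,
                           list(group = mp$families$group,
                                sick = c("arthritis", "not_arthritis")),
                           c(group = "white", sick = "not_arthritis"),
                           "group", latent = ld),
    "disjoint"
  )
})

test_that("degenerate single-level contrast family yields an empty block", {
  tab <- data.frame(g = rep(1, 10), x = rbinom(10, 1, 0.5))
  td <- build_threshold_design(tab, list(group = "g"), c(group = "g"),
                               "group")
  expect_equal(ncol(td$matrix), 0L)
  expect_length(td$group_block, 0)
  expect_error(build_profiles(td), "empty")
})

test_that("covariate reallocation moves columns wholesale and stays disjoint", {
  tab <- synth_generate(synth_config(n = 300, seed = 5))
  mp <- attr(tab, "mapping")
  ld <- build_latent_design(tab, mp$conditions, limitation = "limitation")
  td <- build_threshold_design(tab, mp$families, mp$baselines, "group",
                               singles = mp$singles, latent = ld)

  same <- reallocate_covariates(ld, td, character())
  expect_identical(same$latent, ld)
  expect_identical(same$threshold, td)

  dep <- c("imd_t2", "imd_t3")
  out <- reallocate_covariates(ld, td, dep)
  expect_equal(ncol(out$latent$matrix), ncol(ld$matrix) + 2L)
  expect_equal(ncol(out$threshold$matrix), ncol(td$matrix) - 2L)
  expect_length(intersect(colnames(out$latent$matrix),
                          colnames(out$threshold$matrix)), 0)

  # a second move keeps the two sets disjoint
  out2 <- reallocate_covariates(out$latent, out$threshold,
                                c("gp_use", "nurse_use"))
  expect_length(intersect(colnames(out2$latent$matrix),
                          colnames(out2$threshold$matrix)), 0)
  expect_equal(out2$threshold$group_block, td$group_block)

  expect_error(reallocate_covariates(ld, td, "unknown_col"), "unknown_col")
  expect_error(reallocate_covariates(ld, td, "asian"), "contrast-family")
})
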
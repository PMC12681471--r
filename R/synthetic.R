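# Synthetic EQ-5D-5L-style survey generator. Emulates the statistical
# structure the estimator assumes: sparse correlated binary morbidities
# (single-factor Gaussian copula), a 3-level recent-limitation item, group
# membership with realistic shares, one-hot reporting-covariate families,
# heterogeneous lognormal survey weights, and ordinal outcomes generated by
# running the latent-index / threshold model forward. It matches structure,
# not the joint distribution of any real survey.

default_prevalences <- function() {
  c(alzheimers = 0.0014, angina = 0.036, arthritis = 0.107,
    asthma = 0.106, blindness = 0.0051, cancer = 0.029, deafness = 0.024,
    diabetes = 0.066, epilepsy = 0.0114, high_blood_pressure = 0.167,
    kidney_liver = 0.0145, back_problem = 0.096, mental_health = 0.053,
    neurological = 0.0206, other_condition = 0.134)
}

default_group_shares <- function() {
  c(white = 0.8782, asian = 0.0632, black = 0.0259, mixed = 0.0095,
    other_eth = 0.0232)
}

default_beta <- function(cond_names, limitation) {
  base <- c(alzheimers = 0.6, angina = 0.3, arthritis = 0.5, asthma = 0.15,
            blindness = 0.4, cancer = 0.25, deafness = 0.12, diabetes = 0.2,
            epilepsy = 0.3, high_blood_pressure = 0.08, kidney_liver = 0.25,
            back_problem = 0.45, mental_health = 0.35, neurological = 0.5,
            other_condition = 0.3)
  beta <- ifelse(cond_names %in% names(base), base[cond_names], 0.3)
  names(beta) <- cond_names
  if (limitation) {
    beta <- c(beta, limitation.a_little = 0.35, limitation.a_lot = 0.9)
  }
  beta
}

#' Configuration for the synthetic survey generator
#'
#' Defaults reproduce the descriptive scale of a large English
#' general-practice survey: 15 long-term conditions with marginal
#' prevalences from about 0.14% (dementia) to 17% (high blood pressure),
#' five ethnic-group shares dominated by the baseline group (87.8%), ten
#' age-band-by-sex cells, deprivation terciles, healthcare-use indicators,
#' wave dummies and lognormal survey weights with mean 1. True coefficients
#' are fixed round numbers; the contrast family's cut-point shifts are set
#' by `group_shift` (first threshold) and `group_shift2` (second).
#'
#' @param n sample size.
#' @param seed integer seed (mandatory: every generator call is seeded).
#' @param prevalence named vector of condition marginal probabilities.
#' @param condition_loading single-factor copula loading in \[0, 1)
#'   controlling comorbidity correlation.
#' @param limitation include the 3-level recent-limitation item.
#' @param limitation_probs probabilities for (no, a_little, a_lot).
#' @param limitation_loading copula loading tying limitation to morbidity.
#' @param group_shares named shares of the contrast family; the first name
#'   is the baseline group.
#' @param include_agesex include the 10 age-band-by-sex cells.
#' @param include_imd include deprivation terciles.
#' @param imd_by_group optional named list group -> length-3 tercile
#'   probabilities, inducing a group-deprivation association (for
#'   confounding experiments); default independent uniform terciles.
#' @param include_healthcare include GP-use and nurse-use indicators.
#' @param n_waves number of survey waves (>= 1); wave 1 is the baseline.
#' @param weight_sdlog lognormal sdlog of the survey weights (meanlog set
#'   so the mean weight is 1).
#' @param weight_outcome_dependence strength of an optional dependence of
#'   weights on the first outcome, to probe weighted-vs-unweighted
#'   divergence; 0 (default) keeps weights independent of outcomes.
#' @param true_beta named latent-equation truth; defaults to fixed round
#'   values per condition plus limitation dummies.
#' @param true_lambda threshold intercept truth (length 4).
#' @param true_gamma optional q x 4 truth over the threshold columns; by
#'   default built from `group_shift`/`group_shift2` plus small fixed
#'   values for the remaining reporting covariates.
#' @param group_shift named first-threshold cut-point shifts for the
#'   non-baseline groups.
#' @param group_shift2 named second-threshold shifts (exponent scale).
#' @param dimensions character labels of outcome columns to generate; each
#'   gets an independent latent error draw, sharing the same truth.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n, seed,
                         prevalence = default_prevalences(),
                         condition_loading = 0.5,
                         limitation = TRUE,
                         limitation_probs = c(no = 0.86, a_little = 0.10,
                                              a_lot = 0.04),
                         limitation_loading = 0.4,
                         group_shares = default_group_shares(),
                         include_agesex = TRUE,
                         include_imd = TRUE,
                         imd_by_group = NULL,
                         include_healthcare = TRUE,
                         n_waves = 3,
                         weight_sdlog = 0.5,
                         weight_outcome_dependence = 0,
                         true_beta = NULL,
                         true_lambda = c(0.9, -0.3, -0.5, -0.5),
                         true_gamma = NULL,
                         group_shift = c(asian = 0.2, black = 0.3,
                                         mixed = 0.02, other_eth = 0.15),
                         group_shift2 = NULL,
                         dimensions = "mobility") {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("condition prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(names(prevalence))) {
    stop("prevalence vector must be named", call. = FALSE)
  }
  if (abs(sum(group_shares) - 1) > 1e-8) {
    stop("group shares must sum to 1", call. = FALSE)
  }
  if (condition_loading < 0 || condition_loading >= 1) {
    stop("condition_loading must lie in [0, 1)", call. = FALSE)
  }
  if (length(true_lambda) != 4) stop("true_lambda must have length 4",
                                     call. = FALSE)
  if (is.null(true_beta)) {
    true_beta <- default_beta(names(prevalence), limitation)
  }
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed), prevalence = prevalence,
    condition_loading = condition_loading, limitation = limitation,
    limitation_probs = limitation_probs,
    limitation_loading = limitation_loading, group_shares = group_shares,
    include_agesex = include_agesex, include_imd = include_imd,
    imd_by_group = imd_by_group, include_healthcare = include_healthcare,
    n_waves = as.integer(n_waves), weight_sdlog = weight_sdlog,
    weight_outcome_dependence = weight_outcome_dependence,
    true_beta = true_beta, true_lambda = true_lambda,
    true_gamma = true_gamma, group_shift = group_shift,
    group_shift2 = group_shift2, dimensions = dimensions
  )
  class(cfg) <- "synth_config"
  cfg
}

# threshold-equation column layout implied by a config (excluding baselines)
synth_z_columns <- function(cfg) {
  groups <- names(cfg$group_shares)
  cols <- groups[-1]
  families <- list(group = groups)
  baselines <- c(group = groups[1])
  singles <- character()
  if (cfg$include_agesex) {
    cells <- as.vector(outer(c("male", "female"),
                             c("25_34", "35_44", "45_54", "55_64", "65_74"),
                             paste, sep = "_"))
    families$agesex <- cells
    baselines["agesex"] <- cells[1]
    cols <- c(cols, cells[-1])
  }
  if (cfg$include_imd) {
    families$imd <- paste0("imd_t", 1:3)
    baselines["imd"] <- "imd_t1"
    cols <- c(cols, paste0("imd_t", 2:3))
  }
  if (cfg$n_waves > 1) {
    families$wave <- paste0("wave", seq_len(cfg$n_waves))
    baselines["wave"] <- "wave1"
    cols <- c(cols, paste0("wave", 2:cfg$n_waves))
  }
  # singles come last, matching the column order build_threshold_design
  # produces (families first, standalone covariates appended)
  if (cfg$include_healthcare) {
    singles <- c(singles, "gp_use", "nurse_use")
    cols <- c(cols, "gp_use", "nurse_use")
  }
  list(columns = cols, families = families, baselines = baselines,
       groups = groups)
}

synth_true_gamma <- function(cfg, zcols) {
  if (!is.null(cfg$true_gamma)) {
    G <- as.matrix(cfg$true_gamma)
    if (nrow(G) != length(zcols$columns) || ncol(G) != 4) {
      stop("true_gamma must be ", length(zcols$columns), " x 4",
           call. = FALSE)
    }
    rownames(G) <- zcols$columns
    return(G)
  }
  G <- matrix(0, length(zcols$columns), 4,
              dimnames = list(zcols$columns, NULL))
  shift <- cfg$group_shift
  for (g in names(shift)) {
    if (g %in% rownames(G)) G[g, 1] <- shift[[g]]
  }
  if (!is.null(cfg$group_shift2)) {
    for (g in names(cfg$group_shift2)) {
      if (g %in% rownames(G)) G[g, 2] <- cfg$group_shift2[[g]]
    }
  }
  # mild fixed reporting effects on the remaining covariates
  if (cfg$include_agesex) {
    cells <- setdiff(zcols$families$agesex, zcols$baselines[["agesex"]])
    G[cells, 1] <- 0.02 * seq_along(cells)
  }
  if (cfg$include_imd) {
    G["imd_t2", 1] <- -0.03
    G["imd_t3", 1] <- -0.06
  }
  if (cfg$include_healthcare) {
    G["gp_use", 1] <- 0.05
    G["nurse_use", 1] <- -0.02
  }
  if (cfg$n_waves > 1) {
    G[paste0("wave", 2:cfg$n_waves), 1] <- 0.01
  }
  G
}

one_hot <- function(f, levels) {
  m <- vapply(levels, function(l) as.numeric(f == l), numeric(length(f)))
  colnames(m) <- levels
  m
}

#' Generate a synthetic respondent table
#'
#' Runs the data-generating process forward: conditions from a
#' single-factor Gaussian copula hitting the target marginals, group and
#' covariate families, latent health beta'x + N(0,1), per-row thresholds
#' from the threshold equation, and outcome by interval classification.
#' Fully reproducible from the config seed.
#'
#' @param config a [synth_config()].
#' @return A data frame of class `"synth_table"` with outcome columns (one
#'   per dimension), condition indicators, the limitation item, covariate
#'   dummies and a `weight` column. The hidden ground truth (true
#'   parameters, latent draws, per-row thresholds) is stored in
#'   `attr(x, "truth")` and the design-building recipe in
#'   `attr(x, "mapping")`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n

  fac <- stats::rnorm(n)
  l <- cfg$condition_loading
  conds <- vapply(names(cfg$prevalence), function(k) {
    u <- l * fac + sqrt(1 - l^2) * stats::rnorm(n)
    as.numeric(u < stats::qnorm(cfg$prevalence[[k]]))
  }, numeric(n))

  df <- as.data.frame(conds)
  if (cfg$limitation) {
    ll <- cfg$limitation_loading
    v <- ll * fac + sqrt(1 - ll^2) * stats::rnorm(n)
    pr <- cfg$limitation_probs
    cuts <- stats::qnorm(cumsum(c(pr[["a_lot"]], pr[["a_little"]])))
    df$limitation <- ifelse(v < cuts[1], "a_lot",
                            ifelse(v < cuts[2], "a_little", "no"))
  }

  zcols <- synth_z_columns(cfg)
  grp <- sample(zcols$groups, n, replace = TRUE, prob = cfg$group_shares)
  df <- cbind(df, one_hot(grp, zcols$groups))
  if (cfg$include_agesex) {
    cells <- zcols$families$agesex
    age_p <- c(0.213, 0.212, 0.232, 0.191, 0.152)
    cell_p <- as.vector(outer(c(0.494, 0.506), age_p))
    cs <- sample(cells, n, replace = TRUE, prob = cell_p)
    df <- cbind(df, one_hot(cs, cells))
  }
  if (cfg$include_imd) {
    terc <- paste0("imd_t", 1:3)
    if (is.null(cfg$imd_by_group)) {
      tv <- sample(terc, n, replace = TRUE)
    } else {
      tv <- character(n)
      for (g in zcols$groups) {
        idx <- which(grp == g)
        pg <- cfg$imd_by_group[[g]]
        if (is.null(pg)) pg <- rep(1 / 3, 3)
        tv[idx] <- sample(terc, length(idx), replace = TRUE, prob = pg)
      }
    }
    df <- cbind(df, one_hot(tv, terc))
  }
  if (cfg$include_healthcare) {
    df$gp_use <- stats::rbinom(n, 1, 0.85)
    df$nurse_use <- stats::rbinom(n, 1, 0.35)
  }
  if (cfg$n_waves > 1) {
    wv <- sample(paste0("wave", seq_len(cfg$n_waves)), n, replace = TRUE)
    df <- cbind(df, one_hot(wv, paste0("wave", seq_len(cfg$n_waves))))
  }

  # design matrices under the package's own conventions
  xnames <- names(cfg$true_beta)
  X <- as.matrix(df[names(cfg$prevalence)])
  if (cfg$limitation) {
    X <- cbind(X,
               limitation.a_little = as.numeric(df$limitation == "a_little"),
               limitation.a_lot = as.numeric(df$limitation == "a_lot"))
  }
  X <- X[, xnames, drop = FALSE]
  Z <- as.matrix(df[zcols$columns])
  G <- synth_true_gamma(cfg, zcols)
  truth_params <- hopit_params(cfg$true_beta, cfg$true_lambda, G)
  eta <- drop(X %*% cfg$true_beta)
  tau <- compute_tau(cfg$true_lambda, G, Z)$tau

  h_star <- matrix(NA_real_, n, length(cfg$dimensions),
                   dimnames = list(NULL, cfg$dimensions))
  for (dim_lab in cfg$dimensions) {
    h <- eta + stats::rnorm(n)
    h_star[, dim_lab] <- h
    df[[dim_lab]] <- 1L + rowSums(h >= tau)
  }

  w <- stats::rlnorm(n, -cfg$weight_sdlog^2 / 2, cfg$weight_sdlog)
  if (cfg$weight_outcome_dependence != 0) {
    w <- w * exp(cfg$weight_outcome_dependence *
                   (df[[cfg$dimensions[1]]] - 3) / 2)
    w <- w / mean(w)
  }
  df$weight <- w

  mapping <- list(
    outcomes = stats::setNames(cfg$dimensions, cfg$dimensions),
    conditions = names(cfg$prevalence),
    limitation = if (cfg$limitation) "limitation" else NULL,
    families = zcols$families,
    baselines = zcols$baselines,
    group_family = "group",
    singles = if (cfg$include_healthcare) c("gp_use", "nurse_use")
              else character(),
    weight = "weight"
  )
  attr(df, "truth") <- list(params = truth_params, h_star = h_star,
                            tau = tau, config = cfg)
  attr(df, "mapping") <- mapping
  class(df) <- c("synth_table", "data.frame")
  df
}

#' Build both design matrices from a respondent table and a mapping
#'
#' Convenience wrapper tying the design-construction steps together:
#' optional interaction screening, the latent design, and the threshold
#' design (with disjointness verified).
#'
#' @param table respondent data frame (e.g. a [synth_generate()] result or
#'   a table read with [read_respondents()]).
#' @param mapping list describing the columns (`conditions`, `limitation`,
#'   `families`, `baselines`, `group_family`, `singles`, `weight`); for a
#'   `"synth_table"` the stored mapping is used automatically.
#' @param screen screen 2-/3-way condition interactions into the latent
#'   design.
#' @param min_prevalence prevalence cutoff for the screen.
#' @param max_order highest interaction order.
#' @param weighted survey-weighted prevalence for the screen.
#' @return List with `latent`, `threshold`, `weights` and the
#'   `interactions` table (NULL when `screen = FALSE`).
#' @export
build_designs <- function(table, mapping = attr(table, "mapping"),
                          screen = TRUE, min_prevalence = 0.01,
                          max_order = 3, weighted = TRUE) {
  if (is.null(mapping)) stop("a column mapping is required", call. = FALSE)
  w <- if (!is.null(mapping$weight)) table[[mapping$weight]] else NULL
  inter <- NULL
  if (screen) {
    inter <- screen_interactions(table[mapping$conditions], w,
                                 max_order = max_order,
                                 min_prevalence = min_prevalence,
                                 weighted = weighted)
  }
  latent <- build_latent_design(table, mapping$conditions,
                                limitation = mapping$limitation,
                                interactions = if (is.null(inter)) list()
                                               else inter)
  threshold <- build_threshold_design(table, mapping$families,
                                      mapping$baselines,
                                      mapping$group_family,
                                      singles = mapping$singles,
                                      latent = latent)
  list(latent = latent, threshold = threshold,
       weights = check_weights(w, nrow(table)), interactions = inter)
}

#' Parameter-recovery and coverage experiment
#'
#' For each replicate: generate a synthetic table, fit the model, compute
#' group threshold contrasts with a parametric bootstrap, and compare
#' everything against the generator's truth. The contrast estimand per
#' replicate is the true-parameter threshold difference at that replicate's
#' weighted sample profile.
#'
#' @param config a [synth_config()] (seeds are re-derived per replicate).
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param n_draws bootstrap draws per replicate.
#' @param screen screen interactions into the latent design (truth for
#'   interaction columns is zero).
#' @param dimension which generated outcome to fit (default the first).
#' @return A list of class `"recovery_experiment"` with `parameters` (bias,
#'   RMSE and 95% CI coverage per parameter), `contrasts` (the same per
#'   group and boundary for the threshold differences) and
#'   `n_nonconverged`.
#' @export
recovery_experiment <- function(config, n_replicates, seed, n_draws = 200,
                                screen = FALSE, dimension = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(dimension)) dimension <- config$dimensions[1]
  est <- list(); tru <- list(); ses <- list()
  dlt <- list()
  n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    tab <- synth_generate(cfg)
    des <- build_designs(tab, screen = screen)
    fit <- hopit(tab[[dimension]], des$latent, des$threshold,
                 weights = des$weights, dimension = dimension)
    if (!fit$converged) n_fail <- n_fail + 1L
    truth <- attr(tab, "truth")$params
    tb <- stats::setNames(numeric(ncol(des$latent$matrix)),
                          colnames(des$latent$matrix))
    tb[names(truth$beta)] <- truth$beta
    tg <- truth$gamma[colnames(des$threshold$matrix), , drop = FALSE]
    true_vec <- c(tb, truth$lambda, as.numeric(tg))
    est[[r]] <- fit$coefficients
    ses[[r]] <- sqrt(pmax(diag(fit$vcov), 0))
    tru[[r]] <- true_vec

    profiles <- build_profiles(
      structure(list(matrix = des$threshold$matrix,
                     group_block = des$threshold$group_block),
                class = "threshold_design"), des$weights)
    cts <- threshold_contrasts(fit, profiles, n_draws = n_draws,
                               seed = cfg$seed + 1L)
    rows <- lapply(seq_along(profiles), function(i) {
      td <- delta_tau(truth, profiles[[i]])
      ct <- cts[[i]]
      data.frame(replicate = r, group = ct$group,
                 boundary = boundary_labels(),
                 estimate = unname(ct$delta), truth = unname(td),
                 se = unname(ct$se),
                 covered = td >= ct$ci_se[, 1] & td <= ct$ci_se[, 2],
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    dlt[[r]] <- do.call(rbind, rows)
  }
  E <- do.call(rbind, est); Tm <- do.call(rbind, tru)
  S <- do.call(rbind, ses)
  err <- E - Tm
  cover <- (Tm >= E - 1.96 * S) & (Tm <= E + 1.96 * S)
  params <- data.frame(
    parameter = colnames(E),
    truth = colMeans(Tm), bias = colMeans(err),
    rmse = sqrt(colMeans(err^2)), mean_se = colMeans(S),
    coverage = colMeans(cover), stringsAsFactors = FALSE, row.names = NULL
  )
  dall <- do.call(rbind, dlt)
  agg <- do.call(rbind, lapply(split(dall, list(dall$group, dall$boundary),
                                     drop = TRUE), function(d) {
    data.frame(group = d$group[1], boundary = d$boundary[1],
               truth = mean(d$truth), bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$covered), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(parameters = params, contrasts = agg,
                 replicates = dall, n_nonconverged = n_fail,
                 n_replicates = n_replicates),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Parameter recovery over", x$n_replicates, "replicates (",
      x$n_nonconverged, "non-converged )\n")
  cat(sprintf("  max |parameter bias| %.4f, max parameter RMSE %.4f\n",
              max(abs(x$parameters$bias)), max(x$parameters$rmse)))
  cat("  contrast coverage by group x boundary:\n")
  print(x$contrasts, digits = 3)
  invisible(x)
}
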
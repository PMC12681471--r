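# End-to-end runner: config in; per-dimension fitted models, coefficient /
# contrast / bubble tables and a machine-readable manifest out.

#' Read a respondent table from delimited text
#'
#' Reads a header-row delimited file and applies complete-case filtering
#' over the modelled columns (outcomes, conditions, limitation, covariate
#' families, weight); the number of dropped rows is reported. No imputation
#' is performed.
#'
#' @param path delimited text file with a header row.
#' @param mapping column mapping: a list (see [build_designs()]) or a path
#'   to a YAML/JSON file declaring `outcomes`, `conditions`, `limitation`,
#'   `families`, `baselines`, `group_family`, `singles`, `weight`.
#' @param sep field separator (default `","`).
#' @return The filtered data frame with the mapping in
#'   `attr(x, "mapping")` and the dropped-row count in
#'   `attr(x, "n_dropped")`.
#' @export
read_respondents <- function(path, mapping, sep = ",") {
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  modelled <- unique(c(unlist(mapping$outcomes), mapping$conditions,
                       mapping$limitation, unlist(mapping$families),
                       mapping$singles, mapping$weight))
  missing_cols <- setdiff(modelled, names(df))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(df[modelled])
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("dropped ", n_dropped, " row(s) with missing modelled fields")
  }
  out <- df[keep, , drop = FALSE]
  attr(out, "mapping") <- mapping
  attr(out, "n_dropped") <- n_dropped
  out
}

read_mapping <- function(path) {
  mp <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML mappings", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (f in c("outcomes", "conditions", "limitation", "baselines",
              "group_family", "singles", "weight")) {
    if (!is.null(mp[[f]])) mp[[f]] <- unlist(mp[[f]])
  }
  if (is.null(mp$singles)) mp$singles <- character()
  mp$families <- lapply(mp$families, unlist)
  mp
}

#' Run the full reporting-heterogeneity analysis
#'
#' For each requested outcome dimension: screen interactions, build both
#' designs, fit the survey-weighted model, compute fit metrics and group
#' threshold contrasts with a parametric bootstrap, and (optionally) write
#' coefficient, contrast and bubble tables plus a JSON run manifest.
#'
#' @param config a list with elements:
#'   * `data` — a respondent data frame with a mapping attribute, **or**
#'     `synth` — a [synth_config()], **or** `input`/`mapping` — a delimited
#'     file and mapping for [read_respondents()];
#'   * `dimensions` — outcome columns to fit (default: all mapped);
#'   * `screen` — list(`enabled`, `min_prevalence`, `max_order`,
#'     `weighted`);
#'   * `move` — threshold columns reallocated to the latent equation
#'     (sensitivity specifications);
#'   * `omit` — threshold columns dropped from the model entirely (reduced
#'     specifications; contrast-family columns are refused);
#'   * `n_draws`, `seed` — bootstrap settings;
#'   * `label` — specification label for manifests and comparisons.
#' @param output_dir directory for the result bundle; NULL skips writing.
#' @return (Invisibly) a list of class `"hopit_run"` with `fits`,
#'   `contrasts`, `reports`, `bubble`, `manifest` and `label`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- config
  if (!is.null(cfg$synth)) {
    syn <- cfg$synth
    if (!inherits(syn, "synth_config")) syn <- do.call(synth_config, syn)
    tab <- synth_generate(syn)
  } else if (!is.null(cfg$data)) {
    tab <- cfg$data
  } else if (!is.null(cfg$input)) {
    tab <- read_respondents(cfg$input, cfg$mapping,
                            sep = if (is.null(cfg$sep)) "," else cfg$sep)
  } else {
    stop("config must supply 'data', 'synth' or 'input'", call. = FALSE)
  }
  mapping <- attr(tab, "mapping")
  if (is.null(mapping)) mapping <- cfg$mapping
  if (is.null(mapping)) stop("no column mapping available", call. = FALSE)

  dims <- if (is.null(cfg$dimensions)) unlist(mapping$outcomes)
          else cfg$dimensions
  scr <- utils::modifyList(list(enabled = TRUE, min_prevalence = 0.01,
                                max_order = 3, weighted = TRUE),
                           if (is.null(cfg$screen)) list() else cfg$screen)
  n_draws <- if (is.null(cfg$n_draws)) 1000 else cfg$n_draws
  seed <- if (is.null(cfg$seed)) stop("config must carry a seed",
                                      call. = FALSE) else cfg$seed

  des <- build_designs(tab, mapping, screen = scr$enabled,
                       min_prevalence = scr$min_prevalence,
                       max_order = scr$max_order, weighted = scr$weighted)
  if (!is.null(cfg$move) && length(cfg$move)) {
    moved <- reallocate_covariates(des$latent, des$threshold, cfg$move)
    des$latent <- moved$latent
    des$threshold <- moved$threshold
  }
  if (!is.null(cfg$omit) && length(cfg$omit)) {
    # reduced specification: drop reporting covariates from the threshold
    # equation altogether (contrast-family columns may never be omitted)
    bad <- intersect(cfg$omit, des$threshold$group_block)
    if (length(bad)) {
      stop("cannot omit contrast-family column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(cfg$omit, colnames(des$threshold$matrix))
    if (length(unknown)) {
      stop("omit column(s) not in threshold design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(colnames(des$threshold$matrix), cfg$omit)
    des$threshold <- structure(
      list(matrix = des$threshold$matrix[, keep, drop = FALSE],
           group_block = des$threshold$group_block),
      class = "threshold_design")
  }

  fits <- list(); contrasts <- list(); reports <- list()
  for (dim_lab in dims) {
    fit <- hopit(tab[[dim_lab]], des$latent, des$threshold,
                 weights = des$weights, dimension = dim_lab)
    cts <- threshold_contrasts(fit, n_draws = n_draws,
                               seed = seed + match(dim_lab, dims))
    fits[[dim_lab]] <- fit
    contrasts[[dim_lab]] <- cts
    reports[[dim_lab]] <- fit_report(fit)
  }
  bubble <- export_bubble_table(contrasts)

  manifest <- list(
    package_version = as.character(utils::packageVersion("reportshift")),
    label = if (is.null(cfg$label)) "default" else cfg$label,
    seed = seed, n_draws = n_draws,
    n_obs = nrow(tab),
    n_dropped = if (is.null(attr(tab, "n_dropped"))) 0
                else attr(tab, "n_dropped"),
    dimensions = as.list(dims),
    screen = scr,
    n_screened_interactions = if (is.null(des$interactions)) 0
                              else nrow(des$interactions),
    move = if (is.null(cfg$move)) character() else cfg$move,
    omit = if (is.null(cfg$omit)) character() else cfg$omit,
    synth_seed = if (!is.null(cfg$synth)) {
      if (inherits(cfg$synth, "synth_config")) cfg$synth$seed
      else cfg$synth$seed
    },
    fits = lapply(fits, function(f) list(
      dimension = f$dimension, loglik = f$loglik,
      converged = f$converged, iterations = f$iterations,
      grad_norm = f$grad_norm, npar = f$npar))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (dim_lab in dims) {
      cf <- summary(fits[[dim_lab]])$coefficients
      utils::write.csv(data.frame(parameter = rownames(cf), cf,
                                  check.names = FALSE, row.names = NULL),
                       file.path(output_dir,
                                 paste0("coefficients_", dim_lab, ".csv")),
                       row.names = FALSE)
      utils::write.csv(export_bubble_table(contrasts[[dim_lab]]),
                       file.path(output_dir,
                                 paste0("contrasts_", dim_lab, ".csv")),
                       row.names = FALSE)
    }
    rt <- report_table(reports)
    utils::write.csv(data.frame(term = rownames(rt), rt,
                                check.names = FALSE, row.names = NULL),
                     file.path(output_dir, "report_table.csv"),
                     row.names = FALSE)
    utils::write.csv(bubble, file.path(output_dir, "bubble.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!all(vapply(fits, `[[`, TRUE, "converged"))) {
      writeLines("one or more fits failed to converge",
                 file.path(output_dir, "FAILED"))
    }
  }

  invisible(structure(list(fits = fits, contrasts = contrasts,
                           reports = reports, bubble = bubble,
                           manifest = manifest,
                           label = manifest$label,
                           ok = all(vapply(fits, `[[`, TRUE, "converged"))),
                      class = "hopit_run"))
}

#' @export
print.hopit_run <- function(x, ...) {
  cat("Analysis run '", x$label, "': ", length(x$fits),
      " dimension(s), ", nrow(x$bubble), " contrast rows, converged: ",
      x$ok, "\n", sep = "")
  invisible(x)
}

#' Compare threshold contrasts across model specifications
#'
#' Aligns the group threshold differences of several runs (e.g. the full
#' model vs a main-effects-only model vs covariate reallocations) and flags
#' where a contrast changes sign relative to the first (reference)
#' specification and is statistically significant in the variant.
#'
#' @param runs a named list of [run_pipeline()] results sharing outcome
#'   dimensions and contrast family.
#' @return A data frame keyed by dimension, group and boundary, with one
#'   `delta_*` / `sig_*` column pair per specification and a
#'   `sign_change_*` flag per non-reference specification.
#' @export
compare_specifications <- function(runs) {
  if (!length(runs)) stop("no runs supplied", call. = FALSE)
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    names(runs) <- paste0("spec", seq_along(runs))
  }
  tabs <- lapply(runs, function(r) {
    stopifnot(inherits(r, "hopit_run"))
    export_bubble_table(r$contrasts)
  })
  key0 <- tabs[[1]][c("dimension", "group", "boundary")]
  for (i in seq_along(tabs)[-1]) {
    ki <- tabs[[i]][c("dimension", "group", "boundary")]
    if (!identical(sort(paste(ki$dimension, ki$group, ki$boundary)),
                   sort(paste(key0$dimension, key0$group, key0$boundary)))) {
      stop("specifications have mismatched dimensions or contrast ",
           "families", call. = FALSE)
    }
  }
  out <- key0
  ref <- names(runs)[1]
  for (nm in names(runs)) {
    t2 <- tabs[[nm]]
    m <- match(paste(out$dimension, out$group, out$boundary),
               paste(t2$dimension, t2$group, t2$boundary))
    out[[paste0("delta_", nm)]] <- t2$delta[m]
    out[[paste0("sig_", nm)]] <- t2$significant[m]
  }
  for (nm in setdiff(names(runs), ref)) {
    out[[paste0("sign_change_", nm)]] <-
      sign(out[[paste0("delta_", nm)]]) !=
        sign(out[[paste0("delta_", ref)]]) &
      out[[paste0("delta_", ref)]] != 0 &
      out[[paste0("sig_", nm)]] %in% TRUE
  }
  out
}
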
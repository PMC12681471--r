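# Design construction: the latent-health set x_i (morbidity mains +
# prevalence-screened interactions) and the threshold set z_i (reporting
# covariates). The two sets are kept disjoint throughout: identification of
# the threshold equation rests on no variable appearing in both.

#' Screen two- and three-way condition interactions by joint prevalence
#'
#' Enumerates all pairs (and, when `max_order = 3`, triples) of long-term
#' condition indicators and keeps those whose joint-occurrence prevalence is
#' at least `min_prevalence`. Prevalence is survey-weighted by default, so
#' the screen is consistent with weighted estimation; set `weighted = FALSE`
#' for the unweighted sample proportion. Triples are screened on their own
#' joint prevalence, independently of whether their sub-pairs passed.
#'
#' @param conditions binary (0/1) matrix or data frame of condition
#'   indicators, one column per condition, with column names.
#' @param weights optional non-negative survey weights, one per row.
#' @param max_order highest interaction order considered, 2 or 3.
#' @param min_prevalence minimum joint prevalence, strictly between 0 and 1.
#' @param weighted use survey-weighted prevalence (default) or raw
#'   proportions.
#' @return A data frame of class `"interaction_screen"` with one row per
#'   retained combination: `name`, `order`, `parents` (list column) and
#'   `prevalence`, in lexicographic parent order (all pairs, then triples).
#' @examples
#' m <- cbind(a = c(1, 1, 0, 1), b = c(1, 1, 0, 0), c = c(0, 1, 1, 1))
#' screen_interactions(m, min_prevalence = 0.25)
#' @export
screen_interactions <- function(conditions, weights = NULL, max_order = 3,
                                min_prevalence = 0.01, weighted = TRUE) {
  m <- check_binary_matrix(conditions)
  if (!max_order %in% c(2, 3)) {
    stop("max_order must be 2 or 3", call. = FALSE)
  }
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1 ||
      min_prevalence <= 0 || min_prevalence >= 1) {
    stop("min_prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  w <- check_weights(weights, nrow(m))
  if (!weighted) w <- rep(1, nrow(m))
  wsum <- sum(w)

  nms <- sort(colnames(m))
  rows <- list()
  for (ord in 2:max_order) {
    if (length(nms) < ord) break
    combos <- utils::combn(nms, ord, simplify = FALSE)
    for (cmb in combos) {
      joint <- m[, cmb[1]]
      for (p in cmb[-1]) joint <- joint * m[, p]
      prev <- sum(w * joint) / wsum
      if (prev >= min_prevalence) {
        rows[[length(rows) + 1L]] <- list(
          name = paste(cmb, collapse = ":"), order = ord,
          parents = cmb, prevalence = prev
        )
      }
    }
  }
  out <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    order = vapply(rows, `[[`, 0L, "order"),
    prevalence = vapply(rows, `[[`, 0, "prevalence"),
    stringsAsFactors = FALSE
  )
  out$parents <- lapply(rows, `[[`, "parents")
  class(out) <- c("interaction_screen", "data.frame")
  out
}

#' Build the latent-health design matrix
#'
#' Assembles x_i: one column per long-term condition, two dummies for the
#' recent-limitation question (reference level dropped), and one product
#' column per screened interaction.
#'
#' @param table respondent data frame.
#' @param conditions character vector of binary condition column names.
#' @param limitation optional name of a 3-level categorical column recording
#'   recent limitation; its reference level (default `"no"`, matched
#'   case-insensitively, else the first level) is dropped.
#' @param interactions an `"interaction_screen"` result, or a list of
#'   character vectors of parent condition names.
#' @param limitation_ref reference level for the limitation column.
#' @return An object of class `"latent_design"`: a list with the binary
#'   `matrix` and a `columns` data frame recording each column's provenance
#'   (main effect, limitation dummy, or interaction with its parents).
#' @export
build_latent_design <- function(table, conditions, limitation = NULL,
                                interactions = list(), limitation_ref = NULL) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(conditions, names(table))
  if (length(missing_cols)) {
    stop("condition column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- check_binary_matrix(table[conditions], "conditions")
  kind <- rep("main", length(conditions))
  parents <- as.list(conditions)

  if (!is.null(limitation)) {
    lv <- table[[limitation]]
    if (is.null(lv)) stop("limitation column '", limitation, "' not found",
                          call. = FALSE)
    lv <- as.factor(lv)
    levs <- levels(lv)
    if (length(levs) != 3) {
      stop("limitation column must have exactly 3 levels, found ",
           length(levs), call. = FALSE)
    }
    ref <- limitation_ref
    if (is.null(ref)) {
      hit <- levs[tolower(levs) == "no"]
      ref <- if (length(hit)) hit[1] else levs[1]
    }
    if (!ref %in% levs) stop("limitation reference level '", ref,
                             "' not among levels", call. = FALSE)
    for (lev in setdiff(levs, ref)) {
      X <- cbind(X, as.numeric(lv == lev))
      colnames(X)[ncol(X)] <- paste0(limitation, ".", lev)
      kind <- c(kind, "limitation")
      parents <- c(parents, list(limitation))
    }
  }

  if (inherits(interactions, "interaction_screen")) {
    interactions <- interactions$parents
  }
  for (cmb in interactions) {
    unknown <- setdiff(cmb, conditions)
    if (length(unknown)) {
      stop("interaction parent(s) not among condition columns: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    prod_col <- table[[cmb[1]]]
    for (p in cmb[-1]) prod_col <- prod_col * table[[p]]
    nm <- paste(cmb, collapse = ":")
    if (nm %in% colnames(X)) {
      stop("duplicate design column '", nm, "'", call. = FALSE)
    }
    X <- cbind(X, as.numeric(prod_col))
    colnames(X)[ncol(X)] <- nm
    kind <- c(kind, "interaction")
    parents <- c(parents, list(cmb))
  }

  cols <- data.frame(name = colnames(X), kind = kind,
                     stringsAsFactors = FALSE)
  cols$parents <- parents
  structure(list(matrix = X, columns = cols), class = "latent_design")
}

#' Build the threshold (reporting-behaviour) design matrix
#'
#' Assembles z_i from declared dummy families (each validated one-hot, its
#' baseline level dropped) and standalone binary covariates. One family is
#' flagged as the contrast family (e.g. ethnic group); its non-baseline
#' columns form the `group_block` used by [build_profiles()].
#'
#' @param table respondent data frame.
#' @param families named list: family name -> character vector of binary
#'   column names forming a mutually exclusive, exhaustive set.
#' @param baselines named character vector: family name -> baseline column
#'   to drop.
#' @param group_family name of the contrast family (must be in `families`).
#' @param singles character vector of standalone binary columns entered
#'   as-is.
#' @param latent optional [build_latent_design()] result; if given, column
#'   disjointness between the two equations is verified.
#' @return An object of class `"threshold_design"`: a list with the binary
#'   `matrix` and the `group_block` column names.
#' @export
build_threshold_design <- function(table, families, baselines, group_family,
                                   singles = character(), latent = NULL) {
  stopifnot(is.data.frame(table), is.list(families))
  if (!group_family %in% names(families)) {
    stop("group_family '", group_family, "' is not a declared family",
         call. = FALSE)
  }
  if (!all(names(families) %in% names(baselines))) {
    stop("every family needs a named baseline level", call. = FALSE)
  }
  Z <- NULL
  group_block <- character()
  for (fam in names(families)) {
    cols <- families[[fam]]
    missing_cols <- setdiff(cols, names(table))
    if (length(missing_cols)) {
      stop("family '", fam, "' column(s) not found: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    fm <- check_binary_matrix(table[cols], fam)
    check_one_hot(fm, fam)
    base <- baselines[[fam]]
    if (!base %in% cols) {
      stop("baseline '", base, "' is not a column of family '", fam, "'",
           call. = FALSE)
    }
    keep <- setdiff(cols, base)
    Z <- cbind(Z, fm[, keep, drop = FALSE])
    if (fam == group_family) group_block <- keep
  }
  for (s in singles) {
    if (!s %in% names(table)) stop("single covariate '", s, "' not found",
                                   call. = FALSE)
    Z <- cbind(Z, check_binary(table[[s]], s))
    colnames(Z)[ncol(Z)] <- s
  }
  if (anyDuplicated(colnames(Z))) {
    stop("duplicate threshold design column names", call. = FALSE)
  }
  if (!is.null(latent)) {
    overlap <- intersect(colnames(Z), colnames(latent$matrix))
    if (length(overlap)) {
      stop("column(s) ", paste(overlap, collapse = ", "),
           " appear in both equations; the threshold parametrization ",
           "requires the latent and threshold sets to be disjoint",
           call. = FALSE)
    }
  }
  storage.mode(Z) <- "double"
  structure(list(matrix = Z, group_block = group_block),
            class = "threshold_design")
}

#' Move covariates between the threshold and latent equations
#'
#' Supports sensitivity specifications in which reporting covariates (age-sex
#' cells, deprivation terciles, healthcare use) are treated as determinants
#' of latent health instead of rating behaviour. Columns are moved wholesale
#' from z_i into x_i; moving any contrast-family column is refused because
#' the group contrast is undefined without it.
#'
#' @param latent a `"latent_design"`.
#' @param threshold a `"threshold_design"`.
#' @param move character vector of threshold column names to move (may be
#'   empty, in which case the inputs are returned unchanged).
#' @return A list with updated `latent` and `threshold` designs.
#' @export
reallocate_covariates <- function(latent, threshold, move) {
  stopifnot(inherits(latent, "latent_design"),
            inherits(threshold, "threshold_design"))
  if (!length(move)) return(list(latent = latent, threshold = threshold))
  unknown <- setdiff(move, colnames(threshold$matrix))
  if (length(unknown)) {
    stop("column(s) not in threshold design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  in_group <- intersect(move, threshold$group_block)
  if (length(in_group)) {
    stop("refusing to move contrast-family column(s) ",
         paste(in_group, collapse = ", "),
         " out of the threshold equation: the group contrast is undefined ",
         "without them", call. = FALSE)
  }
  moved <- threshold$matrix[, move, drop = FALSE]
  keep <- setdiff(colnames(threshold$matrix), move)
  new_threshold <- structure(
    list(matrix = threshold$matrix[, keep, drop = FALSE],
         group_block = threshold$group_block),
    class = "threshold_design"
  )
  overlap <- intersect(move, colnames(latent$matrix))
  if (length(overlap)) {
    stop("column(s) ", paste(overlap, collapse = ", "),
         " already present in the latent design", call. = FALSE)
  }
  X <- cbind(latent$matrix, moved)
  cols <- rbind(
    latent$columns[, c("name", "kind")],
    data.frame(name = move, kind = "reallocated", stringsAsFactors = FALSE)
  )
  cols$parents <- c(latent$columns$parents, as.list(move))
  new_latent <- structure(list(matrix = X, columns = cols),
                          class = "latent_design")
  list(latent = new_latent, threshold = new_threshold)
}

#' @export
print.latent_design <- function(x, ...) {
  k <- table(x$columns$kind)
  cat("Latent-health design:", nrow(x$matrix), "rows,",
      ncol(x$matrix), "columns\n")
  cat("  ", paste(names(k), unname(k), sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.threshold_design <- function(x, ...) {
  cat("Threshold design:", nrow(x$matrix), "rows,",
      ncol(x$matrix), "columns\n")
  cat("  contrast family columns:",
      paste(x$group_block, collapse = ", "), "\n")
  invisible(x)
}
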
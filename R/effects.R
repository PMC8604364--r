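# Effect-matrix construction, combination, augmentation, and the
# Frobenius-norm variance decomposition.

new_effect_matrix <- function(M, families, fm, augmented_with = character(),
                              missing_rows = NULL) {
  structure(list(M = M, families = families,
                 augmented_with = augmented_with,
                 missing_rows = missing_rows,
                 subject = fm$design$subject,
                 time = fm$design$time,
                 group = fm$design$group),
            class = "effect_matrix")
}

#' Construct an effect matrix for a set of effect families
#'
#' Zeroes every design column (and coefficient row) outside the requested
#' families and multiplies: `M = X_f B_f`. With time reference-coded on
#' baseline, the time and time-by-group effect matrices have exactly zero
#' baseline rows, so trajectories read as changes from baseline.
#'
#' @param fm an `rm_fit` from [fit_multivariate()].
#' @param families character subset of the fitted design's column
#'   families, e.g. `"time"`, `c("time", "time:group")`.
#' @return An object of class `effect_matrix` (model rows x variables)
#'   carrying per-row subject/time/group annotations.
#' @export
construct_effect_matrix <- function(fm, families) {
  stopifnot(inherits(fm, "rm_fit"))
  if (length(families) == 0) stop("at least one effect family is required")
  available <- unique(fm$design$column_families)
  unknown <- setdiff(families, available)
  if (length(unknown) > 0) {
    stop("effect family not in the fitted design: ",
         paste(unknown, collapse = ", "),
         " (available: ", paste(available, collapse = ", "), ")")
  }
  keep <- names(fm$design$column_families)[fm$design$column_families %in% families]
  M <- fm$design$X[, keep, drop = FALSE] %*% fm$B[keep, , drop = FALSE]
  dimnames(M) <- list(NULL, colnames(fm$B))
  new_effect_matrix(M, sort(unique(families)), fm)
}

#' Sum effect matrices with disjoint families
#'
#' Elementwise sum of effect matrices from the same fit, e.g.
#' `M_T + M_TxG` for a baseline-anchored view of group trajectories, or
#' `M_G + M_TxG` under double reference coding for a control-anchored
#' view.
#'
#' @param ... `effect_matrix` objects, or a single list of them.
#' @return An `effect_matrix` whose families are the union.
#' @export
combine_effect_matrices <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && !inherits(ms[[1]], "effect_matrix")) ms <- ms[[1]]
  stopifnot(length(ms) >= 1,
            all(vapply(ms, inherits, logical(1), "effect_matrix")))
  dims <- vapply(ms, function(m) dim(m$M), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("effect matrices have mismatched dimensions")
  }
  fams <- unlist(lapply(ms, `[[`, "families"))
  if (anyDuplicated(fams)) {
    stop("effect families overlap: ",
         paste(unique(fams[duplicated(fams)]), collapse = ", "))
  }
  if (any(vapply(ms, function(m) length(m$augmented_with) > 0, logical(1)))) {
    stop("combine un-augmented effect matrices, then augment the sum")
  }
  out <- ms[[1]]
  out$M <- Reduce(`+`, lapply(ms, `[[`, "M"))
  out$families <- sort(fams)
  out
}

#' Augment an effect matrix with random effects and/or residuals
#'
#' Adds the subject random-intercept contribution `ZU` (per-subject
#' parallel offsets) and/or the residual matrix `E` back onto the fitted
#' effects, for spaghetti-style assessment of effect size against
#' between-subject and unexplained variation. Missing-response cells of E
#' contribute zero and the affected rows are flagged (downstream
#' projections drop them).
#'
#' @param m an un-augmented `effect_matrix`.
#' @param fm the `rm_fit` it came from.
#' @param with_random add `ZU`.
#' @param with_residuals add `E`.
#' @return The augmented `effect_matrix`.
#' @export
augment_effect_matrix <- function(m, fm, with_random = TRUE,
                                  with_residuals = TRUE) {
  stopifnot(inherits(m, "effect_matrix"), inherits(fm, "rm_fit"))
  if (length(m$augmented_with) > 0) stop("effect matrix is already augmented")
  if (!with_random && !with_residuals) return(m)
  M <- m$M
  aug <- character()
  if (with_random) {
    M <- M + as.matrix(fm$design$Z %*% fm$U)
    aug <- c(aug, "random_effects")
  }
  missing_rows <- NULL
  if (with_residuals) {
    E0 <- fm$E
    missing_rows <- apply(is.na(E0), 1, any)
    E0[is.na(E0)] <- 0
    M <- M + E0
    aug <- c(aug, "residuals")
  }
  m$M <- M
  m$augmented_with <- aug
  m$missing_rows <- missing_rows
  m
}

#' Tidy view of an effect matrix
#'
#' @param m an `effect_matrix`.
#' @param by `"row"` for one row per model record and variable, or
#'   `"cell"` for one row per unique time x group design cell (rows within
#'   a cell of an un-augmented effect matrix are identical).
#' @return A tibble keyed by (subject, time, group) or by design cell.
#' @export
effect_table <- function(m, by = c("row", "cell")) {
  by <- match.arg(by)
  vars <- colnames(m$M)
  if (by == "row") {
    tibble::tibble(
      subject = rep(as.character(m$subject), times = length(vars)),
      time = rep(as.character(m$time), times = length(vars)),
      group = rep(as.character(m$group), times = length(vars)),
      variable = rep(vars, each = nrow(m$M)),
      value = as.vector(m$M)
    )
  } else {
    cell <- interaction(m$time, m$group, drop = TRUE, sep = " / ")
    agg <- apply(m$M, 2, function(col) tapply(col, cell, mean))
    key <- do.call(rbind, strsplit(rownames(agg), " / ", fixed = TRUE))
    tibble::tibble(
      time = rep(key[, 1], times = length(vars)),
      group = rep(key[, 2], times = length(vars)),
      variable = rep(vars, each = nrow(agg)),
      value = as.vector(agg)
    )
  }
}

#' Frobenius-norm variance decomposition across effect families
#'
#' Computes the squared Frobenius norm of each singleton-family effect
#' matrix, of the residuals, and of the (complete-case) response matrix,
#' together with the discrepancy `||Y||^2 - sum ||M_f||^2 - ||E||^2`.
#' The decomposition is exact (discrepancy ~ 0) only for balanced,
#' fully sum-coded, fixed-effects-only designs; with reference-coded time
#' — the default here, needed for the baseline constraint — the effect
#' matrices are not mutually orthogonal and the discrepancy is reported
#' rather than hidden.
#'
#' @param fm an `rm_fit`.
#' @return A tibble with one row per term (`intercept`, `time`, ...,
#'   `random_effects` if present, `residual`) and columns `term`,
#'   `frobenius_sq`; attributes `total` (`||Y||^2`), `discrepancy`, and
#'   `n_rows` (complete-case rows used).
#' @export
variance_decomposition <- function(fm) {
  stopifnot(inherits(fm, "rm_fit"))
  complete <- which(!apply(is.na(fm$design$responses), 1, any) &
                      !apply(is.na(fm$E), 1, any))
  fams <- setdiff(unique(fm$design$column_families), character(0))
  terms <- lapply(fams, function(f) {
    construct_effect_matrix(fm, f)$M[complete, , drop = FALSE]
  })
  names(terms) <- fams
  if (fm$design$spec$random_intercept) {
    terms$random_effects <- as.matrix(fm$design$Z %*% fm$U)[complete, , drop = FALSE]
  }
  terms$residual <- fm$E[complete, , drop = FALSE]
  Y <- fm$design$responses[complete, , drop = FALSE]
  norms <- vapply(terms, function(M) sum(M^2), numeric(1))
  total <- sum(Y^2)
  out <- tibble::tibble(term = names(norms), frobenius_sq = unname(norms))
  attr(out, "total") <- total
  attr(out, "discrepancy") <- total - sum(norms)
  attr(out, "n_rows") <- length(complete)
  out
}
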
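# Categorical coding and fixed/random design-matrix construction for the
# four longitudinal model families.

#' Coding scheme for a categorical factor
#'
#' With reference coding the omitted (reference) level is a row of zeros
#' and effects are expressed relative to it; with sum coding the omitted
#' level is a row of -1 and effects are expressed relative to the mean
#' across levels. A factor with k levels always yields k-1 columns.
#'
#' @param kind `"reference"` or `"sum"`.
#' @param reference the omitted level; `NULL` means the factor's first
#'   level.
#' @return An object of class `coding_scheme`.
#' @export
coding_scheme <- function(kind = c("reference", "sum"), reference = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, reference = reference), class = "coding_scheme")
}

#' Encode a categorical factor as indicator columns
#'
#' @param levels ordered character vector of all factor levels.
#' @param observed vector of observed levels, one per row.
#' @param scheme a [coding_scheme()].
#' @return A numeric matrix with one column per non-reference level, in
#'   level order, named after the levels.
#' @export
encode_factor <- function(levels, observed, scheme = coding_scheme("reference")) {
  observed <- as.character(observed)
  if (!all(observed %in% levels)) {
    stop("unseen level(s): ",
         paste(setdiff(unique(observed), levels), collapse = ", "))
  }
  ref <- scheme$reference %||% levels[1]
  if (!ref %in% levels) stop("reference level not among factor levels")
  cols <- setdiff(levels, ref)
  m <- matrix(0, nrow = length(observed), ncol = length(cols),
              dimnames = list(NULL, cols))
  for (lv in cols) m[observed == lv, lv] <- 1
  if (scheme$kind == "sum") m[observed == ref, ] <- -1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a longitudinal model
#'
#' Chooses one of four model families for column-wise fitting:
#' * `rm_unconstrained` — repeated measures with baseline in the response
#'   and a group main effect (ucLDA);
#' * `rm_constrained` — repeated measures with the group main effect
#'   omitted, so all groups share the modelled baseline mean and the
#'   time-by-group interaction is baseline-adjusted (cLDA);
#' * `ancova` — follow-up responses with the subject's baseline value as a
#'   covariate (longitudinal ANCOVA);
#' * `changes` — follow-up responses expressed as differences from
#'   baseline.
#'
#' Time is always reference-coded with the first (baseline) level as
#' reference; that is what makes the constrained family's baseline
#' constraint and the effect-matrix interpretation work. Group coding is
#' the user's choice.
#'
#' @param family model family, see above.
#' @param group_coding a [coding_scheme()] for the group factor.
#' @param include_group_main logical; forced `FALSE` for
#'   `rm_constrained`. Default `TRUE` otherwise.
#' @param covariates character vector of covariate column names entering
#'   as plain fixed-effect columns (no interaction with time).
#' @param baseline_center_ancova logical; for `ancova`, center the
#'   responses and the baseline covariate on the baseline grand mean.
#' @param random_intercept logical; a subject random intercept. Forced
#'   off for `ancova`/`changes` with exactly two timepoints, where each
#'   subject contributes a single row.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("rm_unconstrained", "rm_constrained",
                                  "ancova", "changes"),
                       group_coding = coding_scheme("sum"),
                       include_group_main = NULL,
                       covariates = character(),
                       baseline_center_ancova = FALSE,
                       random_intercept = TRUE) {
  family <- match.arg(family)
  if (family == "rm_constrained") {
    if (isTRUE(include_group_main)) {
      stop("the constrained family omits the group main effect by definition")
    }
    include_group_main <- FALSE
  }
  include_group_main <- include_group_main %||% TRUE
  structure(list(family = family, group_coding = group_coding,
                 include_group_main = include_group_main,
                 covariates = covariates,
                 baseline_center_ancova = baseline_center_ancova,
                 random_intercept = random_intercept),
            class = "model_spec")
}

interaction_columns <- function(Tm, Gm) {
  # group-major, time-minor: for each group column, all time columns
  if (ncol(Gm) == 0 || ncol(Tm) == 0) {
    return(matrix(0, nrow = nrow(Tm), ncol = 0))
  }
  out <- list()
  for (g in colnames(Gm)) {
    for (t in colnames(Tm)) {
      out[[paste0(t, ":", g)]] <- Tm[, t] * Gm[, g]
    }
  }
  do.call(cbind, out)
}

covariate_columns <- function(ds, rows, covariates) {
  if (length(covariates) == 0) {
    return(matrix(0, nrow = length(rows), ncol = 0))
  }
  if (is.null(ds$covariates) ||
      !all(covariates %in% names(ds$covariates))) {
    stop("covariate(s) not present in dataset: ",
         paste(setdiff(covariates, names(ds$covariates)), collapse = ", "))
  }
  as.matrix(ds$covariates[rows, covariates, drop = FALSE])
}

new_design_matrices <- function(X, Z, column_families, response_rows,
                                responses, subject, time, group,
                                baseline_values, spec) {
  structure(list(X = X, Z = Z, column_families = column_families,
                 response_rows = response_rows, responses = responses,
                 subject = subject, time = time, group = group,
                 baseline_values = baseline_values, spec = spec),
            class = "design_matrices")
}

#' Build fixed and random design matrices for a model specification
#'
#' Constructs the N x p fixed-effect design matrix X, the subject
#' incidence matrix Z, the map from X columns to effect families
#' (`intercept`, `time`, `group`, `time:group`, `covariate`, `baseline`),
#' and the model-row responses. For the repeated-measures families every
#' record is a model row; for `ancova` and `changes` only follow-up
#' records are model rows, with time re-encoded using the first follow-up
#' level as reference.
#'
#' @param ds a `longitudinal_dataset`.
#' @param spec a [model_spec()].
#' @return An object of class `design_matrices`.
#' @export
build_design <- function(ds, spec) {
  stopifnot(inherits(ds, "longitudinal_dataset"), inherits(spec, "model_spec"))
  if (nlevels(ds$time) < 2) stop("at least two time levels are required")
  counts <- table(droplevels(ds$group, exclude = NULL))
  empty <- names(counts)[counts == 0]
  if (any(table(ds$group) == 0)) {
    stop("group(s) with no subjects: ",
         paste(names(table(ds$group))[table(ds$group) == 0], collapse = ", "))
  }
  switch(spec$family,
         rm_unconstrained = ,
         rm_constrained = build_design_rm(ds, spec),
         ancova = build_design_followup(ds, spec, baseline_covariate = TRUE),
         changes = build_design_followup(ds, spec, baseline_covariate = FALSE))
}

build_design_rm <- function(ds, spec) {
  n <- nrow(ds$responses)
  rows <- seq_len(n)
  tlev <- levels(ds$time)
  glev <- levels(ds$group)
  Tm <- encode_factor(tlev, ds$time, coding_scheme("reference", tlev[1]))
  colnames(Tm) <- paste0("time", colnames(Tm))
  Gm <- if (length(glev) > 1) {
    g <- encode_factor(glev, ds$group, spec$group_coding)
    colnames(g) <- paste0("group", colnames(g))
    g
  } else matrix(0, n, 0)
  TG <- interaction_columns(Tm, Gm)
  Cv <- covariate_columns(ds, rows, spec$covariates)

  parts <- list(`(Intercept)` = matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)")),
                time = Tm)
  fams <- c("intercept", rep("time", ncol(Tm)))
  if (spec$include_group_main && ncol(Gm) > 0) {
    parts$group <- Gm
    fams <- c(fams, rep("group", ncol(Gm)))
  }
  if (ncol(TG) > 0) {
    parts$tg <- TG
    fams <- c(fams, rep("time:group", ncol(TG)))
  }
  if (ncol(Cv) > 0) {
    parts$cov <- Cv
    fams <- c(fams, rep("covariate", ncol(Cv)))
  }
  X <- do.call(cbind, parts)
  colnames(X)[1] <- "(Intercept)"
  names(fams) <- colnames(X)

  new_design_matrices(
    X = X, Z = subject_incidence(ds$subject), column_families = fams,
    response_rows = rows, responses = ds$responses,
    subject = ds$subject, time = ds$time, group = ds$group,
    baseline_values = NULL, spec = spec
  )
}

build_design_followup <- function(ds, spec, baseline_covariate) {
  tlev <- levels(ds$time)
  K <- length(tlev)
  if (K < 2) stop("at least two time levels are required")
  follow <- which(ds$time != tlev[1])
  if (length(follow) == 0) stop("no follow-up records")
  flev <- tlev[-1]
  time_f <- factor(as.character(ds$time[follow]), levels = flev)
  glev <- levels(ds$group)

  Tm <- encode_factor(flev, time_f, coding_scheme("reference", flev[1]))
  if (ncol(Tm) > 0) colnames(Tm) <- paste0("time", colnames(Tm))
  Gm <- if (length(glev) > 1) {
    g <- encode_factor(glev, ds$group[follow], spec$group_coding)
    colnames(g) <- paste0("group", colnames(g))
    g
  } else matrix(0, length(follow), 0)
  TG <- interaction_columns(Tm, Gm)
  Cv <- covariate_columns(ds, follow, spec$covariates)

  # baseline response per subject and variable, looked up by subject
  base_rows <- which(ds$time == tlev[1])
  baseline_values <- matrix(NA_real_, nlevels(ds$subject), ncol(ds$responses),
                            dimnames = list(levels(ds$subject),
                                            colnames(ds$responses)))
  baseline_values[as.integer(ds$subject[base_rows]), ] <-
    ds$responses[base_rows, , drop = FALSE]

  parts <- list(`(Intercept)` = matrix(1, length(follow), 1))
  fams <- "intercept"
  if (ncol(Tm) > 0) { parts$time <- Tm; fams <- c(fams, rep("time", ncol(Tm))) }
  if (spec$include_group_main && ncol(Gm) > 0) {
    parts$group <- Gm; fams <- c(fams, rep("group", ncol(Gm)))
  }
  if (ncol(TG) > 0) { parts$tg <- TG; fams <- c(fams, rep("time:group", ncol(TG))) }
  if (ncol(Cv) > 0) { parts$cov <- Cv; fams <- c(fams, rep("covariate", ncol(Cv))) }
  if (baseline_covariate) {
    parts$baseline <- matrix(0, length(follow), 1,
                             dimnames = list(NULL, ".baseline"))
    fams <- c(fams, "baseline")
  }
  X <- do.call(cbind, parts)
  colnames(X)[1] <- "(Intercept)"
  names(fams) <- colnames(X)

  responses <- ds$responses[follow, , drop = FALSE]
  if (!baseline_covariate) {
    # analysis of changes: subtract each subject's baseline per variable
    responses <- responses -
      baseline_values[as.integer(ds$subject[follow]), , drop = FALSE]
  }

  spec$random_intercept <- spec$random_intercept && K > 2

  new_design_matrices(
    X = X, Z = subject_incidence(ds$subject, rows = follow),
    column_families = fams, response_rows = follow, responses = responses,
    subject = ds$subject[follow], time = ds$time[follow],
    group = ds$group[follow],
    baseline_values = if (baseline_covariate) baseline_values else NULL,
    spec = spec
  )
}

subject_incidence <- function(subject, rows = seq_along(subject)) {
  Matrix::sparseMatrix(i = seq_along(rows),
                       j = as.integer(subject[rows]),
                       x = 1,
                       dims = c(length(rows), nlevels(subject)),
                       dimnames = list(NULL, levels(subject)))
}
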
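# Long-format longitudinal multivariate data: construction, validation,
# io, transformation, and baseline-SD scaling.

#' Construct a longitudinal dataset
#'
#' Bundles long-format repeated-measures data — one row per subject x
#' timepoint — into a validated container used by every downstream step.
#' The first time level is treated as baseline throughout the package.
#'
#' @param subject vector of subject identifiers, one per record.
#' @param time vector of time labels, one per record. Coerced to a factor
#'   whose level order is `time_levels` (or order of first appearance when
#'   `time_levels` is `NULL`). Numeric time is treated as labels: time is
#'   always modelled as a categorical factor.
#' @param group vector of group labels, one per record. Every subject must
#'   carry a single group label across all of its records.
#' @param responses numeric matrix or data frame, rows matching records,
#'   one column per response variable (e.g. metabolite). `NA` allowed.
#' @param covariates optional data frame of numeric baseline covariates.
#' @param time_levels,group_levels optional explicit level orderings.
#'
#' @return An object of class `longitudinal_dataset` with elements
#'   `subject`, `time`, `group`, `responses`, `covariates`, `scaling`.
#' @export
longitudinal_dataset <- function(subject, time, group, responses,
                                 covariates = NULL,
                                 time_levels = NULL, group_levels = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "double"
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("V", seq_len(ncol(responses)))
  }
  n <- nrow(responses)
  if (length(subject) != n || length(time) != n || length(group) != n) {
    stop("subject, time, group and responses must describe the same records")
  }
  if (anyNA(subject)) stop("missing subject identifiers are not allowed")
  if (anyNA(time)) stop("records with missing time labels are rejected")
  if (anyNA(group)) stop("records with missing group labels are rejected")

  if (is.null(time_levels)) time_levels <- unique(as.character(time))
  unknown <- setdiff(unique(as.character(time)), time_levels)
  if (length(unknown) > 0) {
    stop("unknown time level(s): ", paste(unknown, collapse = ", "))
  }
  time <- factor(as.character(time), levels = time_levels)
  if (is.null(group_levels)) group_levels <- unique(as.character(group))
  group <- factor(as.character(group), levels = group_levels)
  subject <- factor(as.character(subject), levels = unique(as.character(subject)))

  if (nlevels(time) < 2) stop("at least two time levels are required")

  dup <- duplicated(data.frame(subject, time))
  if (any(dup)) {
    d <- which(dup)[1]
    stop(sprintf("duplicate (subject, time) pair: (%s, %s)",
                 subject[d], time[d]))
  }
  gps <- tapply(as.character(group), subject, function(g) length(unique(g)))
  if (any(gps > 1)) {
    bad <- names(gps)[gps > 1][1]
    stop(sprintf("subject %s has inconsistent group labels", bad))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per record")
  }

  structure(
    list(subject = subject, time = time, group = group,
         responses = responses, covariates = covariates, scaling = NULL),
    class = "longitudinal_dataset"
  )
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<longitudinal_dataset> %d records, %d subjects, %d timepoints, %d group(s), %d variable(s)\n",
    s$N, s$I, s$K, s$H, s$J))
  cat("missing response fraction by timepoint:\n")
  print(round(s$missing_by_time, 3))
  invisible(x)
}

#' Summarize a longitudinal dataset
#'
#' Reports the record count N, subject count I, number of timepoints K,
#' number of groups H, number of response variables J, and the fraction of
#' missing response cells at each timepoint.
#'
#' @param object a `longitudinal_dataset`.
#' @param ... unused.
#' @return A list with elements `N`, `I`, `K`, `H`, `J`, `missing_by_time`.
#' @export
summary.longitudinal_dataset <- function(object, ...) {
  miss <- vapply(levels(object$time), function(tl) {
    cells <- object$responses[object$time == tl, , drop = FALSE]
    if (length(cells) == 0) return(NA_real_)
    mean(is.na(cells))
  }, numeric(1))
  list(N = nrow(object$responses),
       I = nlevels(droplevels(object$subject)),
       K = nlevels(object$time),
       H = nlevels(droplevels(object$group)),
       J = ncol(object$responses),
       missing_by_time = miss)
}

#' Read a long-format delimited table into a longitudinal dataset
#'
#' @param path path to a delimited text file with a header row. The
#'   separator is inferred from the extension (`.csv` comma, otherwise
#'   tab) unless given.
#' @param subject,time,group names of the identifier columns.
#' @param responses character vector of response column names; default is
#'   every numeric column not used for another role.
#' @param covariates optional character vector of covariate column names.
#' @param sep field separator; `NULL` to infer from the file extension.
#' @param time_levels,group_levels optional explicit level orderings
#'   (default: order of first appearance in the file).
#' @return A validated `longitudinal_dataset`.
#' @export
read_long_table <- function(path, subject, time, group,
                            responses = NULL, covariates = NULL,
                            sep = NULL, time_levels = NULL,
                            group_levels = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  roles <- c(subject, time, group, covariates)
  missing_cols <- setdiff(c(roles, responses), names(df))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in file: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(responses)) {
    candidates <- setdiff(names(df), roles)
    responses <- candidates[vapply(df[candidates], is.numeric, logical(1))]
    if (length(responses) == 0) stop("no numeric response columns found")
  }
  longitudinal_dataset(
    subject = df[[subject]], time = df[[time]], group = df[[group]],
    responses = df[responses],
    covariates = if (!is.null(covariates)) df[covariates] else NULL,
    time_levels = time_levels, group_levels = group_levels
  )
}

#' Write a longitudinal dataset as a long-format delimited table
#'
#' Inverse of [read_long_table()]: writes one row per record with
#' `subject`, `time`, `group`, covariate and response columns.
#'
#' @param ds a `longitudinal_dataset`.
#' @param path output file path; `.csv` writes comma-separated, anything
#'   else tab-separated.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(subject = as.character(ds$subject),
                   time = as.character(ds$time),
                   group = as.character(ds$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$covariates)) df <- cbind(df, ds$covariates)
  df <- cbind(df, as.data.frame(ds$responses))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-variable transformation of responses
#'
#' Applies `log` or `sqrt` elementwise to selected response columns, as is
#' conventional for concentration-type metabolomics data before modelling.
#' Missing cells stay missing; the transform tag is recorded in the
#' dataset's scaling state.
#'
#' @param ds a `longitudinal_dataset`.
#' @param transform a single tag (`"none"`, `"log"`, `"sqrt"`) applied to
#'   all variables, or a named character vector per variable.
#' @return The transformed `longitudinal_dataset`.
#' @export
apply_transform <- function(ds, transform) {
  vars <- colnames(ds$responses)
  if (is.null(names(transform)) && length(transform) == 1) {
    transform <- stats::setNames(rep(transform, length(vars)), vars)
  }
  if (!all(names(transform) %in% vars)) {
    stop("transform names must match response variable names")
  }
  tags <- stats::setNames(rep("none", length(vars)), vars)
  tags[names(transform)] <- transform
  bad <- setdiff(tags, c("none", "log", "sqrt"))
  if (length(bad) > 0) stop("unknown transform tag(s): ", paste(bad, collapse = ", "))

  Y <- ds$responses
  for (v in vars) {
    x <- Y[, v]
    obs <- !is.na(x)
    if (tags[[v]] == "sqrt") {
      if (any(x[obs] < 0)) {
        row <- which(obs & x < 0)[1]
        stop(sprintf("sqrt transform: negative value in variable %s at row %d", v, row))
      }
      Y[obs, v] <- sqrt(x[obs])
    } else if (tags[[v]] == "log") {
      if (any(x[obs] <= 0)) {
        row <- which(obs & x <= 0)[1]
        stop(sprintf("log transform: non-positive value in variable %s at row %d", v, row))
      }
      Y[obs, v] <- log(x[obs])
    }
  }
  ds$responses <- Y
  prev <- ds$scaling
  ds$scaling <- scaling_state(
    transform = tags,
    baseline_sd = if (!is.null(prev)) prev$baseline_sd else
      stats::setNames(rep(NA_real_, length(vars)), vars)
  )
  ds
}

#' Scaling state record
#'
#' Records, per response variable, the transform tag applied and the
#' baseline standard deviation used as scaling divisor — enough to
#' re-apply the identical preprocessing to new data.
#'
#' @param transform named character vector of tags (`none`/`log`/`sqrt`).
#' @param baseline_sd named numeric vector of divisors (`NA` if unscaled).
#' @return An object of class `scaling_state`.
#' @export
scaling_state <- function(transform, baseline_sd) {
  stopifnot(identical(names(transform), names(baseline_sd)))
  structure(list(transform = transform, baseline_sd = baseline_sd),
            class = "scaling_state")
}

#' Scale each response variable to its baseline standard deviation
#'
#' Divides every response column by the sample standard deviation (n-1
#' denominator) of its non-missing baseline (first timepoint)
#' observations, so variables are expressed in units of their
#' between-subject baseline spread. Fails loudly on degenerate columns.
#'
#' @param ds a `longitudinal_dataset`.
#' @return A list with elements `dataset` (scaled) and `state`
#'   (a [scaling_state()] recording the divisors).
#' @export
scale_to_baseline_sd <- function(ds) {
  base <- ds$time == levels(ds$time)[1]
  Y <- ds$responses
  sds <- apply(Y[base, , drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x)
  })
  bad <- names(sds)[is.na(sds) | sds == 0]
  if (length(bad) > 0) {
    stop("baseline SD is zero or undefined for variable(s): ",
         paste(bad, collapse = ", "))
  }
  ds$responses <- sweep(Y, 2, sds, "/")
  tags <- if (!is.null(ds$scaling)) ds$scaling$transform else
    stats::setNames(rep("none", ncol(Y)), colnames(Y))
  state <- scaling_state(transform = tags, baseline_sd = sds)
  ds$scaling <- state
  list(dataset = ds, state = state)
}

#' Re-apply a recorded scaling state to new data
#'
#' Applies the recorded per-variable transform and then divides by the
#' recorded baseline SDs, so new data land on the training scale.
#'
#' @param ds a `longitudinal_dataset` on the raw scale.
#' @param state a `scaling_state`.
#' @return The transformed and scaled `longitudinal_dataset`.
#' @export
apply_scaling <- function(ds, state) {
  stopifnot(inherits(state, "scaling_state"))
  ds <- apply_transform(ds, state$transform)
  if (!all(is.na(state$baseline_sd))) {
    if (anyNA(state$baseline_sd)) stop("scaling state has undefined divisors")
    ds$responses <- sweep(ds$responses, 2, state$baseline_sd, "/")
  }
  ds$scaling <- state
  ds
}

#' Serialize a scaling state as a key-value text file
#' @param state a `scaling_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scaling_state <- function(state, path) {
  df <- data.frame(variable = names(state$transform),
                   transform = unname(state$transform),
                   baseline_sd = unname(state$baseline_sd))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scaling state written by [write_scaling_state()]
#' @param path input path.
#' @return A `scaling_state`.
#' @export
read_scaling_state <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  scaling_state(stats::setNames(df$transform, df$variable),
                stats::setNames(df$baseline_sd, df$variable))
}
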
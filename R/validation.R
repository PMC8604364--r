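# Group-stratified nonparametric case bootstrap of the full pipeline,
# with orthogonal Procrustes rotation and percentile intervals.

#' Orthogonal Procrustes rotation toward a target loading matrix
#'
#' Finds the orthogonal `A x A` matrix `Q` minimizing
#' `||P_boot Q - P_ref||_F` via the closed-form construction from the
#' singular value decomposition of `P_boot' P_ref`, removing the
#' rotational and sign ambiguity of principal components across bootstrap
#' replicates. The caller applies the same rotation to the replicate's
#' scores.
#'
#' @param P_boot J x A replicate loadings.
#' @param P_ref J x A reference (non-bootstrapped) loadings.
#' @return A list with `rotation` (A x A orthogonal) and `P_rot`
#'   (`P_boot %*% rotation`).
#' @export
procrustes_rotate <- function(P_boot, P_ref) {
  stopifnot(identical(dim(P_boot), dim(P_ref)))
  M <- crossprod(P_boot, P_ref)
  if (all(abs(M) < .Machine$double.eps)) {
    warning("degenerate (zero) loadings; using identity rotation")
    Q <- diag(ncol(P_boot))
  } else {
    sv <- svd(M)
    Q <- sv$u %*% t(sv$v)
  }
  list(rotation = Q, P_rot = P_boot %*% Q)
}

#' Percentile interval from bootstrap replicates
#'
#' Empirical percentiles at `100 * alpha / 2` and `100 * (1 - alpha / 2)`
#' with linear interpolation between order statistics.
#'
#' @param samples numeric vector of replicate values (length >= 2).
#' @param alpha interval level; `0.05` gives the 2.5th and 97.5th
#'   percentiles.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(samples, alpha = 0.05) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2) stop("at least 2 samples are required")
  q <- stats::quantile(samples, probs = c(alpha / 2, 1 - alpha / 2),
                       type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

stratified_resample <- function(subjects_by_group) {
  # sample subjects with replacement within each group, to original size
  unlist(lapply(subjects_by_group, function(s) {
    s[sample.int(length(s), length(s), replace = TRUE)]
  }), use.names = FALSE)
}

resample_dataset <- function(ds, subjects) {
  # assemble a replicate dataset; duplicated subjects get fresh unique ids
  # so each copy carries its own random intercept
  idx_by_subject <- split(seq_along(ds$subject), ds$subject)
  rows <- idx_by_subject[subjects]
  new_ids <- rep(paste0("bs", seq_along(subjects)), lengths(rows))
  rows <- unlist(rows, use.names = FALSE)
  longitudinal_dataset(
    subject = new_ids,
    time = as.character(ds$time[rows]),
    group = as.character(ds$group[rows]),
    responses = ds$responses[rows, , drop = FALSE],
    covariates = if (!is.null(ds$covariates))
      ds$covariates[rows, , drop = FALSE] else NULL,
    time_levels = levels(ds$time),
    group_levels = levels(ds$group)
  )
}

#' Stratified case bootstrap of the RM-ASCA+ pipeline
#'
#' Resamples whole subjects with replacement within each group (keeping
#' each group at its original size), re-applies the per-variable transform
#' and recomputes the baseline-SD scaling from every replicate, refits the
#' model, rebuilds and re-centers the requested effect matrix, decomposes
#' it, Procrustes-rotates the replicate loadings toward the reference
#' loadings (applying the same rotation to the scores), and accumulates
#' percentile intervals for cell scores and loadings.
#'
#' The intervals are approximate: the Procrustes target is the loading
#' matrix, which naturally narrows the loading intervals, and percentile
#' bands should not be read as parametric 95% confidence intervals.
#'
#' @param ds a `longitudinal_dataset` on the raw (untransformed) scale.
#' @param spec a [model_spec()].
#' @param families effect families to combine and decompose, e.g.
#'   `c("time", "time:group")`.
#' @param A number of components carried through the bootstrap.
#' @param n_boot number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param transform per-variable transform tags (see [apply_transform()]),
#'   or `NULL` for none.
#' @param scale_baseline recompute and apply baseline-SD scaling per
#'   replicate (and for the reference fit).
#' @param alpha interval level (default 0.05).
#' @param method fit method passed to [fit_multivariate()].
#' @param resampler function(subjects_by_group) returning a vector of
#'   subject ids for one replicate; the default is the stratified
#'   with-replacement sampler. Exposed so degenerate samplers (e.g. the
#'   identity resample) can be injected.
#' @return An object of class `bootstrap_result` with the reference
#'   decomposition (`reference`), tibbles `score_ci` (time, group,
#'   component, estimate, lower, upper) and `loading_ci` (variable,
#'   component, estimate, lower, upper), `n_boot`, `kept`, `skipped`,
#'   `alpha`, `seed`, and per-replicate diagnostics.
#' @export
bootstrap_rm_asca <- function(ds, spec, families, A = 2, n_boot = 1000,
                              seed = 1, transform = NULL,
                              scale_baseline = TRUE, alpha = 0.05,
                              method = "ML", resampler = NULL) {
  stopifnot(n_boot >= 1)
  resampler <- resampler %||% stratified_resample

  prep <- function(d) {
    if (!is.null(transform)) d <- apply_transform(d, transform)
    if (scale_baseline) d <- scale_to_baseline_sd(d)$dataset
    d
  }
  decompose <- function(d) {
    fm <- fit_multivariate(d, spec, method = method)
    m <- construct_effect_matrix(fm, families)
    center_and_pca(m, A = A)
  }

  ref <- decompose(prep(ds))
  ref_cells <- scores_by_cell(ref)
  cell_key <- paste(ref_cells$time, ref_cells$group, sep = "\r")
  comp <- colnames(ref$loadings)
  J <- nrow(ref$loadings)

  score_draws <- array(NA_real_, c(n_boot, nrow(ref_cells), A))
  loading_draws <- array(NA_real_, c(n_boot, J, A))
  converged <- logical(n_boot)

  sub_map <- unique(data.frame(s = as.character(ds$subject),
                               g = as.character(ds$group),
                               stringsAsFactors = FALSE))
  subjects_by_group <- split(sub_map$s, sub_map$g)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_boot)

  for (b in seq_len(n_boot)) {
    set.seed(rep_seeds[b])
    rep_dec <- tryCatch(
      suppressWarnings(decompose(prep(resample_dataset(
        ds, resampler(subjects_by_group))))),
      error = function(e) NULL
    )
    if (is.null(rep_dec)) next
    rot <- procrustes_rotate(rep_dec$loadings, ref$loadings)
    loading_draws[b, , ] <- rot$P_rot
    rep_dec$scores <- rep_dec$scores %*% rot$rotation
    colnames(rep_dec$scores) <- comp
    rep_cells <- scores_by_cell(rep_dec)
    idx <- match(cell_key, paste(rep_cells$time, rep_cells$group, sep = "\r"))
    score_draws[b, , ] <- as.matrix(rep_cells[idx, comp])
    converged[b] <- TRUE
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  kept <- sum(converged)
  if (kept < 2) stop("fewer than 2 bootstrap replicates converged")
  skipped <- n_boot - kept
  if (skipped > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates were skipped", skipped, n_boot))
  }

  ci_tab <- function(draws, est, key_df) {
    out <- list()
    for (a in seq_len(A)) {
      lo <- up <- numeric(nrow(key_df))
      for (r in seq_len(nrow(key_df))) {
        ci <- percentile_ci(draws[converged, r, a], alpha)
        lo[r] <- ci[["lower"]]
        up[r] <- ci[["upper"]]
      }
      out[[a]] <- tibble::as_tibble(cbind(
        as.data.frame(key_df),
        data.frame(component = comp[a], estimate = unname(est[, a]),
                   lower = lo, upper = up)))
    }
    do.call(rbind, out)
  }

  score_ci <- ci_tab(score_draws, as.matrix(ref_cells[, comp]),
                     ref_cells[, c("time", "group")])
  loading_ci <- ci_tab(loading_draws, ref$loadings,
                       tibble::tibble(variable = rownames(ref$loadings)))

  structure(list(reference = ref, score_ci = score_ci,
                 loading_ci = loading_ci, n_boot = n_boot, kept = kept,
                 skipped = skipped, alpha = alpha, seed = seed,
                 converged = converged),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d kept, %d skipped), alpha = %g\n",
              x$n_boot, x$kept, x$skipped, x$alpha))
  invisible(x)
}
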
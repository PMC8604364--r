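# Simultaneous component analysis of effect matrices: mean-centering,
# PCA by singular value decomposition, augmented-score projection.

#' Mean-center an effect matrix and decompose it with PCA
#'
#' Column means over model rows are subtracted first (the bootstrap
#' re-centers every replicate the same way), then the centered matrix is
#' decomposed by singular value decomposition. Rows are model rows, so
#' design cells with more observed records carry proportionally more
#' weight. A deterministic sign convention makes output platform-stable:
#' each loading column is flipped so its largest-magnitude element is
#' positive (ties broken by the first index).
#'
#' @param m an `effect_matrix` (not residual-augmented; augmented
#'   matrices are projected with [project_augmented()], not decomposed).
#' @param A number of components; default `min(rank, 5)`. If `A` exceeds
#'   the matrix rank the trailing components are zero-variance and a
#'   warning is issued.
#' @return An object of class `sca_decomposition` with `loadings` (J x A,
#'   orthonormal columns), `scores` (rows x A), `explained_fraction`,
#'   `center`, `singular_values`, `source_families`, and per-row
#'   subject/time/group annotations.
#' @export
center_and_pca <- function(m, A = NULL) {
  stopifnot(inherits(m, "effect_matrix"))
  if ("residuals" %in% m$augmented_with) {
    stop("residual-augmented matrices are projected, not decomposed; ",
         "use project_augmented()")
  }
  M <- m$M
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  sv <- svd(Mc)
  tol <- max(dim(Mc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank == 0) warning("effect matrix is constant; all components are zero")
  if (is.null(A)) A <- max(min(rank, 5L), 1L)
  if (A > min(dim(Mc))) stop("A exceeds the matrix dimensions")
  if (A > rank && rank > 0) {
    warning(sprintf("A = %d exceeds rank %d; trailing components have zero variance",
                    A, rank))
  }
  d <- sv$d[seq_len(A)]
  P <- sv$v[, seq_len(A), drop = FALSE]
  Tm <- sweep(sv$u[, seq_len(A), drop = FALSE], 2, d, "*")
  Tm[, d <= tol] <- 0
  explained <- if (sum(sv$d^2) > 0) d^2 / sum(sv$d^2) else rep(0, A)

  # sign convention: largest-|loading| element positive per column
  for (a in seq_len(A)) {
    jstar <- which.max(abs(P[, a]))
    if (P[jstar, a] < 0) {
      P[, a] <- -P[, a]
      Tm[, a] <- -Tm[, a]
    }
  }
  dimnames(P) <- list(colnames(M), paste0("PC", seq_len(A)))
  colnames(Tm) <- paste0("PC", seq_len(A))

  structure(list(loadings = P, scores = Tm,
                 explained_fraction = stats::setNames(explained,
                                                      paste0("PC", seq_len(A))),
                 center = center, singular_values = d,
                 source_families = m$families,
                 subject = m$subject, time = m$time, group = m$group),
            class = "sca_decomposition")
}

#' @export
print.sca_decomposition <- function(x, ...) {
  cat(sprintf("<sca_decomposition> of [%s], %d component(s)\n",
              paste(x$source_families, collapse = " + "),
              ncol(x$loadings)))
  cat("explained variance fraction:\n")
  print(round(x$explained_fraction, 4))
  invisible(x)
}

#' Project an augmented effect matrix onto an existing decomposition
#'
#' Centers the augmented matrix with the decomposition's own column means
#' and projects it on the loadings: `T_aug = (M_aug - center) P`. Rows
#' whose residual cells were missing are dropped and reported via the
#' `"dropped_rows"` attribute.
#'
#' @param dec an `sca_decomposition`.
#' @param m_aug an `effect_matrix` over the same variables and model rows
#'   (typically the decomposition's input augmented with `ZU` and/or `E`).
#' @return A tibble with per-row subject/time/group and one column per
#'   component.
#' @export
project_augmented <- function(dec, m_aug) {
  stopifnot(inherits(dec, "sca_decomposition"), inherits(m_aug, "effect_matrix"))
  if (ncol(m_aug$M) != nrow(dec$loadings)) {
    stop("variable dimensions do not match the decomposition")
  }
  keep <- seq_len(nrow(m_aug$M))
  dropped <- integer(0)
  if (!is.null(m_aug$missing_rows) && any(m_aug$missing_rows)) {
    dropped <- which(m_aug$missing_rows)
    keep <- which(!m_aug$missing_rows)
  }
  Ta <- sweep(m_aug$M[keep, , drop = FALSE], 2, dec$center) %*% dec$loadings
  out <- tibble::tibble(
    subject = as.character(m_aug$subject[keep]),
    time = as.character(m_aug$time[keep]),
    group = as.character(m_aug$group[keep])
  )
  for (a in seq_len(ncol(Ta))) out[[colnames(dec$loadings)[a]]] <- Ta[, a]
  attr(out, "dropped_rows") <- dropped
  out
}

#' Scores aggregated to unique design cells
#'
#' One row per time x group cell; for un-augmented effect matrices all
#' model rows in a cell share the same score, so the cell value is exact.
#'
#' @param dec an `sca_decomposition`.
#' @return A tibble with `time`, `group` and one column per component.
#' @export
scores_by_cell <- function(dec) {
  cell <- interaction(dec$time, dec$group, drop = TRUE, sep = "\r")
  agg <- apply(dec$scores, 2, function(col) tapply(col, cell, mean))
  agg <- matrix(agg, nrow = nlevels(cell),
                dimnames = list(levels(cell), colnames(dec$scores)))
  key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- tibble::tibble(time = key[, 1], group = key[, 2])
  for (a in colnames(agg)) out[[a]] <- unname(agg[, a])
  # preserve the dataset's time ordering
  out[order(match(out$time, levels(dec$time)),
            match(out$group, levels(dec$group))), ]
}

#' Tidy loadings table
#' @param dec an `sca_decomposition`.
#' @return A tibble with `variable`, `component`, `loading`.
#' @export
loadings_table <- function(dec) {
  P <- dec$loadings
  tibble::tibble(
    variable = rep(rownames(P), times = ncol(P)),
    component = rep(colnames(P), each = nrow(P)),
    loading = as.vector(P)
  )
}
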
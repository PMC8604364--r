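# Column-wise random-intercept linear (mixed) model fitting: Y = XB + ZU + E.

#' Fit one response column against a design matrix
#'
#' Fits `y = X beta + Z u + e` with a subject random intercept
#' `u ~ N(0, sigma_u^2)` (via [lme4::lmer()]) or, when
#' `random_intercept = FALSE`, an ordinary least-squares model. Rows with
#' missing response are dropped before fitting (all-available-data
#' analysis); subjects left with no rows get `u = 0` by convention.
#'
#' @param y numeric response vector, one entry per model row; `NA` allowed.
#' @param X numeric fixed-effect design matrix with named columns.
#' @param subject factor of subject ids per model row; its full level set
#'   defines the random-coefficient vector.
#' @param random_intercept logical.
#' @param method `"ML"` (default, maximum likelihood) or `"REML"`.
#' @return A list with `beta` (named, length p), `u` (named, one per
#'   subject level), `residuals` (length `nrow(X)`, `NA` where unused),
#'   `sigma_u2`, `sigma_e2`, `loglik`, `n_used`, `boundary` (`TRUE` when
#'   the subject variance was estimated at the zero boundary).
#' @export
fit_single_response <- function(y, X, subject, random_intercept = TRUE,
                                method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(length(y) == nrow(X), length(subject) == nrow(X))
  used <- which(!is.na(y) & stats::complete.cases(X))
  Xu <- X[used, , drop = FALSE]
  qrX <- qr(Xu)
  if (qrX$rank < ncol(Xu)) {
    dropped <- colnames(Xu)[qrX$pivot[(qrX$rank + 1):ncol(Xu)]]
    stop("design matrix is rank deficient after dropping missing rows; ",
         "collinear column(s): ", paste(dropped, collapse = ", "))
  }
  p <- ncol(X)
  u <- stats::setNames(rep(0, nlevels(subject)), levels(subject))
  res <- rep(NA_real_, length(y))
  boundary <- FALSE

  if (random_intercept) {
    dat <- list(.y = y[used], .X = Xu, .subj = droplevels(subject[used]))
    fit <- withCallingHandlers(
      lme4::lmer(.y ~ 0 + .X + (1 | .subj), data = dat,
                 REML = (method == "REML"),
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore", calc.derivs = FALSE)),
      message = function(m) invokeRestart("muffleMessage")
    )
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
      stop("mixed-model optimizer did not converge: ",
           paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
    }
    beta <- lme4::fixef(fit)
    names(beta) <- sub("^\\.X", "", names(beta))
    re <- lme4::ranef(fit)$.subj
    u[rownames(re)] <- re[, 1]
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_u2 <- vc$vcov[vc$grp == ".subj"]
    sigma_e2 <- stats::sigma(fit)^2
    if (lme4::isSingular(fit, tol = 1e-6) && sigma_u2 < 1e-8) {
      boundary <- TRUE
      sigma_u2 <- 0
      warning("subject-intercept variance estimated at the zero boundary",
              call. = FALSE)
    }
    res[used] <- y[used] - as.vector(Xu %*% beta) -
      u[as.character(subject[used])]
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- stats::lm.fit(Xu, y[used])
    beta <- stats::setNames(fit$coefficients, colnames(Xu))
    res[used] <- fit$residuals
    n <- length(used)
    rss <- sum(fit$residuals^2)
    sigma_u2 <- 0
    sigma_e2 <- rss / max(n - p, 1)
    s2_ml <- rss / n
    ll <- -0.5 * n * (log(2 * pi) + log(s2_ml) + 1)
  }

  list(beta = beta, u = u, residuals = res,
       sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
       loglik = ll, n_used = length(used), boundary = boundary)
}

#' Fit the model column-wise to every response variable
#'
#' Builds the design for `spec`, then fits each response column
#' independently and collects the coefficient matrix B (p x J), the
#' random-intercept matrix U (subjects x J), the residual matrix E
#' (model rows x J, `NA` where the response is missing), and per-variable
#' variance components. For the `ancova` family, the `.baseline`
#' placeholder column of X is filled per response with that variable's
#' subject baseline values, and subjects missing baseline are excluded
#' for that response.
#'
#' @param ds a `longitudinal_dataset`.
#' @param spec a [model_spec()].
#' @param method `"ML"` (default) or `"REML"`.
#' @param on_error `"stop"` (default) to fail on the first variable whose
#'   fit fails, or `"skip"` to drop failing variables and report them.
#' @return An object of class `rm_fit` with elements `B`, `U`, `E`,
#'   `var_u`, `var_e`, `loglik`, `n_used`, `boundary`, `fit_method`,
#'   `design`, `failed` (named character vector of error messages for
#'   skipped variables, if any).
#' @export
fit_multivariate <- function(ds, spec, method = c("ML", "REML"),
                             on_error = c("stop", "skip")) {
  method <- match.arg(method)
  on_error <- match.arg(on_error)
  dm <- build_design(ds, spec)
  X <- dm$X
  J <- ncol(dm$responses)
  vars <- colnames(dm$responses)
  p <- ncol(X)
  I <- nlevels(dm$subject)

  rows_per_subject <- table(droplevels(dm$subject))
  if (mean(rows_per_subject == 1) > 0.2 && dm$spec$random_intercept) {
    warning("more than 20% of subjects contribute a single row; ",
            "the subject/residual variance split is weakly identified",
            call. = FALSE)
  }

  B <- matrix(NA_real_, p, J, dimnames = list(colnames(X), vars))
  U <- matrix(0, I, J, dimnames = list(levels(dm$subject), vars))
  E <- matrix(NA_real_, nrow(X), J, dimnames = list(NULL, vars))
  var_u <- var_e <- loglik <- stats::setNames(rep(NA_real_, J), vars)
  n_used <- stats::setNames(rep(0L, J), vars)
  boundary <- stats::setNames(rep(FALSE, J), vars)
  failed <- character()

  has_baseline_col <- ".baseline" %in% colnames(X)
  for (j in seq_len(J)) {
    yj <- dm$responses[, j]
    Xj <- X
    if (has_baseline_col) {
      bl <- dm$baseline_values[as.integer(dm$subject), j]
      if (dm$spec$baseline_center_ancova) {
        m0 <- mean(dm$baseline_values[, j], na.rm = TRUE)
        bl <- bl - m0
        yj <- yj - m0
      }
      Xj[, ".baseline"] <- bl
      yj[is.na(bl)] <- NA  # subjects missing baseline are excluded
    }
    f <- tryCatch(
      fit_single_response(yj, Xj, dm$subject,
                          random_intercept = dm$spec$random_intercept,
                          method = method),
      error = function(e) e
    )
    if (inherits(f, "error")) {
      if (on_error == "stop") {
        stop("fit failed for variable ", vars[j], ": ", conditionMessage(f))
      }
      failed[vars[j]] <- conditionMessage(f)
      next
    }
    B[, j] <- f$beta[colnames(X)]
    U[, j] <- f$u
    E[, j] <- f$residuals
    var_u[j] <- f$sigma_u2
    var_e[j] <- f$sigma_e2
    loglik[j] <- f$loglik
    n_used[j] <- f$n_used
    boundary[j] <- f$boundary
  }
  if (length(failed) == length(vars)) {
    stop("all variables failed to fit; first error: ", failed[1])
  }

  structure(list(B = B, U = U, E = E, var_u = var_u, var_e = var_e,
                 loglik = loglik, n_used = n_used, boundary = boundary,
                 fit_method = method, design = dm, failed = failed),
            class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat(sprintf("<rm_fit> %s model, %d fixed effects x %d variable(s), %d model rows\n",
              x$design$spec$family, nrow(x$B), ncol(x$B), nrow(x$E)))
  cat(sprintf("fit method: %s; random intercept: %s\n", x$fit_method,
              x$design$spec$random_intercept))
  if (length(x$failed) > 0) {
    cat("failed variables:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export fixed-effect coefficients and variance components as a tidy table
#'
#' One row per (variable, coefficient), plus per-variable variance
#' components — the univariate companion table to the multivariate
#' decomposition.
#'
#' @param fm an `rm_fit`.
#' @return A tibble with columns `variable`, `term`, `family`,
#'   `estimate`, `sigma_u2`, `sigma_e2`, `loglik`, `n_used`.
#' @export
coefficient_table <- function(fm) {
  stopifnot(inherits(fm, "rm_fit"))
  vars <- colnames(fm$B)
  terms <- rownames(fm$B)
  tibble::tibble(
    variable = rep(vars, each = length(terms)),
    term = rep(terms, times = length(vars)),
    family = rep(unname(fm$design$column_families[terms]), times = length(vars)),
    estimate = as.vector(fm$B),
    sigma_u2 = rep(unname(fm$var_u), each = length(terms)),
    sigma_e2 = rep(unname(fm$var_e), each = length(terms)),
    loglik = rep(unname(fm$loglik), each = length(terms)),
    n_used = rep(unname(fm$n_used), each = length(terms))
  )
}
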
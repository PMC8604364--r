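# Synthetic longitudinal multivariate data from the random-intercept
# generative model Y = X B + Z gamma + E, with known ground truth and
# configurable MCAR/MAR missingness.

#' Configure a synthetic longitudinal study
#'
#' Ground truth is specified as a coefficient matrix `B_true` on the
#' unconstrained repeated-measures coding (intercept, reference-coded
#' time with baseline as reference, group under `group_coding`, and
#' time-by-group products, group-major), so simulated truth and fitted
#' estimates are directly comparable. Use [cell_means_to_coefficients()]
#' to derive `B_true` from per-cell expected values.
#'
#' @param subjects_per_group integer vector, one count per group.
#' @param K number of timepoints (first level is baseline).
#' @param J number of response variables.
#' @param B_true p x J coefficient matrix, `p = 1 + (K-1) + (H-1) +
#'   (K-1)(H-1)` (group rows present only when H > 1).
#' @param sigma_u subject random-intercept SD (scalar or length-J).
#' @param sigma_e residual SD (scalar or length-J).
#' @param missing missingness mechanism: `list(mechanism = "none")`;
#'   `list(mechanism = "mcar", rate = r)` with `r` a scalar or length-K
#'   per-timepoint rate (baseline missable via a nonzero first entry); or
#'   `list(mechanism = "mar", intercept = a, slope = b)` where each
#'   post-baseline cell of variable j is dropped with probability
#'   `plogis(a + b * baseline_j)` — missing at random given the observed
#'   baseline.
#' @param group_coding [coding_scheme()] used to interpret the group rows
#'   of `B_true`.
#' @param group_levels,time_levels,variable_names optional labels.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(subjects_per_group, K, J, B_true,
                              sigma_u = 1, sigma_e = 1,
                              missing = list(mechanism = "none"),
                              group_coding = coding_scheme("sum"),
                              group_levels = NULL, time_levels = NULL,
                              variable_names = NULL) {
  H <- length(subjects_per_group)
  stopifnot(K >= 2, J >= 1, H >= 1, all(subjects_per_group >= 1))
  stopifnot(all(sigma_u >= 0), all(sigma_e >= 0))
  p <- 1 + (K - 1) + (H > 1) * (H - 1) + (H > 1) * (K - 1) * (H - 1)
  B_true <- as.matrix(B_true)
  if (nrow(B_true) != p || ncol(B_true) != J) {
    stop(sprintf("B_true must be %d x %d for K = %d, H = %d, J = %d",
                 p, J, K, H, J))
  }
  if (missing$mechanism == "mcar") {
    if (any(missing$rate < 0 | missing$rate > 1)) {
      stop("MCAR rate must lie in [0, 1]")
    }
  }
  structure(list(
    subjects_per_group = subjects_per_group, K = K, J = J, H = H,
    B_true = B_true,
    sigma_u = rep_len(sigma_u, J), sigma_e = rep_len(sigma_e, J),
    missing = missing, group_coding = group_coding,
    group_levels = group_levels %||% paste0("g", seq_len(H)),
    time_levels = time_levels %||% paste0("t", seq_len(K) - 1),
    variable_names = variable_names %||% paste0("V", seq_len(J))
  ), class = "simulation_config")
}

#' Generate a dataset from the random-intercept generative model
#'
#' Draws per-subject intercepts `gamma_i ~ N(0, sigma_u^2)` and residuals
#' `e ~ N(0, sigma_e^2)`, sets `Y = X B_true + Z gamma + E` on the full
#' subjects x timepoints grid, and applies the configured missingness.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; generation is reproducible given the seed.
#' @return A list with `dataset` (a `longitudinal_dataset`) and `truth`
#'   (list with `B`, `column_families`, `gamma`, `X`, the complete
#'   response matrix `Y_complete`, and the config).
#' @export
generate_dataset <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  I <- sum(cfg$subjects_per_group)
  subj <- paste0("s", formatC(seq_len(I), width = nchar(I), flag = "0"))
  grp <- rep(cfg$group_levels, cfg$subjects_per_group)
  subject <- rep(subj, each = cfg$K)
  group <- rep(grp, each = cfg$K)
  time <- rep(cfg$time_levels, times = I)

  skeleton <- longitudinal_dataset(
    subject = subject, time = time, group = group,
    responses = matrix(0, I * cfg$K, cfg$J,
                       dimnames = list(NULL, cfg$variable_names)),
    time_levels = cfg$time_levels, group_levels = cfg$group_levels
  )
  spec <- model_spec("rm_unconstrained", group_coding = cfg$group_coding)
  dm <- build_design(skeleton, spec)

  gamma <- matrix(stats::rnorm(I * cfg$J), I, cfg$J) %*% diag(cfg$sigma_u, cfg$J)
  E <- matrix(stats::rnorm(I * cfg$K * cfg$J), I * cfg$K, cfg$J) %*%
    diag(cfg$sigma_e, cfg$J)
  Y <- dm$X %*% cfg$B_true + as.matrix(dm$Z %*% gamma) + E
  dimnames(Y) <- list(NULL, cfg$variable_names)
  dimnames(gamma) <- list(subj, cfg$variable_names)

  skeleton$responses <- Y
  ds <- skeleton
  if (cfg$missing$mechanism != "none") {
    ds <- apply_missingness(ds, cfg)
  }
  rownames(cfg$B_true) <- colnames(dm$X)
  list(dataset = ds,
       truth = list(B = cfg$B_true, column_families = dm$column_families,
                    gamma = gamma, X = dm$X, Y_complete = Y, config = cfg))
}

#' Apply the configured missingness mechanism to a complete dataset
#'
#' MCAR drops each cell independently at the stated rate (per-timepoint
#' rates supported, so baseline missingness can be emulated). MAR drops
#' each post-baseline cell of variable j with probability
#' `plogis(intercept + slope * baseline_j)` — a logistic function of the
#' subject's observed baseline value of the same variable, so the
#' mechanism is missing-at-random given observed data; baseline rows are
#' never dropped under MAR.
#'
#' @param ds a `longitudinal_dataset`.
#' @param cfg a [simulation_config()] whose `missing` mechanism is not
#'   `"none"`.
#' @return The dataset with response cells set to `NA`.
#' @export
apply_missingness <- function(ds, cfg) {
  mech <- cfg$missing$mechanism
  Y <- ds$responses
  K_levels <- levels(ds$time)
  if (mech == "mcar") {
    rate <- cfg$missing$rate
    if (any(rate < 0 | rate > 1)) stop("MCAR rate must lie in [0, 1]")
    rate <- if (length(rate) == 1) rep(rate, length(K_levels)) else
      rep_len(rate, length(K_levels))
    row_rate <- rate[as.integer(ds$time)]
    if (identical(cfg$missing$unit %||% "cell", "record")) {
      # whole samples go missing (e.g. a biopsy not taken)
      drop_row <- stats::runif(nrow(Y)) < row_rate
      Y[drop_row, ] <- NA
    } else {
      drop <- matrix(stats::runif(length(Y)) < row_rate, nrow(Y), ncol(Y))
      Y[drop] <- NA
    }
  } else if (mech == "mar") {
    a <- cfg$missing$intercept
    b <- cfg$missing$slope
    base_rows <- which(ds$time == K_levels[1])
    baseline <- matrix(NA_real_, nlevels(ds$subject), ncol(Y))
    baseline[as.integer(ds$subject[base_rows]), ] <- Y[base_rows, , drop = FALSE]
    follow <- ds$time != K_levels[1]
    pr <- stats::plogis(a + b * baseline[as.integer(ds$subject), , drop = FALSE])
    drop <- follow & (matrix(stats::runif(length(Y)), nrow(Y)) < pr)
    drop[is.na(drop)] <- FALSE
    Y[drop] <- NA
  } else {
    stop("unknown missingness mechanism: ", mech)
  }
  ds$responses <- Y
  ds
}

#' Convert per-cell expected values into model coefficients
#'
#' Maps a K x H x J array of cell means onto the unconstrained
#' repeated-measures coding, by solving the cell-level design for the
#' coefficients.
#'
#' @param means K x H x J array (time x group x variable) of expected
#'   values.
#' @param group_coding a [coding_scheme()].
#' @return A p x J coefficient matrix usable as `B_true`.
#' @export
cell_means_to_coefficients <- function(means, group_coding = coding_scheme("sum")) {
  d <- dim(means)
  stopifnot(length(d) == 3)
  K <- d[1]; H <- d[2]; J <- d[3]
  tl <- paste0("t", seq_len(K) - 1)
  gl <- paste0("g", seq_len(H))
  cells <- longitudinal_dataset(
    subject = rep(gl, each = K),  # one pseudo-subject per group
    time = rep(tl, times = H), group = rep(gl, each = K),
    responses = matrix(0, K * H, 1),
    time_levels = tl, group_levels = gl
  )
  dm <- build_design(cells, model_spec("rm_unconstrained",
                                       group_coding = group_coding))
  Ymeans <- matrix(aperm(means, c(1, 2, 3)), K * H, J)
  qr.solve(dm$X, Ymeans)
}

#' Preset simulation scenarios
#'
#' Two shapes mirroring common clinical-trial metabolomics designs:
#' * `"neoava_like"` — 2 randomized groups of 62 and 60 subjects, 3
#'   timepoints, 16 variables, reference-coded group, MCAR missingness
#'   of 14/36/29% by timepoint. Half the variables drift downward over
#'   time and half upward (magnitudes 0.4–1.2 baseline-SD units by the
#'   final timepoint), and the treated group's change is amplified by 50%.
#' * `"bariatric_like"` — 3 non-randomized groups of 60/27/19 subjects, 5
#'   timepoints, 21 variables, sum-coded group (third group omitted),
#'   MCAR missingness 0/7/8/12/32%. Variables mix a sustained step
#'   response with a transient post-intervention response, and the first
#'   group diverges on a subset of variables.
#'
#' Both use `sigma_u = 0.7` and `sigma_e = 0.7`, giving a baseline
#' between-subject SD near 1 (the scale of baseline-SD-standardized
#' data).
#'
#' @param name preset name.
#' @return A [simulation_config()].
#' @export
simulation_preset <- function(name = c("neoava_like", "bariatric_like")) {
  name <- match.arg(name)
  if (name == "neoava_like") {
    K <- 3; H <- 2; J <- 16
    sgn <- rep(c(-1, 1), length.out = J)
    mag <- seq(0.4, 1.2, length.out = J)
    time2 <- sgn * mag          # change from baseline at final timepoint
    time1 <- 0.5 * time2        # halfway at the mid timepoint
    B <- rbind(
      0,                        # intercept
      time1, time2,             # time main effects (reference group)
      0,                        # group main effect at baseline (randomized)
      0.5 * time1, 0.5 * time2  # treated group changes 50% more
    )
    simulation_config(
      subjects_per_group = c(62, 60), K = K, J = J, B_true = B,
      sigma_u = 0.7, sigma_e = 0.7,
      missing = list(mechanism = "mcar", rate = c(0.14, 0.36, 0.29),
                     unit = "record"),
      group_coding = coding_scheme("reference", "control"),
      group_levels = c("control", "treatment"),
      variable_names = paste0("met", seq_len(J))
    )
  } else {
    K <- 5; H <- 3; J <- 21
    step <- rep(c(-1, 1, -0.5, 0.8, 0.3, -0.8, 0.6), length.out = J)
    transient <- rep(c(0.6, 0, -0.4), length.out = J)
    tmain <- rbind(0.9 * step + transient,        # t1
                   step + 0.6 * transient,        # t2
                   step + 0.3 * transient,        # t3
                   step)                          # t4
    # group 1 ("distal") diverges on a subset of variables over time
    div <- rep(c(0.5, 0, 0), length.out = J)
    int_g1 <- outer(seq(0.25, 1, length.out = K - 1), div)
    int_g2 <- matrix(0, K - 1, J)
    B <- rbind(0,                       # intercept
               tmain,                   # time
               matrix(0, 2, J),         # group baseline differences
               int_g1, int_g2)          # time-by-group (group-major)
    simulation_config(
      subjects_per_group = c(60, 27, 19), K = K, J = J, B_true = B,
      sigma_u = 0.7, sigma_e = 0.7,
      missing = list(mechanism = "mcar", rate = c(0, 0.07, 0.08, 0.12, 0.32),
                     unit = "record"),
      group_coding = coding_scheme("sum", "sleeve"),
      group_levels = c("distal", "proximal", "sleeve"),
      variable_names = paste0("met", seq_len(J))
    )
  }
}
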
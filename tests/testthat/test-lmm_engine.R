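# Column-wise mixed-model fitting: oracles and model-family equivalences.

test_that("noiseless data return the generating coefficients exactly", {
  B <- matrix(c(1, 2, -1, 0, 0, 0), 6, 1)
  sim <- balanced_sim(I_per_group = 6, K = 3, J = 1,
                      sigma_u = 0, sigma_e = 0, B = B)
  dm <- build_design(sim$dataset,
                     model_spec("rm_unconstrained",
                                group_coding = coding_scheme("reference", "g1")))
  f <- fit_single_response(dm$responses[, 1], dm$X, dm$subject)
  expect_equal(unname(f$beta), c(1, 2, -1, 0, 0, 0), tolerance = 1e-8)
  expect_lt(f$sigma_e2, 1e-10)
})

test_that("mixed-model fixed effects equal OLS on balanced complete data", {
  sim <- balanced_sim(I_per_group = 15, K = 3, J = 3, seed = 11)
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("reference", "g1"))
  fm <- fit_multivariate(sim$dataset, spec)
  dm <- fm$design
  for (j in 1:3) {
    ols <- qr.solve(dm$X, dm$responses[, j])
    expect_equal(unname(fm$B[, j]), unname(ols), tolerance = 1e-6)
  }
})

test_that("variance components match the one-way ANOVA method of moments", {
  # balanced one-way layout: intercept-only X, I = 50 subjects x K = 4
  I <- 50; K <- 4
  set.seed(202)
  gamma <- rnorm(I, sd = 1)
  y <- rep(gamma, each = K) + rnorm(I * K, sd = 1) + 3
  subject <- factor(rep(seq_len(I), each = K))
  X <- matrix(1, I * K, 1, dimnames = list(NULL, "(Intercept)"))

  # independent oracle: classical random-effects ANOVA table
  subj_means <- tapply(y, subject, mean)
  ms_between <- K * sum((subj_means - mean(y))^2) / (I - 1)
  ms_within <- sum((y - subj_means[subject])^2) / (I * (K - 1))
  mom_u2 <- (ms_between - ms_within) / K
  mom_e2 <- ms_within

  f <- fit_single_response(y, X, subject, method = "ML")
  expect_equal(f$sigma_u2, mom_u2, tolerance = 0.1)
  expect_equal(f$sigma_e2, mom_e2, tolerance = 0.1)
  expect_equal(unname(f$beta), mean(y), tolerance = 0.05)
})

test_that("missing responses are dropped per variable, not listwise", {
  sim <- balanced_sim(I_per_group = 10, K = 3, J = 2, seed = 5)
  ds <- sim$dataset
  # variable 1 heavily missing at the last timepoint
  gone <- which(ds$time == "t2")[c(1:5, 11:15)]  # five subjects per group
  ds$responses[gone, 1] <- NA
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("reference", "g1"))
  fm <- suppressWarnings(fit_multivariate(ds, spec))
  expect_equal(unname(fm$n_used), c(50L, 60L))
  expect_true(all(is.na(fm$E[gone, 1])))
  expect_false(anyNA(fm$E[, 2]))
  expect_false(anyNA(fm$B[c("(Intercept)", "timet1"), 1]))
})

test_that("rank deficiency after dropping rows names the collinear columns", {
  sim <- balanced_sim(I_per_group = 8, K = 3, J = 1, seed = 9)
  ds <- sim$dataset
  ds$responses[ds$time == "t2", 1] <- NA  # time t2 column becomes all-zero
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("reference", "g1"))
  expect_error(fit_multivariate(ds, spec), "rank deficient.*timet2")
})

test_that("residuals satisfy the model identity on used rows", {
  sim <- balanced_sim(I_per_group = 12, K = 3, J = 2, seed = 21)
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("reference", "g1"))
  fm <- fit_multivariate(sim$dataset, spec)
  dm <- fm$design
  for (j in 1:2) {
    recon <- dm$X %*% fm$B[, j] + as.matrix(dm$Z %*% fm$U[, j]) + fm$E[, j]
    expect_equal(unname(recon[, 1]), unname(dm$responses[, j]),
                 tolerance = 1e-8)
  }
  expect_true(all(fm$var_u >= 0))
  expect_true(all(fm$var_e > 0))
})

test_that("the ANCOVA baseline coefficient differs per response", {
  sim <- balanced_sim(I_per_group = 15, K = 3, J = 3, seed = 31)
  spec <- model_spec("ancova", group_coding = coding_scheme("reference", "g1"))
  fm <- fit_multivariate(sim$dataset, spec)
  bl <- fm$B[".baseline", ]
  expect_gt(stats::sd(bl), 0)
  # a subject with missing baseline is excluded for that response only
  ds <- sim$dataset
  base_row <- which(ds$subject == levels(ds$subject)[1] & ds$time == "t0")
  ds$responses[base_row, 1] <- NA
  fm2 <- fit_multivariate(ds, spec)
  expect_equal(unname(fm2$n_used[1]), unname(fm$n_used[1]) - 2L)
  expect_equal(unname(fm2$n_used[2]), unname(fm$n_used[2]))
})

test_that("unconstrained interaction estimates equal analysis-of-changes estimates", {
  # complete balanced data; reference-coded group in both families
  sim <- balanced_sim(I_per_group = 20, K = 3, J = 2, seed = 41)
  gref <- coding_scheme("reference", "g1")
  fm_uc <- fit_multivariate(sim$dataset, model_spec("rm_unconstrained",
                                                    group_coding = gref))
  fm_ch <- fit_multivariate(sim$dataset, model_spec("changes",
                                                    group_coding = gref))
  for (j in 1:2) {
    # group difference in change at first and second follow-up
    uc <- unname(fm_uc$B[c("timet1:groupg2", "timet2:groupg2"), j])
    ch <- unname(c(fm_ch$B["groupg2", j],
                   fm_ch$B["groupg2", j] + fm_ch$B["timet2:groupg2", j]))
    expect_equal(uc, ch, tolerance = 1e-6)
  }
})

test_that("changes with the baseline added as covariate reduces to ANCOVA", {
  # replacing follow-up responses by changes and then fitting ANCOVA (which
  # adds the baseline covariate) must reproduce the ANCOVA group effects
  sim <- balanced_sim(I_per_group = 15, K = 3, J = 1, seed = 51)
  ds <- sim$dataset
  gref <- coding_scheme("reference", "g1")
  fm_anc <- fit_multivariate(ds, model_spec("ancova", group_coding = gref))

  ds_diff <- ds
  base <- ds$responses[ds$time == "t0", 1][as.integer(ds$subject)]
  follow <- ds$time != "t0"
  ds_diff$responses[follow, 1] <- ds$responses[follow, 1] - base[follow]
  fm_diff <- fit_multivariate(ds_diff, model_spec("ancova", group_coding = gref))

  keep <- c("groupg2", "timet2:groupg2")
  expect_equal(unname(fm_diff$B[keep, 1]), unname(fm_anc$B[keep, 1]),
               tolerance = 1e-6)
  expect_equal(unname(fm_diff$B[".baseline", 1]),
               unname(fm_anc$B[".baseline", 1]) - 1, tolerance = 1e-6)
})

test_that("constrained-model interaction approaches the ANCOVA group effect", {
  # two timepoints, large I: the two baseline-adjustment routes agree
  B <- matrix(c(0.3, 0.5, 0.4), 3, 1)  # intercept, time, time x group
  cfg <- simulation_config(subjects_per_group = c(1000, 1000), K = 2, J = 1,
                           B_true = rbind(B[1], B[2], 0, B[3]),
                           sigma_u = 1, sigma_e = 1,
                           group_coding = coding_scheme("reference", "g1"))
  sim <- generate_dataset(cfg, seed = 61)
  gref <- coding_scheme("reference", "g1")
  fm_clda <- fit_multivariate(sim$dataset,
                              model_spec("rm_constrained", group_coding = gref))
  fm_anc <- fit_multivariate(sim$dataset,
                             model_spec("ancova", group_coding = gref))
  expect_lt(abs(fm_clda$B["timet1:groupg2", 1] - fm_anc$B["groupg2", 1]), 0.05)
})

test_that("a boundary variance estimate warns rather than errors", {
  # no subject-level variance at all: sigma_u is estimated at zero
  set.seed(77)
  I <- 30; K <- 3
  y <- rnorm(I * K)
  subject <- factor(rep(seq_len(I), each = K))
  X <- matrix(1, I * K, 1, dimnames = list(NULL, "(Intercept)"))
  expect_warning(f <- fit_single_response(y, X, subject), "zero boundary")
  expect_equal(f$sigma_u2, 0)
})

test_that("mostly single-row subjects trigger the identifiability warning", {
  sim <- balanced_sim(I_per_group = 10, K = 3, J = 1, seed = 91)
  ds <- sim$dataset
  keep <- !duplicated(ds$subject) | ds$subject %in% c("s01", "s11")
  ds2 <- longitudinal_dataset(
    subject = as.character(ds$subject)[keep],
    time = as.character(ds$time)[keep],
    group = as.character(ds$group)[keep],
    responses = ds$responses[keep, , drop = FALSE],
    time_levels = levels(ds$time))
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("reference", "g1"))
  expect_warning(suppressMessages(fit_multivariate(ds2, spec)),
                 "single row")
})
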
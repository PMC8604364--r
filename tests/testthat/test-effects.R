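# Effect-matrix construction, combination, augmentation, and the
# Frobenius variance decomposition.

fit_two_group <- function(seed = 7, family = "rm_unconstrained",
                          coding = coding_scheme("sum", "g1"),
                          I = 12, K = 3, J = 3) {
  sim <- balanced_sim(I_per_group = I, K = K, J = J, seed = seed,
                      group_coding = coding)
  list(sim = sim, fm = fit_multivariate(sim$dataset,
                                        model_spec(family, group_coding = coding)))
}

test_that("baseline rows of time-family effect matrices are exactly zero", {
  fw <- fit_two_group()
  for (fams in list("time", "time:group", c("time", "time:group"))) {
    m <- construct_effect_matrix(fw$fm, fams)
    base <- m$time == levels(m$time)[1]
    expect_true(all(m$M[base, ] == 0))
  }
})

test_that("all-family effect matrix equals the fixed-effect fitted values", {
  fw <- fit_two_group()
  fams <- unique(fw$fm$design$column_families)
  m <- construct_effect_matrix(fw$fm, fams)
  fitted <- fw$fm$design$X %*% fw$fm$B
  expect_equal(m$M, fitted, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("singleton-family matrices sum to the all-family matrix", {
  fw <- fit_two_group()
  fams <- unique(fw$fm$design$column_families)
  singles <- lapply(fams, construct_effect_matrix, fm = fw$fm)
  total <- Reduce(`+`, lapply(singles, `[[`, "M"))
  all_m <- construct_effect_matrix(fw$fm, fams)$M
  expect_equal(total, all_m, tolerance = 1e-12)
  # and the combinator produces the same sum with union families
  comb <- combine_effect_matrices(singles)
  expect_equal(comb$M, all_m, tolerance = 1e-12)
  expect_setequal(comb$families, fams)
})

test_that("combination requires disjoint families and matching dimensions", {
  fw <- fit_two_group()
  mt <- construct_effect_matrix(fw$fm, "time")
  expect_error(combine_effect_matrices(mt, mt), "overlap")
  expect_error(construct_effect_matrix(fw$fm, character(0)),
               "at least one effect family")
  expect_error(construct_effect_matrix(fw$fm, "baseline"),
               "not in the fitted design")
  # triangle inequality sanity check on Frobenius norms
  mtg <- construct_effect_matrix(fw$fm, "time:group")
  comb <- combine_effect_matrices(mt, mtg)
  expect_lte(sqrt(sum(comb$M^2)),
             sqrt(sum(mt$M^2)) + sqrt(sum(mtg$M^2)) + 1e-12)
})

test_that("under the constrained model predicted baseline means are group-invariant", {
  fw <- fit_two_group(family = "rm_constrained",
                      coding = coding_scheme("reference", "g1"))
  expect_false("group" %in% fw$fm$design$column_families)
  fams <- unique(fw$fm$design$column_families)
  pred <- construct_effect_matrix(fw$fm, fams)$M
  base <- fw$fm$design$time == "t0"
  by_group <- apply(pred[base, , drop = FALSE], 2,
                    function(col) tapply(col, fw$fm$design$group[base], mean))
  expect_equal(by_group["g1", ], by_group["g2", ], tolerance = 1e-10)
})

test_that("augmentation adds ZU and E and flags missing residual cells", {
  fw <- fit_two_group()
  fm <- fw$fm
  m <- construct_effect_matrix(fm, c("time", "time:group"))
  # noiseless model: augmenting changes nothing
  B <- matrix(c(1, 0.5, -0.3, 0, 0, 0), 6, 1)
  sim0 <- balanced_sim(I_per_group = 5, K = 3, J = 1, sigma_u = 0,
                       sigma_e = 0, B = B,
                       group_coding = coding_scheme("sum", "g1"))
  fm0 <- suppressWarnings(
    fit_multivariate(sim0$dataset, model_spec(group_coding = coding_scheme("sum", "g1"))))
  m0 <- construct_effect_matrix(fm0, c("time", "time:group"))
  aug0 <- augment_effect_matrix(m0, fm0, TRUE, TRUE)
  expect_equal(aug0$M, m0$M, tolerance = 1e-6)

  # random-only augmentation shifts each subject by a constant per response
  aug_r <- augment_effect_matrix(m, fm, with_random = TRUE,
                                 with_residuals = FALSE)
  offs <- aug_r$M - m$M
  for (s in levels(droplevels(fm$design$subject))) {
    rows <- which(fm$design$subject == s)
    expect_equal(offs[rows, , drop = FALSE],
                 offs[rep(rows[1], length(rows)), , drop = FALSE],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # full augmentation reconstructs the centered data identity:
  # M_T + M_TxG + ZU + E = Y - M_0 - M_G on observed rows
  aug <- augment_effect_matrix(m, fm, TRUE, TRUE)
  rest <- construct_effect_matrix(fm, c("intercept", "group"))$M
  expect_equal(aug$M + rest, fm$design$responses,
               ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(augment_effect_matrix(aug, fm), "already augmented")
})

test_that("missing residual cells contribute zero and are flagged", {
  sim <- balanced_sim(I_per_group = 10, K = 3, J = 2, seed = 13)
  ds <- sim$dataset
  ds$responses[2, 1] <- NA
  fm <- fit_multivariate(ds, model_spec(group_coding = coding_scheme("sum", "g1")))
  m <- construct_effect_matrix(fm, "time")
  aug <- augment_effect_matrix(m, fm, with_random = FALSE, with_residuals = TRUE)
  expect_true(aug$missing_rows[2])
  expect_equal(sum(aug$missing_rows), 1L)
  aug_known <- aug$M[2, 2] - m$M[2, 2]
  expect_equal(aug_known, fm$E[2, 2])
  expect_equal(aug$M[2, 1], m$M[2, 1])  # zero contribution for the NA cell
})

test_that("the Frobenius decomposition is exact for balanced sum-coded GLM fits", {
  sim <- balanced_sim(I_per_group = 10, K = 3, J = 3, seed = 17,
                      sigma_u = 0, sigma_e = 1,
                      group_coding = coding_scheme("sum", "g1"))
  ds <- sim$dataset
  # fixed-effects-only fit with fully sum-coded factors
  spec <- model_spec("rm_unconstrained",
                     group_coding = coding_scheme("sum", "g1"),
                     random_intercept = FALSE)
  fm <- fit_multivariate(ds, spec)
  # rebuild with sum-coded time for the orthogonality claim
  dm <- fm$design
  tlev <- levels(ds$time)
  Tm <- encode_factor(tlev, ds$time, coding_scheme("sum", tlev[1]))
  Gm <- encode_factor(levels(ds$group), ds$group, coding_scheme("sum", "g1"))
  X <- cbind(1, Tm, Gm, Tm * as.vector(Gm))
  M_parts <- list(intercept = 1:1, time = 2:3, group = 4, tg = 5:6)
  beta <- qr.solve(X, ds$responses)
  Y <- ds$responses
  norms <- vapply(M_parts, function(ix) {
    sum((X[, ix, drop = FALSE] %*% beta[ix, , drop = FALSE])^2)
  }, numeric(1))
  Ehat <- Y - X %*% beta
  discrepancy <- sum(Y^2) - sum(norms) - sum(Ehat^2)
  expect_lt(abs(discrepancy), 1e-8 * sum(Y^2))
})

test_that("reference-coded time yields a reported nonzero discrepancy", {
  sim <- balanced_sim(I_per_group = 10, K = 3, J = 3, seed = 19,
                      group_coding = coding_scheme("sum", "g1"))
  fm <- fit_multivariate(sim$dataset,
                         model_spec(group_coding = coding_scheme("sum", "g1")))
  vd <- variance_decomposition(fm)
  expect_true(all(c("intercept", "time", "group", "time:group",
                    "random_effects", "residual") %in% vd$term))
  expect_gt(abs(attr(vd, "discrepancy")), 1e-6 * attr(vd, "total"))
  expect_equal(attr(vd, "n_rows"), nrow(sim$dataset$responses))
})

test_that("a zero response matrix decomposes into all-zero terms", {
  sim <- balanced_sim(I_per_group = 5, K = 3, J = 2, seed = 23,
                      group_coding = coding_scheme("sum", "g1"))
  ds <- sim$dataset
  ds$responses[] <- 0
  fm <- suppressWarnings(
    fit_multivariate(ds, model_spec(group_coding = coding_scheme("sum", "g1"))))
  vd <- variance_decomposition(fm)
  expect_equal(vd$frobenius_sq, rep(0, nrow(vd)), tolerance = 1e-20)
  expect_equal(attr(vd, "total"), 0)
})

test_that("effect tables key rows by record or by design cell", {
  fw <- fit_two_group()
  m <- construct_effect_matrix(fw$fm, "time")
  tab_row <- effect_table(m, "row")
  expect_equal(nrow(tab_row), nrow(m$M) * ncol(m$M))
  tab_cell <- effect_table(m, "cell")
  expect_equal(nrow(tab_cell), 6 * ncol(m$M))  # 3 times x 2 groups
  # cell values match the unique row values
  v1 <- tab_cell$value[tab_cell$time == "t1" & tab_cell$group == "g1" &
                         tab_cell$variable == colnames(m$M)[1]]
  rows <- which(fw$fm$design$time == "t1" & fw$fm$design$group == "g1")
  expect_equal(v1, unname(m$M[rows[1], 1]))
})
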
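test_that("the in-law inflation factor is the defining ratio", {
  expect_equal(iif(0.5, 0.4, 0.2), 1)
  expect_equal(round(iif(0.42, 0.52, 0.29), 2), 1.33)
  # rounded published inputs can differ in the second decimal from a ratio
  # computed on unrounded estimates
  expect_equal(round(iif(0.48, 0.40, 0.29), 2), 1.51)
  expect_true(is.na(iif(0, 0.4, 0.2)))
  expect_equal(iif(c(0.5, 0.3), c(0.4, 0.5), c(0.2, 0.3)), c(1, 2))
})

test_that("path-traced expectations match the printed mechanism algebra", {
  d <- expected_relative_correlations(mechanism_params("direct", m = 0.5, r_s = 0.4))
  expect_equal(unlist(d[c("r_partner", "r_sibling", "r_inlaw", "iif")]),
               c(r_partner = 0.5, r_sibling = 0.4, r_inlaw = 0.2, iif = 1))
  i <- expected_relative_correlations(
    mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.5, r_e = 0))
  expect_equal(unlist(i[c("r_partner", "r_sibling", "r_inlaw", "iif")]),
               c(r_partner = 0.3, r_sibling = 0.25, r_inlaw = 0.15, iif = 2))
  s <- expected_relative_correlations(mechanism_params("stratification", q = 0.6))
  expect_equal(unlist(s[c("r_partner", "r_sibling", "r_inlaw")]),
               c(r_partner = 0.36, r_sibling = 0.36, r_inlaw = 0.36))
  expect_equal(s$iif, 1 / 0.36)
  # residual sibling similarity equal to the latent one restores IIF = 1
  eq <- expected_relative_correlations(
    mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.4, r_e = 0.4))
  expect_equal(eq$iif, 1)
  expect_error(mechanism_params("direct", m = 1.2, r_s = 0.4), "inside")
  expect_error(mechanism_params("indirect", a2 = 1.7, mu = 0.5, r_m = 0.5),
               "inside")
})

test_that("the quad model recovers a direct-assortment structure", {
  pop <- simulate_quads(mechanism_params("direct", m = 0.5, r_s = 0.4),
                        simulation_design(30000, seed = 201))
  fit <- fit_quad_model(pop, "trait")
  expect_true(fit$converged)
  s <- fit$structure
  expect_lt(abs(s$r_partner - 0.5), 3 * fit$se[["r_partner"]])
  expect_lt(abs(s$r_sibling - 0.4), 3 * fit$se[["r_sibling"]])
  expect_lt(abs(s$r_inlaw - 0.2), 3 * fit$se[["r_inlaw"]])
  expect_lt(abs(s$r_cosib - 0.4 * 0.5 * 0.4), 3 * fit$se[["r_cosib"]])
  con <- fit_quad_model(pop, "trait", constrained = TRUE, se = FALSE)
  expect_gte(fit$loglik + 1e-4, con$loglik)
  expect_equal(con$structure$r_inlaw,
               con$structure$r_partner * con$structure$r_sibling)
  tst <- lrt_direct_assortment(fit, con)
  expect_equal(tst$iif, iif(s$r_partner, s$r_sibling, s$r_inlaw))
  expect_gt(tst$p_raw, 0.001)
})

test_that("degenerate quad data raise a boundary error", {
  pop <- data.frame(trait_index = rep(1, 50), trait_partner = rep(1, 50),
                    trait_sib_index = rep(1, 50), trait_sib_partner = rep(1, 50))
  expect_error(fit_quad_model(pop, "trait"), "single value")
})

test_that("binary quad FIML recovers the liability structure", {
  pop <- simulate_quads(
    mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.5, r_e = 0),
    simulation_design(20000, list(trait_spec("dep", "binary", 0.0909)),
                      seed = 202))
  fit <- fit_quad_model(pop, "dep")
  expect_identical(fit$kind, "binary")
  expect_true(fit$converged)
  expect_lt(abs(fit$structure$r_partner - 0.30),
            3 * fit$se[["r_partner"]])
  expect_lt(abs(fit$structure$r_sibling - 0.25),
            3 * fit$se[["r_sibling"]])
  expect_lt(abs(fit$structure$r_inlaw - 0.15),
            3 * fit$se[["r_inlaw"]])
})

test_that("sex adjustment on thresholds leaves the correlations intact", {
  pop <- simulate_quads(mechanism_params("direct", m = 0.5, r_s = 0.4),
                        simulation_design(20000, seed = 203))
  # shift sibling means by sex to create a real threshold covariate
  for (role in c("sib_index", "sib_partner")) {
    col <- paste0("trait_", role)
    pop[[col]] <- pop[[col]] + 0.4 * pop[[paste0("sex_", role)]]
  }
  fit <- fit_quad_model(pop, "trait", adjust = "sex")
  expect_lt(abs(fit$structure$r_sibling - 0.4), 3 * fit$se[["r_sibling"]])
  raw <- fit_quad_model(pop, "trait", se = FALSE)
  # unadjusted, the sex shift leaks into the sibling correlation
  expect_lt(abs(fit$structure$r_sibling - 0.4),
            abs(raw$structure$r_sibling - 0.4) + 0.02)
})

test_that("LRT bookkeeping follows the chi-square(1) survival function", {
  free <- fake_quad_fit(-1000, constrained = FALSE)
  con <- fake_quad_fit(-1000, constrained = TRUE)
  t0 <- lrt_direct_assortment(free, con)
  expect_equal(t0$lrt_stat, 0)
  expect_equal(t0$p_raw, 1)
  con5 <- fake_quad_fit(-1005, constrained = TRUE)
  t1 <- lrt_direct_assortment(free, con5)
  expect_equal(t1$lrt_stat, 10)
  # chi-square(1) tail via the normal: P(chi2 > s) = 2*Phi(-sqrt(s))
  expect_equal(t1$p_raw, 2 * pnorm(-sqrt(10)), tolerance = 1e-12)
  expect_equal(t1$df, 1L)
  bad_con <- fake_quad_fit(-990, constrained = TRUE)
  expect_error(lrt_direct_assortment(free, bad_con), "refit")
  expect_error(lrt_direct_assortment(con, free), "free fit, constrained fit")
})

test_that("direct-assortment LRT holds its nominal size", {
  set.seed(204)
  reps <- 500
  params <- mechanism_params("direct", m = 0.5, r_s = 0.4)
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    pop <- simulate_quads(params, simulation_design(1500, seed = NULL))
    free <- fit_quad_model(pop, "trait", se = FALSE)
    con <- fit_quad_model(pop, "trait", constrained = TRUE, se = FALSE)
    pvals[i] <- lrt_direct_assortment(free, con)$p_raw
  }
  rej <- mean(pvals < 0.05)
  # binomial 3-sigma band around 0.05 at 500 replicates
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  # median of the null LRT sits near the chi-square(1) median
  stats <- qchisq(1 - pvals, 1)
  expect_lt(abs(median(stats) - qchisq(0.5, 1)), 0.12)
})

test_that("equality LRT distinguishes equal from unequal correlation sets", {
  set.seed(205)
  z1 <- rbvn(5000, 0.3); z2 <- rbvn(5000, 0.3)
  ea <- estimate_pearson(z1[, 1], z1[, 2])
  eb <- estimate_pearson(z2[, 1], z2[, 2])
  same <- lrt_equal_correlations(list(t1 = ea), list(t1 = eb))
  expect_equal(same$df, 1L)
  expect_gt(same$p, 0.05)
  # identical data: the common-r fit loses nothing
  self <- lrt_equal_correlations(list(t1 = ea), list(t1 = ea))
  expect_lt(self$stat, 0.01)
  z3 <- rbvn(5000, 0.55)
  ec <- estimate_pearson(z3[, 1], z3[, 2])
  diff <- lrt_equal_correlations(list(t1 = ea), list(t1 = ec))
  expect_lt(diff$p, 1e-6)
  # df bookkeeping: one constraint per trait
  multi <- lrt_equal_correlations(list(a = ea, b = eb, c = ec),
                                  list(a = eb, b = ea, c = ec))
  expect_equal(multi$df, 3L)
  expect_error(lrt_equal_correlations(list(a = ea), list(a = ea, b = eb)),
               "same traits")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  # hand-applied step-up: p_(i) * m / i with cumulative minimum from the top
  hand <- rev(cummin(rev(p * 6 / seq_len(6))))
  expect_equal(bh_adjust(p), hand)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})
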
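test_that("identical params, design, and seed give identical populations", {
  p <- mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.5, r_e = 0.1)
  d <- simulation_design(2000, list(trait_spec("dep", "binary", 0.09)), seed = 301)
  expect_identical(simulate_quads(p, d), simulate_quads(p, d))
  expect_identical(skewed_liability(p, d, -0.5), skewed_liability(p, d, -0.5))
})

test_that("dichotomization hits the requested prevalence", {
  set.seed(302)
  z <- rnorm(100000)
  for (prev in c(0.016, 0.0909, 0.5)) {
    y <- dichotomize(z, prev)
    expect_lt(abs(mean(y) - prev), 3 * sqrt(prev * (1 - prev) / 1e5))
  }
  expect_equal(dichotomize(c(-1, 1), 0.5), c(0L, 1L))  # threshold at the median
  expect_error(dichotomize(z, 0), "inside")
  # simulated binary traits inherit the calibration
  pop <- simulate_quads(mechanism_params("direct", m = 0.5, r_s = 0.4),
                        simulation_design(50000,
                          list(trait_spec("su", "binary", 0.016),
                               trait_spec("dep", "binary", 0.0909)),
                          seed = 303))
  for (tr in c("su", "dep")) {
    prev <- if (tr == "su") 0.016 else 0.0909
    obs <- mean(pop[[paste0(tr, "_index")]], na.rm = TRUE)
    expect_lt(abs(obs - prev), 3 * sqrt(prev * (1 - prev) / 50000))
  }
})

test_that("simulated correlations match the path-traced expectations", {
  specs <- list(
    mechanism_params("direct", m = 0.5, r_s = 0.4),
    mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.5, r_e = 0),
    mechanism_params("indirect", a2 = 0.5, mu = 0.6, r_m = 0.4, r_e = 0.4),
    mechanism_params("stratification", q = 0.6))
  for (k in seq_along(specs)) {
    p <- specs[[k]]
    e <- expected_relative_correlations(p)
    pop <- simulate_quads(p, simulation_design(50000, seed = 310 + k,
                                               sibling_availability = 1))
    z <- as.matrix(pop[, paste0("trait_", quad_roles())])
    got <- c(cor(z[, 1], z[, 2]),
             mean(c(cor(z[, 1], z[, 3]), cor(z[, 2], z[, 4]))),
             mean(c(cor(z[, 1], z[, 4]), cor(z[, 2], z[, 3]))),
             cor(z[, 3], z[, 4]))
    want <- c(e$r_partner, e$r_sibling, e$r_inlaw, e$r_cosib)
    for (j in 1:4)
      expect_lt(abs(got[j] - want[j]), 3 * mc_se_cor(want[j], 50000) + 0.005)
  }
})

test_that("a zero copath removes partner and in-law similarity", {
  pop <- simulate_quads(mechanism_params("direct", m = 0, r_s = 0.4),
                        simulation_design(30000, seed = 320))
  expect_lt(abs(cor(pop$trait_index, pop$trait_partner)),
            3 * mc_se_cor(0, 30000))
  expect_lt(abs(cor(pop$trait_index, pop$trait_sib_partner,
                    use = "complete.obs")), 0.02)
})

test_that("sibling availability and missingness thin the expected roles", {
  d <- simulation_design(20000, sibling_availability = 0.7,
                         missingness = c(partner = 0.1), seed = 321)
  pop <- simulate_quads(mechanism_params("direct", m = 0.5, r_s = 0.4), d)
  expect_lt(abs(mean(!is.na(pop$trait_sib_index)) - 0.7), 0.015)
  expect_lt(abs(mean(!is.na(pop$trait_partner)) - 0.9), 0.01)
  expect_true(all(!is.na(pop$trait_index)))
})

test_that("the convergence overlay is the identity at zero and follows variance bookkeeping", {
  p <- mechanism_params("direct", m = 0.5, r_s = 0.4)
  pop <- simulate_quads(p, simulation_design(40000, seed = 322))
  expect_identical(overlay_convergence(pop, 0, 0), pop)
  # shared environment on top of independent partners: r = n2 / (1 + n2)
  pop0 <- simulate_quads(mechanism_params("direct", m = 0, r_s = 0.4),
                         simulation_design(40000, seed = 323))
  conv <- overlay_convergence(pop0, n2 = 0.2, x = 0)
  expect_lt(abs(cor(conv$trait_index, conv$trait_partner) - 0.2 / 1.2),
            3 * mc_se_cor(0.2 / 1.2, 40000) + 0.003)
  expect_lt(abs(cor(conv$trait_index, conv$trait_sib_partner,
                    use = "complete.obs")), 0.02)
  expect_lt(abs(sd(conv$trait_index) - 1), 0.02)  # re-standardized
})

test_that("convergence drives the in-law inflation factor below one", {
  p <- mechanism_params("direct", m = 0.5, r_s = 0.4)
  pop <- simulate_quads(p, simulation_design(60000, seed = 324))
  conv <- overlay_convergence(pop, n2 = 0.2, x = 0)
  fit <- fit_quad_model(conv, "trait", se = FALSE)
  s <- fit$structure
  expect_lt(iif(s$r_partner, s$r_sibling, s$r_inlaw), 0.95)
})

test_that("skewed liabilities carry the requested skew direction", {
  p <- mechanism_params("direct", m = 0.5, r_s = 0.4)
  d <- simulation_design(50000, seed = 325, sibling_availability = 1)
  skew <- function(v) mean(((v - mean(v)) / sd(v))^3)
  for (variant in c(FALSE, TRUE)) {
    left <- skewed_liability(p, d, skew_gamma = -0.8,
                             skew_innovations = variant)
    right <- skewed_liability(p, d, skew_gamma = 0.8,
                              skew_innovations = variant)
    expect_lt(skew(left$trait_index), -0.3)
    expect_gt(skew(right$trait_index), 0.3)
  }
  none <- skewed_liability(p, d, skew_gamma = 0)
  expect_lt(abs(skew(none$trait_index)), 0.05)
  expect_identical(as.data.frame(none)$trait_index,
                   as.data.frame(simulate_quads(p, d))$trait_index)
})

test_that("innovation skewing preserves the Pearson product identity exactly", {
  p <- mechanism_params("direct", m = 0.5, r_s = 0.4)
  d <- simulation_design(50000, seed = 326, sibling_availability = 1)
  left <- skewed_liability(p, d, skew_gamma = -0.8, skew_innovations = TRUE)
  # the chain index -> partner -> sib_partner is linear in the skewed
  # innovations, so r_ab * r_bc = r_ac on the liability scale
  r_ab <- cor(left$trait_index, left$trait_partner)
  r_bc <- cor(left$trait_partner, left$trait_sib_partner)
  r_ac <- cor(left$trait_index, left$trait_sib_partner)
  expect_lt(abs(r_ab * r_bc - r_ac), 3 * mc_se_cor(0.2, 50000))
})

test_that("multitrait populations follow the factor structure", {
  params <- mechanism_params("indirect", a = 0.5, mu = 0.7, r_m = 0.5, r_e = 0)
  traits <- data.frame(name = c("edu", "health"),
                       kind = c("continuous", "continuous"),
                       prevalence = NA, loading = c(0.8, 0.5),
                       r_sib_resid = c(0, 0))
  pop <- simulate_multitrait(traits, params,
                             simulation_design(60000, seed = 326))
  # partner health correlation = a_h * mu * a_h = 0.25 * 0.7
  expect_lt(abs(cor(pop$health_index, pop$health_partner) - 0.175),
            3 * mc_se_cor(0.175, 60000) + 0.003)
  # cross-trait partner correlation = a_e * mu * a_h
  expect_lt(abs(cor(pop$edu_index, pop$health_partner) - 0.8 * 0.7 * 0.5),
            3 * mc_se_cor(0.28, 60000) + 0.003)
  # zero loadings remove cross-trait partner similarity
  traits0 <- transform(traits, loading = 0)
  pop0 <- simulate_multitrait(traits0, params,
                              simulation_design(30000, seed = 327))
  expect_lt(abs(cor(pop0$edu_index, pop0$health_partner)), 0.02)
  expect_error(simulate_multitrait(transform(traits, loading = c(1.2, 0.5)),
                                   params, simulation_design(100, seed = 1)),
               "loadings")
})

test_that("two health traits with equal loadings match within- and cross-trait similarity", {
  params <- mechanism_params("indirect", a = 0.5, mu = 0.6, r_m = 0.5, r_e = 0)
  traits <- data.frame(name = c("h1", "h2"), kind = "continuous",
                       prevalence = NA, loading = 0.5, r_sib_resid = 0)
  pop <- simulate_multitrait(traits, params,
                             simulation_design(60000, seed = 328))
  within <- cor(pop$h1_index, pop$h1_partner)
  across <- cor(pop$h1_index, pop$h2_partner)
  expect_lt(abs(within - across), 0.02)
})

test_that("quad tables round-trip through CSV with metadata", {
  p <- mechanism_params("direct", m = 0.54, r_s = 0.37)
  pop <- simulate_quads(p, simulation_design(
    500, list(trait_spec("su", "binary", 0.016)), seed = 329))
  path <- withr::local_tempfile(fileext = ".csv")
  write_quads(pop, path)
  back <- read_quads(path)
  expect_equal(as.data.frame(pop), as.data.frame(back))
  expect_equal(attr(back, "params")$m, 0.54)
  expect_equal(attr(back, "design")$n_families, 500L)
  expect_equal(attr(back, "design")$traits[[1]]$prevalence, 0.016)
})

test_that("long-form quad tables pivot to the wide dialect", {
  pop <- data.frame(
    family_id = rep(1:3, each = 2),
    role = rep(c("index", "partner"), 3),
    dep = c(1, 0, 0, 0, NA, 1),
    sex = c(0, 1, 0, 1, 0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pop, path, row.names = FALSE, na = "")
  wide <- read_quads(path, format = "long")
  expect_equal(wide$dep_index, c(1, 0, NA))
  expect_equal(wide$dep_partner, c(0, 0, 1))
  expect_equal(wide$sex_partner, c(1, 1, 1))
})
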
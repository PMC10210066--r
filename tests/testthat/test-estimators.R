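mt2_rec <- function(conc = 1.7e-6) {
  multisite_receptor(mt_constants("mt2_ref32"), conc, "MT2")
}

par_lig <- function(conc) {
  competitor_ligand(7.1e-13, conc, stoich = 2, label = "PAR")
}

forward_transfer <- function(lig, mt_conc = 1.7e-6) {
  st <- solve_speciation(zn_system(mt2_rec(mt_conc), lig,
                                   total_metal = 7 * mt_conc))
  st$complex_conc[[1]]
}

test_that("stepwise estimator collapses to kd * t / L in the symmetric case", {
  lig <- competitor_ligand(1e-9, 1e-5, label = "C")
  obs <- competition_observation(1e-6, lig, transferred = 0.5e-6)
  est <- kd1_stepwise(obs)
  expect_equal(10^(-est$neg_log_kd),
               1e-9 * 0.5e-6 / (1e-5 - 0.5e-6), tolerance = 1e-12)
  expect_identical(est$model, "stepwise")
})

test_that("stepwise round trip through the solver recovers the weakest site", {
  est <- vapply(c(5e-6, 1e-5), function(pc) {
    t <- forward_transfer(par_lig(pc))
    kd1_stepwise(competition_observation(1.7e-6, par_lig(pc),
                                         transferred = t))$neg_log_kd
  }, 0)
  expect_equal(mean(est), -log10(2e-8), tolerance = 0.05)
})

test_that("stepwise estimator signals out-of-regime inputs", {
  lig <- par_lig(5e-6)
  expect_error(kd1_stepwise(competition_observation(1.7e-6, lig,
                                                    transferred = 0)),
               class = "zincomp_no_transfer")
  expect_error(kd1_stepwise(competition_observation(1.7e-6, lig,
                                                    transferred = 1.8e-6)),
               class = "zincomp_out_of_regime")
})

test_that("cooperative aggregate satisfies its defining equation", {
  # unit-free magnitudes where t^n does not underflow
  lig <- competitor_ligand(kd = 2, total_conc = 20, stoich = 1, label = "C")
  obs <- competition_observation(1, lig, transferred = 3, n_sites = 7)
  est <- kdav_cooperative(obs)
  apo <- 3 / 7
  agg <- 2^7 * 3^7 * apo / ((1 - apo) * (20 - 3)^7)
  expect_equal(10^est$details$log10_kd_aggregate, agg, tolerance = 1e-12)
  expect_equal(est$neg_log_kd, -log10(agg) / 7, tolerance = 1e-12)
  # literal divide-by-n reduction is available but distinct
  est2 <- kdav_cooperative(obs, reduction = "divide")
  expect_equal(10^(-est2$neg_log_kd), agg / 7, tolerance = 1e-12)
})

test_that("cooperative estimate lies between weakest and tightest site", {
  t <- forward_transfer(par_lig(2e-4))
  est <- kdav_cooperative(competition_observation(1.7e-6, par_lig(2e-4),
                                                  transferred = t))
  expect_gt(est$neg_log_kd, -log10(2e-8))
  expect_lt(est$neg_log_kd, -log10(1.6e-12))
})

test_that("cooperative -logKdav grows with competitor concentration", {
  concs <- c(2e-5, 5e-5, 1e-4, 2e-4, 4e-4)
  vals <- vapply(concs, function(pc) {
    t <- forward_transfer(par_lig(pc))
    kdav_cooperative(competition_observation(1.7e-6, par_lig(pc),
                                             transferred = t))$neg_log_kd
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("stepwise and cooperative estimates from one observation differ", {
  t <- forward_transfer(par_lig(1e-5))
  obs <- competition_observation(1.7e-6, par_lig(1e-5), transferred = t)
  s <- kd1_stepwise(obs); c_ <- kdav_cooperative(obs)
  expect_false(isTRUE(all.equal(s$neg_log_kd, c_$neg_log_kd)))
  expect_false(s$model == c_$model)
})

test_that("CI estimator reproduces the ATP transfer arithmetic", {
  atp <- competitor_ligand(7.7e-6, 20e-3, label = "ATP")
  obs <- competition_observation(38e-6, atp, transferred_eq = 0.46)
  est <- kd1_from_ci(obs, ci = 5.1)
  expect_identical(est$model, "ci_based")
  expect_equal(est$neg_log_kd, 8.23, tolerance = 0.005)
})

test_that("CI estimator identities and regime errors", {
  # 50% transfer with [ZnZ] = [Z] makes Kd1 = Kd(ZnZ)
  lig <- competitor_ligand(1, 2, label = "Z")
  obs <- competition_observation(2, lig, transferred = 1)
  expect_equal(kd1_from_ci(obs, ci = 6)$neg_log_kd, 6, tolerance = 1e-12)
  # with a genuine 1:1 competitor, ci = -log10(kd) recovers kd1_stepwise
  c2 <- competitor_ligand(1e-7, 1e-3, label = "C")
  obs2 <- competition_observation(38e-6, c2, transferred_eq = 0.4)
  expect_equal(kd1_from_ci(obs2, ci = 7)$neg_log_kd,
               kd1_stepwise(obs2)$neg_log_kd, tolerance = 1e-12)
  expect_error(kd1_from_ci(competition_observation(2, lig, transferred = 2),
                           ci = 6), class = "zincomp_out_of_regime")
})

test_that("fluorescence readout identities", {
  expect_equal(free_metal_from_fluorescence(150, 100, 200, 5.5e-9), 5.5e-9)
  zero <- free_metal_from_fluorescence(100, 100, 200, 5.5e-9)
  expect_identical(as.numeric(zero), 0)
  expect_true(attr(zero, "underflow"))
  expect_error(free_metal_from_fluorescence(200, 100, 200, 5.5e-9),
               class = "zincomp_saturation")
  # bound/free ratio of 2 doubles the probe constant
  f <- 100 + 2 / 3 * 100   # (f - fmin)/(fmax - f) = 2
  expect_equal(free_metal_from_fluorescence(f, 100, 200, 5.5e-9), 1.1e-8,
               tolerance = 1e-9)
})

test_that("isotherm fit recovers a noiseless logistic exactly", {
  x <- seq(6.5, 10, 0.25)
  y <- 1 / (1 + 10^(1 * (8.3 - x)))
  fit <- fit_transfer_isotherm(cbind(x, y))
  co <- coef(fit)
  expect_equal(unname(co["midpoint"]), 8.3, tolerance = 1e-6)
  expect_equal(unname(co["hill_n"]), 1, tolerance = 1e-6)
  expect_equal(unname(co["plateau"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_equal(predict(fit, 8.3), unname(co["plateau"]) / 2, tolerance = 1e-6)
})

test_that("two overlapping sites give a Hill slope above one", {
  # forward-simulate a probe titration of a two-site receptor: within the
  # probe-accessible window the second event steepens the apparent isotherm
  rec <- multisite_receptor(c(2e-8, 1.1e-10), 0.5e-6)
  pc <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 1, 1.5, 2) * 1e-6
  pts <- t(vapply(pc, function(p) {
    st <- solve_speciation(zn_system(rec,
      competitor_ligand(5.5e-9, p, label = "probe"),
      total_metal = 2 * 0.5e-6))
    c(-log10(st$free_metal), st$complex_conc[[1]] / 0.5e-6)
  }, c(0, 0)))
  fit <- fit_transfer_isotherm(pts)
  expect_gt(unname(coef(fit)["hill_n"]), 1)
})

test_that("flat data raise a no-transition error", {
  expect_error(fit_transfer_isotherm(cbind(seq(7, 9, 0.25), 0.5)),
               class = "zincomp_no_transition")
})

test_that("grid matching recovers a family member and flags boundaries", {
  zf_sc <- exchange_scenario(3.63e-9, 5e-6, response = "saturation")
  ratios <- c(0.5, 1, 1.5, 2)
  pts <- cbind(ratios, vapply(ratios, function(r) zf_sc(8.6, r), 0))
  est <- match_hypothetical_site(pts, zf_sc)
  expect_equal(est$neg_log_kd, 8.6)
  expect_false(est$details$boundary)
  # a 10^-13 M donor is out of the window: flagged at the grid edge
  pts13 <- cbind(ratios, vapply(ratios, function(r) zf_sc(13, r), 0))
  expect_warning(est13 <- match_hypothetical_site(pts13, zf_sc),
                 "boundary")
  expect_true(est13$details$boundary)
})

test_that("grid matching the observed PTP1B inhibition gives 8.2", {
  sc <- exchange_scenario(1.6e-8, 1e-7, response = "activity")
  est <- match_hypothetical_site(cbind(1, 0.61), sc, grid = seq(5.5, 10, 0.1))
  expect_equal(est$neg_log_kd, 8.2)
})

test_that("probe-titration pipeline recovers the weakest site", {
  tab <- gen_probe_titration(ground_truth(sigma = 0, floor_frac = 0))
  fit <- kd1_from_probe_titration(tab, 5.5e-9, 0.5e-6)
  expect_equal(unname(coef(fit)["midpoint"]), -log10(2e-8), tolerance = 0.05)
})
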
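mt2_rec <- function(conc = 1.7e-6) {
  multisite_receptor(mt_constants("mt2_ref32"), conc, "MT2")
}

test_that("degenerate systems return exact zeros", {
  st <- solve_speciation(zn_system(mt2_rec(),
    competitor_ligand(7.1e-13, 4e-4, stoich = 2, label = "PAR"),
    total_metal = 0))
  expect_identical(st$free_metal, 0)
  expect_true(all(unlist(st$site_occupancy) == 0))
  expect_true(all(st$complex_conc == 0))
})

test_that("single 1:1 site matches the closed-form binding quadratic", {
  kd <- 1e-9; rtot <- 1e-6; mtot <- 1e-6
  st <- solve_speciation(zn_system(multisite_receptor(kd, rtot), NULL,
                                   total_metal = mtot))
  # free metal is the positive root of Mf^2 + (Kd + R - M)Mf - Kd*M = 0
  b <- kd + rtot - mtot
  mf <- (-b + sqrt(b^2 + 4 * kd * mtot)) / 2
  expect_equal(st$free_metal, mf, tolerance = 1e-9)
  expect_equal(st$site_occupancy[[1]][1], mf / (mf + kd), tolerance = 1e-9)
})

test_that("MT2 + PAR speciation matches the log-grid bisection oracle", {
  sys <- zn_system(mt2_rec(),
    competitor_ligand(7.1e-13, 4e-4, stoich = 2, label = "PAR"),
    total_metal = 11.9e-6)
  st <- solve_speciation(sys)
  or <- oracle_speciation(sys)
  expect_lt(rel_diff(st$free_metal, or$free_metal), 1e-6)
  expect_lt(rel_diff(st$complex_conc[[1]], or$complex_conc[1]), 1e-6)
  expect_lt(rel_diff(st$free_ligand[[1]], or$free_ligand[1]), 1e-6)
  expect_lt(rel_diff(st$bound_receptor[1], or$bound_receptor[1]), 1e-6)
})

test_that("mass balances hold across randomized systems", {
  set.seed(42)
  for (i in 1:200) {
    sys <- random_system()
    st <- solve_speciation(sys)
    expect_lte(st$residual, 1e-9)
    # ligand balance: free + stoich * complex = total
    for (j in seq_along(sys$ligands)) {
      l <- sys$ligands[[j]]
      expect_lt(rel_diff(st$free_ligand[[j]] + l$stoich * st$complex_conc[[j]],
                         l$total_conc), 1e-9)
    }
    expect_true(all(unlist(st$site_occupancy) >= 0 &
                      unlist(st$site_occupancy) <= 1))
  }
})

test_that("transfer to a 1:1 competitor is monotone in its conc and kd", {
  transferred <- function(kd, conc) {
    st <- solve_speciation(zn_system(mt2_rec(),
      competitor_ligand(kd, conc, label = "C"), total_metal = 7 * 1.7e-6))
    st$complex_conc[[1]]
  }
  concs <- 10^seq(-6, -3, 0.5)
  t_conc <- vapply(concs, function(cc) transferred(1e-9, cc), 0)
  expect_true(all(diff(t_conc) >= -1e-15))
  kds <- 10^seq(-12, -7, 0.5)
  t_kd <- vapply(kds, function(k) transferred(k, 1e-4), 0)
  expect_true(all(diff(t_kd) <= 1e-15))
})

test_that("occupancy and transfer-fraction formulas are exact", {
  expect_equal(occupancy_at_free_metal(1e-9, 1e-9), 0.5)
  expect_equal(occupancy_at_free_metal(2e-8, 0), 0)
  expect_equal(occupancy_at_free_metal(2e-8, 1e-9), 1e-9 / 2.1e-8)
  expect_error(occupancy_at_free_metal(-1e-9, 1e-9), class = "zincomp_error")

  single <- multisite_receptor(1e-9, 1e-6)
  expect_equal(transfer_fraction_vs_free_metal(single, 1e-9)$fraction_released,
               0.5)
  # MT2 releases about 7.25% of its seven ions at 20 nM free zinc
  tf <- transfer_fraction_vs_free_metal(mt2_rec(), 2e-8)$fraction_released
  expect_equal(tf, 0.07251, tolerance = 1e-3)
  # limit Zf -> 0: everything released
  expect_equal(transfer_fraction_vs_free_metal(mt2_rec(), 1e-20)$fraction_released,
               1, tolerance = 1e-6)
  # monotone non-increasing over a grid
  grid <- 10^seq(-13, -7, 0.25)
  fr <- transfer_fraction_vs_free_metal(mt2_rec(), grid)$fraction_released
  expect_true(all(diff(fr) <= 0))
  expect_error(transfer_fraction_vs_free_metal(mt2_rec(), numeric(0)),
               class = "zincomp_error")
})

test_that("buffering isotherm is competitor-independent", {
  rec <- mt2_rec()
  iso <- buffering_isotherm(rec, competitor_kds = c(1e-9, 1e-10, 1e-11),
                            concs = 10^seq(-6, -3, 0.5))
  ref <- transfer_fraction_vs_free_metal(rec, iso$free_metal)
  expect_true(all(abs(iso$fraction_released - ref$fraction_released) < 1e-6))
})

test_that("pairwise exchange reproduces printed competition endpoints", {
  # equimolar PTP1B vs a single-site donor at -logKd 8.2: 61% activity left
  ex <- pairwise_exchange(10^-8.2, 1e-7, 1.6e-8, 1e-7)
  expect_equal(ex$acceptor_bound, 0.0386e-6, tolerance = 5e-3)
  expect_equal(round(100 * (1 - ex$acceptor_saturation)), 61)
  # weakened zinc finger at 2:1 donor excess: ~60% saturated
  ex2 <- pairwise_exchange(10^-8.6, 10e-6, 3.63e-9, 5e-6)
  expect_equal(100 * ex2$acceptor_saturation, 60, tolerance = 0.03)
  # symmetric exchange: half the metal crosses
  ex3 <- pairwise_exchange(1e-9, 1e-6, 1e-9, 1e-6)
  expect_equal(ex3$acceptor_bound, 0.5e-6, tolerance = 1e-9)
})

test_that("pairwise exchange agrees with the full solver when free metal is negligible", {
  set.seed(7)
  for (i in 1:20) {
    dk <- 10^runif(1, -10, -8); ak <- dk * 10^runif(1, -1, 1)
    dtot <- 10^runif(1, -6, -5); atot <- 10^runif(1, -6, -5)
    st <- solve_speciation(zn_system(multisite_receptor(dk, dtot),
      competitor_ligand(ak, atot, label = "acc"), total_metal = dtot))
    if (st$free_metal < 1e-3 * dtot) {
      ex <- pairwise_exchange(dk, dtot, ak, atot)
      expect_equal(ex$acceptor_bound, st$complex_conc[[1]],
                   tolerance = 0.02)
    }
  }
})

test_that("solver rejects invalid input", {
  expect_error(multisite_receptor(c(1e-9, -1), 1e-6), class = "zincomp_error")
  expect_error(competitor_ligand(1e-9, 1e-6, stoich = 3),
               class = "zincomp_error")
  expect_error(zn_system(mt2_rec(), NULL, total_metal = -1),
               class = "zincomp_error")
  expect_error(solve_speciation(zn_system(mt2_rec(), NULL, 1e-6),
                                tolerance = 1e-3), class = "zincomp_error")
})
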
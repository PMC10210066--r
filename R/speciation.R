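# Equilibrium speciation of one divalent metal among independent receptor
# sites, competitor ligands and a free-ion pool.
#
# The only unknown is free metal Mf: for independent sites the bound metal
# per site is the Langmuir term T*Mf/(Mf+Kd); for a 1:1 ligand the free
# ligand follows from its own mass balance as Lf = Ltot/(1+Mf/Kd), and for
# a 1:2 ligand (2 ligands per metal, overall constant Kd12 in M^2) Lf is the
# positive root of (2*Mf/Kd12)*Lf^2 + Lf - Ltot = 0.  Total bound metal is
# strictly increasing in Mf, so the metal balance has a unique root, found
# on a log10 bracket [-25, log10(total)+2].

ligand_species <- function(lig, mf) {
  if (lig$total_conc <= 0 || mf <= 0)
    return(list(free = lig$total_conc, complex = 0))
  if (lig$stoich == 1L) {
    lf <- lig$total_conc / (1 + mf / lig$kd)
    list(free = lf, complex = mf * lf / lig$kd)
  } else {
    a <- 2 * mf / lig$kd
    # stable root of a*Lf^2 + Lf - Ltot = 0
    lf <- 2 * lig$total_conc / (1 + sqrt(1 + 4 * a * lig$total_conc))
    list(free = lf, complex = mf * lf^2 / lig$kd)
  }
}

bound_metal <- function(system, mf) {
  rec <- sum(vapply(system$receptors, function(r)
    r$total_conc * sum(mf / (mf + r$site_kds)), 0))
  cpx <- sum(vapply(system$ligands, function(l)
    ligand_species(l, mf)$complex, 0))
  c(receptor = rec, complex = cpx)
}

#' Solve equilibrium speciation by mass balance
#'
#' Distributes the total metal of a [zn_system()] among free ion, receptor
#' sites (independent, fixed step constants) and competitor complexes, by
#' root finding on log10 free metal.  Bracketing on the log scale makes the
#' search unconditionally convergent over the physically relevant range of
#' free Zn(II) (roughly 1e-13 to 1e-7 M in MT competition work).
#'
#' @param system A [zn_system()].
#' @param tolerance Relative mass-balance tolerance, in (0, 1e-6].
#' @return An object of class `speciation_state`: a list with `free_metal`,
#'   `free_ligand` (named, molar), `complex_conc` (named, molar),
#'   `site_occupancy` (list per receptor, fractions weakest-first),
#'   `bound_receptor` (molar per receptor) and `residual` (relative
#'   mass-balance defect).
#' @examples
#' sys <- zn_system(multisite_receptor(1e-9, 1e-6), NULL, total_metal = 1e-6)
#' solve_speciation(sys)
#' @export
solve_speciation <- function(system, tolerance = 1e-9) {
  if (!inherits(system, "zn_system")) zc_stop("`system` must be a zn_system")
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1e-6)
    zc_stop("`tolerance` must be in (0, 1e-6]")
  mtot <- system$total_metal
  state <- function(mf) {
    ligs <- lapply(system$ligands, ligand_species, mf = mf)
    occ <- lapply(system$receptors, function(r) mf / (mf + r$site_kds))
    bound <- vapply(seq_along(system$receptors), function(i)
      system$receptors[[i]]$total_conc * sum(occ[[i]]), 0)
    cpx <- vapply(ligs, `[[`, 0, "complex")
    tot <- mf + sum(bound) + sum(cpx)
    res <- if (mtot > 0) abs(tot - mtot) / mtot else abs(tot)
    structure(list(free_metal = mf,
                   free_ligand = vapply(ligs, `[[`, 0, "free"),
                   complex_conc = cpx,
                   site_occupancy = occ,
                   bound_receptor = bound,
                   residual = res),
              class = "speciation_state")
  }
  if (mtot == 0) return(state(0))
  f <- function(lmf) {
    mf <- 10^lmf
    mf + sum(bound_metal(system, mf)) - mtot
  }
  lo <- -25; hi <- log10(mtot) + 2
  if (f(lo) > 0) lo <- -40   # pathologically small totals
  root <- tryCatch(
    stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                   maxiter = 2000),
    error = function(e) zc_stop(paste("speciation solver failed:",
                                      conditionMessage(e)),
                                type = "solver_failure"))
  st <- state(10^root$root)
  if (st$residual > tolerance)
    zc_stop(sprintf("mass balance not met: relative residual %.3g", st$residual),
            type = "solver_failure", residual = st$residual)
  st
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("<speciation_state> free metal %.4g M (residual %.2g)\n",
              x$free_metal, x$residual))
  if (length(x$complex_conc))
    cat("  complexes:", paste(sprintf("%s %.4g M", names(x$complex_conc),
                                      x$complex_conc), collapse = ", "), "\n")
  for (i in seq_along(x$site_occupancy))
    cat(sprintf("  receptor %d occupancy: %s\n", i,
                paste(sprintf("%.3f", x$site_occupancy[[i]]), collapse = " ")))
  invisible(x)
}

#' Langmuir occupancy of a single site
#'
#' @param site_kd Site dissociation constant (molar, > 0).
#' @param free_metal Free metal concentration (molar, >= 0).
#' @return Fractional occupancy `free_metal / (free_metal + site_kd)`.
#' @examples
#' occupancy_at_free_metal(1e-9, 1e-9)  # 0.5 at Kd
#' @export
occupancy_at_free_metal <- function(site_kd, free_metal) {
  check_number(site_kd, "site_kd", strict_min = 0)
  check_number(free_metal, "free_metal", min = 0)
  free_metal / (free_metal + site_kd)
}

#' Fraction of receptor metal released as a function of free metal
#'
#' For a fully loaded receptor the fraction of its metal transferred to any
#' pool of competitors depends only on the equilibrium free metal
#' concentration, not on which competitor set that concentration: this is
#' the buffering isotherm fraction(Zf) = (1/n) * sum_i Kdi / (Kdi + Zf).
#'
#' @param receptor A [multisite_receptor()].
#' @param free_metal_grid Free metal concentrations (molar, > 0).
#' @return Data frame with columns `free_metal` and `fraction_released`.
#' @examples
#' mt2 <- multisite_receptor(mt_constants("mt2_ref32"), 1.7e-6)
#' transfer_fraction_vs_free_metal(mt2, 10^seq(-13, -7, 0.5))
#' @export
transfer_fraction_vs_free_metal <- function(receptor, free_metal_grid) {
  if (!inherits(receptor, "multisite_receptor"))
    zc_stop("`receptor` must be a multisite_receptor")
  if (length(free_metal_grid) == 0) zc_stop("empty free-metal grid")
  check_number(free_metal_grid, "free_metal_grid", strict_min = 0)
  frac <- vapply(free_metal_grid, function(zf)
    mean(receptor$site_kds / (receptor$site_kds + zf)), 0)
  data.frame(free_metal = free_metal_grid, fraction_released = frac)
}

#' Pairwise metal exchange between a donor site and an acceptor
#'
#' Solves the two-species exchange equilibrium in which a loaded donor site
#' passes its metal directly to an acceptor without an explicit free-metal
#' pool: with x the exchanged amount,
#' `x^2 / ((donor_total - x) * (acceptor_total - x)) = donor_kd / acceptor_kd`.
#' This is the formalism in which the exchange constant relates only the
#' loaded and once-depleted donor species; it is appropriate whenever free
#' metal is negligible against the totals (tight binding on both sides).
#'
#' @param donor_kd,acceptor_kd Site dissociation constants (molar, > 0).
#' @param donor_total,acceptor_total Total concentrations (molar, > 0).
#' @return List with `released` (= `acceptor_bound`, molar), `kex`
#'   (exchange constant) and fractional `donor_released` / `acceptor_bound`.
#' @examples
#' # equal constants, equal totals: half the metal crosses
#' pairwise_exchange(1e-9, 1e-6, 1e-9, 1e-6)$acceptor_bound
#' @export
pairwise_exchange <- function(donor_kd, donor_total, acceptor_kd,
                              acceptor_total) {
  for (nm in c("donor_kd", "donor_total", "acceptor_kd", "acceptor_total"))
    check_number(get(nm), nm, strict_min = 0, len = 1)
  kex <- donor_kd / acceptor_kd
  a <- 1 - kex
  b <- kex * (donor_total + acceptor_total)
  cc <- -kex * donor_total * acceptor_total
  x <- if (abs(a) < 1e-14) -cc / b else (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  hi <- min(donor_total, acceptor_total)
  if (!is.finite(x) || x <= 0 || x >= hi)
    zc_stop("no exchange root in the physical interval",
            type = "model_inconsistency")
  list(released = x, acceptor_bound = x, kex = kex,
       donor_released = x / donor_total, acceptor_saturation = x / acceptor_total)
}
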
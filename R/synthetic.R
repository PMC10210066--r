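# Seeded generators of realistic assay datasets from a ground-truth
# multi-site model, so that every estimator and assay conversion can be
# exercised without an experimental file.  Identical (truth, parameters,
# seed) always produce identical datasets; the caller's RNG state is left
# untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

noisy <- function(x, sigma, floor_abs) {
  if (sigma <= 0 && all(floor_abs <= 0)) return(x)
  x * (1 + stats::rnorm(length(x), 0, sigma)) +
    stats::rnorm(length(x), 0, floor_abs)
}

#' Ground truth for synthetic assay generation
#'
#' Bundles the generating receptor model and the noise model.  Defaults are
#' the seven-site MT2 solution model (`mt2_ref32` constants) and 2 percent
#' multiplicative Gaussian noise on every measured signal with an additive
#' floor of 0.1 percent of full scale.
#'
#' @param site_kds Site constants (molar), weakest-first; default
#'   `mt_constants("mt2_ref32")`.
#' @param sigma Multiplicative noise standard deviation (default 0.02).
#' @param floor_frac Additive noise floor as a fraction of full scale
#'   (default 0.001).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(site_kds = mt_constants("mt2_ref32"),
                         sigma = 0.02, floor_frac = 0.001) {
  check_number(site_kds, "site_kds", strict_min = 0)
  check_number(sigma, "sigma", min = 0, len = 1)
  check_number(floor_frac, "floor_frac", min = 0, len = 1)
  structure(list(site_kds = sort(site_kds, decreasing = TRUE),
                 sigma = sigma, floor_frac = floor_frac),
            class = "ground_truth")
}

truth_receptor <- function(truth, conc, label = "receptor") {
  multisite_receptor(truth$site_kds, conc, label)
}

#' Synthetic PAR kinetic absorbance traces
#'
#' Emulates the chromogenic competition: the fully loaded receptor is mixed
#' with PAR and the Zn(PAR)2 absorbance at 492 nm approaches its
#' equilibrium plateau exponentially (time constant `tau`).  Without a
#' reducing agent a linear drift is added, emulating the continuous
#' absorbance rise caused by thiol oxidation; such traces never plateau.
#'
#' @param truth A [ground_truth()].
#' @param par_concs Total PAR concentrations (molar); default 5-400 uM.
#' @param mt_conc Receptor concentration (molar), default 1.7e-6.
#' @param with_reducing_agent Flag (default TRUE).
#' @param tau Kinetic time constant (s), default 300.
#' @param t_end,dt Trace length and sampling step (s).
#' @param par_kd12 PAR overall 1:2 constant (M^2), default 7.1e-13.
#' @param epsilon,path Beer-Lambert parameters for Zn(PAR)2.
#' @param drift Drift rate without reducing agent, in fractions of the
#'   equilibrium absorbance per second (default 1e-4).
#' @param seed RNG seed.
#' @return Data frame with columns `par_conc_M`, `time_s`, `signal_au`;
#'   attribute `equilibrium` holds the noiseless plateau per concentration.
#' @export
gen_par_kinetics <- function(truth, par_concs = c(5, 10, 20, 50, 100, 150,
                                                  200, 300, 400) * 1e-6,
                             mt_conc = 1.7e-6, with_reducing_agent = TRUE,
                             tau = 300, t_end = 3000, dt = 5,
                             par_kd12 = 7.1e-13, epsilon = 71500, path = 1,
                             drift = 1e-4, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rec <- truth_receptor(truth, mt_conc, "MT2")
  n <- length(truth$site_kds)
  times <- seq(0, t_end, by = dt)
  eq <- vapply(par_concs, function(pc) {
    st <- solve_speciation(zn_system(rec,
      competitor_ligand(par_kd12, pc, stoich = 2, label = "PAR"),
      total_metal = n * mt_conc))
    epsilon * path * unname(st$complex_conc[1])
  }, 0)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(par_concs), function(i) {
      sig <- eq[i] * (1 - exp(-times / tau))
      if (!with_reducing_agent) sig <- sig + drift * eq[i] * times
      data.frame(par_conc_M = par_concs[i], time_s = times,
                 signal_au = noisy(sig, truth$sigma,
                                   truth$floor_frac * eq[i]))
    }))
    structure(out, equilibrium = stats::setNames(eq, par_concs),
              reducing_agent = with_reducing_agent)
  })
}

#' Synthetic fluorescent-probe titration table
#'
#' Emulates a ZnAF-2F style competition: the loaded receptor equilibrates
#' with increasing probe; per point the fluorescence interpolates between
#' the calibration endpoints with the bound-probe fraction,
#' `F = Fmin + (Fmax - Fmin) * bound/total`.  Fmax scales with probe
#' concentration; Fmin is 5 percent of Fmax (residual fluorescence of the
#' metal-free probe).
#'
#' @param truth A [ground_truth()].
#' @param probe A [competitor_ligand()] template; its `kd` is used, its
#'   concentration is taken from `probe_concs`.  Default ZnAF-2F (5.5e-9 M).
#' @param probe_concs Probe concentrations (molar), default 0.05-2 uM.
#' @param mt_conc Receptor concentration (molar), default 0.5e-6.
#' @param f_scale Fluorescence yield of the saturated probe (au per molar).
#' @param seed RNG seed.
#' @return Data frame with columns `probe_conc_M`, `f`, `f0`, `fmin`,
#'   `fmax`; attribute `free_metal` holds the noiseless equilibrium values.
#' @export
gen_probe_titration <- function(truth,
                                probe = competitor_ligand(5.5e-9, 0,
                                                          label = "ZnAF-2F"),
                                probe_concs = c(0.05, 0.1, 0.2, 0.3, 0.5,
                                                0.7, 1, 1.5, 2) * 1e-6,
                                mt_conc = 0.5e-6, f_scale = 1e9,
                                seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rec <- truth_receptor(truth, mt_conc, "MT2")
  n <- length(truth$site_kds)
  sim <- lapply(probe_concs, function(pc) {
    if (pc == 0) return(list(fb = 0, zf = 0))
    lig <- competitor_ligand(probe$kd, pc, stoich = probe$stoich,
                             label = probe$label)
    st <- solve_speciation(zn_system(rec, lig, total_metal = n * mt_conc))
    list(fb = unname(st$complex_conc[1]) / pc, zf = st$free_metal)
  })
  fmax <- f_scale * probe_concs
  fmin <- 0.05 * fmax
  f <- fmin + (fmax - fmin) * vapply(sim, `[[`, 0, "fb")
  # full scale is per measurement: each point carries its own calibration
  floor_abs <- truth$floor_frac * fmax
  out <- with_seed(seed, data.frame(
    probe_conc_M = probe_concs,
    f = noisy(f, truth$sigma, floor_abs),
    f0 = noisy(fmin, truth$sigma, floor_abs),
    fmin = noisy(fmin, truth$sigma, floor_abs),
    fmax = noisy(fmax, truth$sigma, floor_abs)))
  attr(out, "free_metal") <- vapply(sim, `[[`, 0, "zf")
  out
}

#' Synthetic enzyme-inhibition rate pairs
#'
#' The weakest site of the truth model donates metal to a zinc-inhibited
#' enzyme by pairwise exchange; the sample rate is the control rate scaled
#' by the remaining active fraction.
#'
#' @param truth A [ground_truth()].
#' @param enzyme A [competitor_ligand()] for the enzyme site; default PTP1B
#'   (Kd 1.6e-8 M, 1e-7 M).
#' @param mt_conc Donor concentration (molar), default equimolar 1e-7.
#' @param control_rate Control initial rate (au/s).
#' @param n_rep Number of replicate pairs (default 4).
#' @param seed RNG seed.
#' @return Data frame with `replicate`, `rate_sample`, `rate_control`.
#' @export
gen_activity_assay <- function(truth,
                               enzyme = competitor_ligand(1.6e-8, 1e-7,
                                                          label = "PTP1B"),
                               mt_conc = 1e-7, control_rate = 1e-3,
                               n_rep = 4, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  ex <- pairwise_exchange(truth$site_kds[1], mt_conc,
                          enzyme$kd, enzyme$total_conc)
  active <- 1 - ex$acceptor_saturation
  with_seed(seed, data.frame(
    replicate = seq_len(n_rep),
    rate_sample = noisy(rep(control_rate * active, n_rep), truth$sigma,
                        truth$floor_frac * control_rate),
    rate_control = noisy(rep(control_rate, n_rep), truth$sigma,
                         truth$floor_frac * control_rate)))
}

#' Synthetic zinc-finger CD titration
#'
#' Metal transfer from the loaded receptor to a metal-free zinc finger at
#' increasing donor:acceptor molar ratios, read out as ellipticity at
#' 222 nm.  The equilibrium endpoint comes from full speciation over the
#' `n_donor_sites` weakest truth sites; the first site equilibrates fast
#' (`tau1`), any further sites slowly (`tau2`), reproducing the
#' time-dependent saturation seen over minutes-to-an-hour readings.
#'
#' @param truth A [ground_truth()].
#' @param zf A [competitor_ligand()]; default the weakened finger
#'   ZF133-11_C/E (Kd 3.63e-9 M) at 5 uM.
#' @param ratios Donor:acceptor molar ratios, default 0.1-2.
#' @param time_points_min Reading times in minutes, default c(3, 10, 20, 60).
#' @param n_donor_sites How many weakest sites can donate (default 2).
#' @param theta_apo,theta_holo Ellipticity baselines (mdeg).
#' @param tau1,tau2 Time constants (minutes) of the first and later events.
#' @param seed RNG seed.
#' @return Data frame with `ratio`, `time_min`, `theta_mdeg`; attribute
#'   `saturation_eq` holds the noiseless endpoint saturation per ratio.
#' @export
gen_cd_titration <- function(truth,
                             zf = competitor_ligand(3.63e-9, 5e-6,
                                                    label = "ZF133-11_C/E"),
                             ratios = seq(0.1, 2, 0.1),
                             time_points_min = c(3, 10, 20, 60),
                             n_donor_sites = 2,
                             theta_apo = -3, theta_holo = -11,
                             tau1 = 2, tau2 = 25, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  kds <- truth$site_kds[seq_len(n_donor_sites)]
  sat_eq <- vapply(ratios, function(r) {
    mt <- r * zf$total_conc
    if (mt == 0) return(0)
    rec <- multisite_receptor(kds, mt, "donor")
    st <- solve_speciation(zn_system(rec, zf,
                                     total_metal = n_donor_sites * mt))
    unname(st$complex_conc[1]) / zf$total_conc
  }, 0)
  sat1 <- vapply(ratios, function(r) {
    mt <- r * zf$total_conc
    if (mt == 0) return(0)
    rec <- multisite_receptor(kds[1], mt, "donor")
    st <- solve_speciation(zn_system(rec, zf, total_metal = mt))
    unname(st$complex_conc[1]) / zf$total_conc
  }, 0)
  sat1 <- pmin(sat1, sat_eq)
  grid <- expand.grid(time_min = time_points_min, ratio = ratios)
  sat_t <- mapply(function(r, tm) {
    i <- match(r, ratios)
    sat1[i] * (1 - exp(-tm / tau1)) +
      (sat_eq[i] - sat1[i]) * (1 - exp(-tm / tau2))
  }, grid$ratio, grid$time_min)
  theta <- theta_apo + sat_t * (theta_holo - theta_apo)
  with_seed(seed, {
    out <- data.frame(ratio = grid$ratio, time_min = grid$time_min,
                      theta_mdeg = noisy(theta, truth$sigma,
                                         truth$floor_frac *
                                           abs(theta_holo - theta_apo)))
    structure(out, saturation_eq = stats::setNames(sat_eq, ratios),
              theta_apo = theta_apo, theta_holo = theta_holo)
  })
}

#' Synthetic SEC partition of metal between protein and a weak ligand
#'
#' The loaded receptor is incubated with a large excess of a weak
#' low-molecular-weight ligand, modelled as the hypothetical 1:1 complex of
#' its competitivity index (Kd = 10^-CI), and the mixture is separated; the
#' readout is the metal remaining in the protein fraction, in equivalents.
#'
#' @param truth A [ground_truth()].
#' @param ci Competitivity index of the ligand at its total concentration.
#' @param ligand_total Total ligand concentration (molar), default 40e-3.
#' @param mt_conc Receptor concentration (molar), default 38e-6.
#' @param n_rep Number of replicates (default 4).
#' @param seed RNG seed.
#' @return Data frame with `replicate`, `zn_eq_protein`; attribute
#'   `transferred_eq` is the noiseless transferred equivalents.
#' @export
gen_sec_partition <- function(truth, ci, ligand_total = 40e-3,
                              mt_conc = 38e-6, n_rep = 4, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rec <- truth_receptor(truth, mt_conc, "MT2")
  n <- length(truth$site_kds)
  if (ligand_total > 0) {
    lig <- competitor_ligand(10^(-ci), ligand_total, label = "Z")
    st <- solve_speciation(zn_system(rec, lig, total_metal = n * mt_conc))
    in_protein <- st$bound_receptor[1] / mt_conc
  } else {
    st <- solve_speciation(zn_system(rec, NULL, total_metal = n * mt_conc))
    in_protein <- st$bound_receptor[1] / mt_conc
  }
  with_seed(seed, structure(
    data.frame(replicate = seq_len(n_rep),
               zn_eq_protein = noisy(rep(in_protein, n_rep), truth$sigma,
                                     truth$floor_frac * n)),
    transferred_eq = n - in_protein))
}
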
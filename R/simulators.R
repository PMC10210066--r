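# Model-critique simulations: what the single-affinity ("cooperative")
# estimator reports when the underlying protein actually has differentiated
# sites, the competitor-independent buffering isotherm, hypothetical-site
# transfer families and two-receptor metal-loading titrations.

#' Bias surface of the single-affinity average constant
#'
#' For every (competitor Kd, competitor concentration) cell, the full
#' differentiated-site speciation is solved, the transferred metal is fed to
#' the cooperative estimator, and both the transferred percentage and the
#' naive -logKd_av are recorded.  Across such a grid the naive average moves
#' by several log units although the generating receptor never changes:
#' the estimator, not the protein, varies.
#'
#' @param receptor A fully loaded [multisite_receptor()].
#' @param kds Competitor dissociation constants (molar), 1:1 stoichiometry.
#' @param concs Competitor total concentrations (molar).
#' @param stoich Competitor stoichiometry (default 1).
#' @return Object of class `bias_surface`: data frame with columns `kd`,
#'   `conc`, `transferred_pct`, `neg_log_kdav` (NA where the estimator is
#'   out of regime, e.g. no transfer).
#' @examples
#' mt2 <- multisite_receptor(mt_constants("mt2_ref32"), 1.7e-6)
#' simulate_bias_surface(mt2, kds = 10^seq(-12, -7, 1), concs = c(1e-5, 1e-4))
#' @export
simulate_bias_surface <- function(receptor, kds = 10^seq(-14, -6, 0.5),
                                  concs = 10^seq(-6, -3, 0.5), stoich = 1) {
  if (!inherits(receptor, "multisite_receptor"))
    zc_stop("`receptor` must be a multisite_receptor")
  n <- length(receptor$site_kds)
  grid <- expand.grid(kd = sort(kds), conc = sort(concs))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lig <- competitor_ligand(grid$kd[i], grid$conc[i], stoich = stoich,
                             label = "probe")
    out <- tryCatch({
      st <- solve_speciation(zn_system(receptor, lig,
                                       total_metal = n * receptor$total_conc))
      t <- unname(st$complex_conc[1])
      obs <- competition_observation(receptor$total_conc, lig,
                                     transferred = t, n_sites = n)
      est <- tryCatch(kdav_cooperative(obs)$neg_log_kd,
                      zincomp_error = function(e) NA_real_)
      c(100 * t / (n * receptor$total_conc), est)
    }, zincomp_solver_failure = function(e) c(NA_real_, NA_real_))
    data.frame(kd = grid$kd[i], conc = grid$conc[i],
               transferred_pct = out[1], neg_log_kdav = out[2])
  })
  structure(do.call(rbind, rows), class = c("bias_surface", "data.frame"),
            receptor = receptor)
}

#' @export
print.bias_surface <- function(x, ...) {
  cat(sprintf("<bias_surface> %d cells; naive -logKdav range %.2f .. %.2f\n",
              nrow(x), min(x$neg_log_kdav, na.rm = TRUE),
              max(x$neg_log_kdav, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.bias_surface <- function(x, ...) {
  kds <- sort(unique(x$kd))
  graphics::plot(NULL, xlim = range(log10(x$conc)),
                 ylim = range(x$neg_log_kdav, na.rm = TRUE),
                 xlab = "log10 competitor conc (M)",
                 ylab = "naive -logKd(av)", ...)
  for (k in kds) {
    sub <- x[x$kd == k, ]
    graphics::lines(log10(sub$conc), sub$neg_log_kdav)
  }
  invisible(x)
}

#' Transfer curve families for hypothetical donor sites
#'
#' Evaluates a pairwise-exchange scenario over an abscissa grid for each
#' member of a family of donor -logKd values: tighter donors give lower
#' acceptor saturation at every abscissa, so the curves are strictly
#' ordered and an observed saturation picks out the donor affinity.
#'
#' @param scenario A scenario function from [exchange_scenario()].
#' @param kd_family Donor -logKd values.
#' @param x_grid Abscissa values (donor:acceptor molar ratios).
#' @return Data frame with columns `neg_log_kd`, `x`, `value`.
#' @export
simulate_transfer_scenarios <- function(scenario, kd_family = 7:12,
                                        x_grid = seq(0.1, 2, 0.1)) {
  check_number(kd_family, "kd_family")
  check_number(x_grid, "x_grid", strict_min = 0)
  out <- expand.grid(x = x_grid, neg_log_kd = kd_family)
  out$value <- mapply(function(g, xx) scenario(g, xx),
                      out$neg_log_kd, out$x)
  out[c("neg_log_kd", "x", "value")]
}

#' Metal-loading titration of two competing receptors
#'
#' Full speciation at each added-metal point for a mixture of a multi-site
#' receptor (e.g. apo-MT2) and a single-site acceptor (e.g. a zinc finger),
#' reporting the apo fraction of each.  Swapping the multi-site constant set
#' (solution-derived vs ESI-MS-derived) changes the predicted curves.
#'
#' @param receptor_a Multi-site [multisite_receptor()].
#' @param receptor_b Single-site [multisite_receptor()].
#' @param metal_eq_grid Added metal in equivalents of `receptor_a` total.
#' @return Data frame with `metal_eq`, `apo_fraction_a` (fraction of
#'   receptor-a sites empty), `apo_fraction_b`, `free_metal`.
#' @examples
#' mt2 <- multisite_receptor(mt_constants("mt2_ref32"), 30e-6, "MT2")
#' cp1 <- multisite_receptor(5.0e-13, 30e-6, "CP1")
#' simulate_loading_titration(mt2, cp1, metal_eq_grid = c(2, 6))
#' @export
simulate_loading_titration <- function(receptor_a, receptor_b,
                                       metal_eq_grid = seq(0, 8, 0.5)) {
  for (r in list(receptor_a, receptor_b))
    if (!inherits(r, "multisite_receptor"))
      zc_stop("receptors must be multisite_receptor objects")
  check_number(metal_eq_grid, "metal_eq_grid", min = 0)
  rows <- lapply(metal_eq_grid, function(eq) {
    st <- solve_speciation(zn_system(list(receptor_a, receptor_b), NULL,
                                     total_metal = eq * receptor_a$total_conc))
    data.frame(metal_eq = eq,
               apo_fraction_a = 1 - mean(st$site_occupancy[[1]]),
               apo_fraction_b = 1 - mean(st$site_occupancy[[2]]),
               free_metal = st$free_metal)
  })
  do.call(rbind, rows)
}

#' Buffering isotherm by full speciation against arbitrary competitors
#'
#' Runs the full solver for a receptor against each supplied competitor at
#' each concentration and returns the released metal fraction together with
#' the solver's own equilibrium free metal.  Plotted against free metal the
#' points collapse onto [transfer_fraction_vs_free_metal()] regardless of
#' the competitor: the buffering isotherm is competitor-independent.
#'
#' @param receptor A [multisite_receptor()].
#' @param competitor_kds 1:1 competitor constants (molar).
#' @param concs Competitor concentrations (molar).
#' @return Data frame with `kd`, `conc`, `free_metal`, `fraction_released`.
#' @export
buffering_isotherm <- function(receptor, competitor_kds = c(1e-9, 1e-10, 1e-11),
                               concs = 10^seq(-6, -3, 0.5)) {
  n <- length(receptor$site_kds)
  grid <- expand.grid(kd = competitor_kds, conc = concs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lig <- competitor_ligand(grid$kd[i], grid$conc[i], label = "probe")
    st <- solve_speciation(zn_system(receptor, lig,
                                     total_metal = n * receptor$total_conc))
    released <- 1 - mean(st$site_occupancy[[1]])
    data.frame(kd = grid$kd[i], conc = grid$conc[i],
               free_metal = st$free_metal, fraction_released = released)
  })
  do.call(rbind, rows)
}
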
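#' Multi-site metal receptor
#'
#' A macromolecule binding one divalent metal at `n` independent sites with
#' fixed step dissociation constants.  Sites are indexed weakest-first:
#' `site_kds[1]` is the constant of the most loosely bound ion (for a fully
#' loaded seven-site protein, the Zn7 -> Zn6 step).
#'
#' @param site_kds Conditional dissociation constants (molar), one per site.
#'   Any order is accepted; they are sorted weakest-first (decreasing Kd).
#' @param total_conc Total receptor concentration (molar).
#' @param label Optional text label.
#' @return An object of class `multisite_receptor`.
#' @examples
#' mt2 <- multisite_receptor(mt_constants("mt2_ref32"), 1.7e-6, "MT2")
#' mt2
#' @export
multisite_receptor <- function(site_kds, total_conc, label = "receptor") {
  check_number(site_kds, "site_kds", strict_min = 0)
  check_number(total_conc, "total_conc", min = 0, len = 1)
  structure(list(site_kds = sort(site_kds, decreasing = TRUE),
                 total_conc = total_conc, label = as.character(label)[1]),
            class = "multisite_receptor")
}

#' @export
print.multisite_receptor <- function(x, ...) {
  cat(sprintf("<multisite_receptor> %s: %d site(s), %.3g M total\n",
              x$label, length(x$site_kds), x$total_conc))
  cat("  -logKd (weakest first):",
      paste(sprintf("%.2f", -log10(x$site_kds)), collapse = ", "), "\n")
  invisible(x)
}

#' Competing metal ligand
#'
#' A chelator, probe or protein site competing for the metal with 1:1 or
#' 1:2 metal:ligand stoichiometry.  For 1:2 ligands (e.g. PAR) `kd` is the
#' overall two-ligand dissociation constant in molar^2 and two ligand
#' molecules are consumed per bound metal.
#'
#' @param kd Conditional dissociation constant (molar for `stoich = 1`,
#'   molar^2 for `stoich = 2`).
#' @param total_conc Total ligand concentration (molar).
#' @param stoich Ligands per metal, 1 or 2.
#' @param label Optional text label.
#' @return An object of class `competitor_ligand`.
#' @examples
#' par <- competitor_ligand(7.1e-13, 4e-4, stoich = 2, label = "PAR")
#' @export
competitor_ligand <- function(kd, total_conc, stoich = 1, label = "ligand") {
  check_number(kd, "kd", strict_min = 0, len = 1)
  check_number(total_conc, "total_conc", min = 0, len = 1)
  if (!stoich %in% c(1, 2)) zc_stop("`stoich` must be 1 or 2")
  structure(list(kd = kd, total_conc = total_conc, stoich = as.integer(stoich),
                 label = as.character(label)[1]),
            class = "competitor_ligand")
}

#' @export
print.competitor_ligand <- function(x, ...) {
  cat(sprintf("<competitor_ligand> %s: 1:%d, Kd %.3g M%s, %.3g M total\n",
              x$label, x$stoich, x$kd, if (x$stoich == 2) "^2" else "",
              x$total_conc))
  invisible(x)
}

#' Competition system definition
#'
#' Bundles receptors, competing ligands and a total metal concentration for
#' the speciation solver.  All constants are conditional values at the pH
#' given in `ph_note`; protonation microstates are not modelled.
#'
#' @param receptors A `multisite_receptor` or list of them.
#' @param ligands A `competitor_ligand`, list of them, or `NULL`.
#' @param total_metal Total metal concentration (molar).
#' @param ph_note Annotation only; default "pH 7.4".
#' @return An object of class `zn_system`.
#' @examples
#' sys <- zn_system(multisite_receptor(mt_constants("mt2_ref32"), 1.7e-6),
#'                  competitor_ligand(7.1e-13, 4e-4, stoich = 2, label = "PAR"),
#'                  total_metal = 7 * 1.7e-6)
#' @export
zn_system <- function(receptors, ligands = NULL, total_metal,
                      ph_note = "pH 7.4") {
  if (inherits(receptors, "multisite_receptor")) receptors <- list(receptors)
  if (inherits(ligands, "competitor_ligand")) ligands <- list(ligands)
  if (is.null(ligands)) ligands <- list()
  if (!all(vapply(receptors, inherits, TRUE, "multisite_receptor")))
    zc_stop("`receptors` must be multisite_receptor objects")
  if (!all(vapply(ligands, inherits, TRUE, "competitor_ligand")))
    zc_stop("`ligands` must be competitor_ligand objects")
  check_number(total_metal, "total_metal", min = 0, len = 1)
  labs <- vapply(ligands, `[[`, "", "label")
  if (anyDuplicated(labs))
    labs <- make.unique(labs)
  names(ligands) <- labs
  structure(list(receptors = receptors, ligands = ligands,
                 total_metal = total_metal, ph_note = ph_note),
            class = "zn_system")
}

#' @export
print.zn_system <- function(x, ...) {
  cat(sprintf("<zn_system> %.3g M total metal (%s)\n", x$total_metal,
              x$ph_note))
  for (r in x$receptors) print(r)
  for (l in x$ligands) print(l)
  invisible(x)
}
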
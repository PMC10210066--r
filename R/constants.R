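#' Packaged stability-constant sets for metallothionein zinc sites
#'
#' Step (per-site) conditional dissociation constants for the seven Zn(II)
#' sites of mammalian metallothioneins, as determined by different
#' experimental routes.  Constants are conditional (apparent) values; the
#' solution sets refer to pH 7.4.  Sites are ordered weakest-first, i.e.
#' element 1 is the dissociation constant of the most loosely bound ion
#' (the Zn7 -> Zn6 step).
#'
#' Available sets:
#' \describe{
#'   \item{`mt2_ref32`}{Human MT2 solution model from fluorescent-probe
#'     competition: four tight sites at 1.6e-12 M, one at 3.6e-11 M, one at
#'     1.1e-10 M and one weak site at 2e-8 M.}
#'   \item{`mt1_esi`}{Human MT1 gas-phase (ESI-MS) model; seven narrowly
#'     spaced picomolar sites.}
#'   \item{`mt2_esi`}{Human MT2 gas-phase (ESI-MS) model; seven picomolar
#'     sites.}
#' }
#'
#' @param set Name of the constant set.
#' @return Numeric vector of seven dissociation constants (molar),
#'   weakest-first, with attribute `"set"`.
#' @examples
#' mt_constants("mt2_ref32")
#' @export
mt_constants <- function(set = c("mt2_ref32", "mt1_esi", "mt2_esi")) {
  sets <- list(
    mt2_ref32 = c(2e-8, 1.1e-10, 3.6e-11, rep(1.6e-12, 4)),
    mt1_esi   = sort(c(4.5e-13, 3.4e-13, 3.0e-13, 4.3e-13,
                       6.2e-13, 8.9e-13, 1.6e-12), decreasing = TRUE),
    mt2_esi   = sort(c(1.3e-12, 1.0e-12, 1.6e-12, 2.0e-12,
                       2.0e-11, 1.3e-11, 2.5e-11), decreasing = TRUE)
  )
  if (length(set) == 1 && !set[1] %in% names(sets))
    zc_stop(sprintf("unknown constant set '%s'; available sets: %s",
                    set[1], paste(names(sets), collapse = ", ")),
            type = "config")
  set <- match.arg(set)
  structure(sets[[set]], set = set)
}

#' Zinc competitors used in MT2 competition experiments
#'
#' Conditional dissociation constants (pH 7.4) of the Zn(II) complexes of
#' the competitors used to probe the weak zinc site of MT2: the chromogenic
#' chelator PAR (1:2 metal:ligand, constant in M^2), the fluorescent probe
#' ZnAF-2F, zinc-finger peptides, the enzyme PTP1B, and low-molecular-weight
#' ligands characterised by a competitivity index (CI) rather than a single
#' 1:1 constant (for these, `kd` is NA and `ci` carries the -log of the
#' apparent aggregate-complex constant at the stated total concentration).
#'
#' @return A data frame with columns `label`, `method`, `stoich`
#'   (ligands per metal), `kd` (molar for 1:1, molar^2 for 1:2),
#'   `neg_log_kd`, `ci_low`, `ci_high` (NA unless CI-characterised).
#' @examples
#' zn_competitors()
#' @export
zn_competitors <- function() {
  data.frame(
    label  = c("PAR", "ZnAF-2F", "ZF133-11", "ZF133-11_C/E", "PTP1B",
               "ZScan20", "ZNF442", "CP1-2015", "ATP", "GSH", "L-His"),
    method = c("UV-vis", "fluorimetry", "CD", "CD", "enzymatic",
               "ESI-MS", "ESI-MS", "ESI-MS", "SEC", "SEC", "SEC"),
    stoich = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    kd     = c(7.1e-13, 5.5e-9, 3.31e-13, 3.63e-9, 1.6e-8,
               1.3e-8, 4.0e-11, 5.0e-13, NA, NA, NA),
    neg_log_kd = c(12.1, 8.3, 12.5, 8.4, 7.8, 7.9, 10.4, 12.3, NA, NA, NA),
    ci_low  = c(NA, NA, NA, NA, NA, NA, NA, NA, 5.1, 6.4, 6.8),
    ci_high = c(NA, NA, NA, NA, NA, NA, NA, NA, 5.1, 6.7, 7.2),
    stringsAsFactors = FALSE
  )
}

#' Reported weakest-site affinities of human MT2 by competition method
#'
#' The -logKd1 values of the weakest Zn(II)-binding site of human MT2
#' obtained with each competitor.  Two independent protein preparations give
#' two entries for PAR and ZnAF-2F.  Gas-phase (ESI-MS) determinations are
#' flagged `solution = FALSE`; entries from the low-molecular-weight (LMW)
#' ligand competition are flagged `lmw = TRUE`.  Competitors too strong to
#' resolve the weak site are omitted (no numeric result exists for them).
#'
#' @return Data frame with columns `competitor`, `neg_log_kd1`,
#'   `uncertainty`, `solution`, `lmw`.
#' @examples
#' ## mean over all solution-based determinations
#' r <- mt2_kd1_results()
#' mean(r$neg_log_kd1[r$solution])
#' @export
mt2_kd1_results <- function() {
  data.frame(
    competitor  = c("PTP1B", "PAR", "PAR (pH 8 prep.)", "ZF133-11_C/E",
                    "ZnAF-2F", "ZnAF-2F (pH 8 prep.)", "ATP", "GSH", "L-His",
                    "ZScan20", "ZNF442"),
    neg_log_kd1 = c(8.2, 8.6, 8.1, 8.6, 8.32, 8.19, 7.9, 8.9, 8.7, 11, 11),
    uncertainty = c(0.2, 0.3, 0.5, 0.1, 0.01, 0.01, 0.2, 0.1, 0.3, NA, NA),
    solution    = c(rep(TRUE, 9), FALSE, FALSE),
    lmw         = c(rep(FALSE, 6), TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}
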
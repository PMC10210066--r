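# Independent speciation oracle: plain bisection on log10 free metal with
# nested bisection on each ligand's free concentration.  Shares no code
# with the package solver (which brackets with uniroot and closed-form
# ligand balances).

oracle_ligand_free <- function(stoich, kd, ltot, mf, iters = 80) {
  if (ltot <= 0 || mf <= 0) return(ltot)
  lo <- 0; hi <- ltot
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cpx <- if (stoich == 1) mf * mid / kd else mf * mid^2 / kd
    if (mid + stoich * cpx > ltot) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

oracle_speciation <- function(system, iters = 80) {
  mtot <- system$total_metal
  species <- function(mf) {
    lf <- vapply(system$ligands, function(l)
      oracle_ligand_free(l$stoich, l$kd, l$total_conc, mf), 0)
    cpx <- vapply(seq_along(system$ligands), function(i) {
      l <- system$ligands[[i]]
      if (l$stoich == 1) mf * lf[i] / l$kd else mf * lf[i]^2 / l$kd
    }, 0)
    bound <- vapply(system$receptors, function(r)
      r$total_conc * sum(mf / (mf + r$site_kds)), 0)
    list(lf = lf, cpx = cpx, bound = bound,
         total = mf + sum(bound) + sum(cpx))
  }
  if (mtot == 0) {
    sp <- species(0)
    return(list(free_metal = 0, free_ligand = sp$lf, complex_conc = sp$cpx,
                bound_receptor = sp$bound))
  }
  lo <- -20; hi <- log10(mtot) + 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (species(10^mid)$total > mtot) hi <- mid else lo <- mid
  }
  mf <- 10^((lo + hi) / 2)
  sp <- species(mf)
  list(free_metal = mf, free_ligand = sp$lf, complex_conc = sp$cpx,
       bound_receptor = sp$bound)
}

# Random competition systems for property tests.
random_system <- function() {
  n_sites <- sample(1:8, 1)
  kds <- 10^stats::runif(n_sites, -13, -7)
  rtot <- 10^stats::runif(1, -7, -5)
  rec <- multisite_receptor(kds, rtot)
  n_lig <- sample(0:3, 1)
  ligs <- lapply(seq_len(n_lig), function(i) {
    st <- sample(1:2, 1)
    kd <- if (st == 1) 10^stats::runif(1, -12, -6) else 10^stats::runif(1, -14, -10)
    competitor_ligand(kd, 10^stats::runif(1, -6, -3), stoich = st,
                      label = paste0("L", i))
  })
  mtot <- stats::runif(1, 0.1, 1.2) * n_sites * rtot
  zn_system(rec, ligs, total_metal = mtot)
}

rel_diff <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, 0, d / s)
}
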
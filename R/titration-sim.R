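#' Bound complex concentration for 1:1 binding (exact quadratic solution)
#'
#' Solves `P + L <-> PL` with dissociation constant `kd` by the exact mass
#' balance: `[PL] = ((P_t + L_t + Kd) - sqrt((P_t + L_t + Kd)^2 -
#' 4 P_t L_t)) / 2` (the physical root).
#'
#' @param protein_total,ligand_total total concentrations (same units as
#'   `kd`; conventionally micromolar).
#' @param kd dissociation constant (> 0).
#' @return Bound complex concentration(s), vectorized over inputs.
#' @export
#' @examples
#' equilibrium_bound(2, 2, 2)
equilibrium_bound <- function(protein_total, ligand_total, kd) {
  stopifnot(all(kd > 0), all(protein_total >= 0), all(ligand_total >= 0))
  s <- protein_total + ligand_total + kd
  disc <- s^2 - 4 * protein_total * ligand_total
  (s - sqrt(pmax(disc, 0))) / 2
}

#' Coupled competition equilibrium for probe and competitor
#'
#' Solves the two simultaneous 1:1 equilibria `P + N <-> PN` (probe,
#' `kd_probe`) and `P + C <-> PC` (competitor, `kd_comp`) exactly, by
#' root-finding on free protein: `P_t = P_f (1 + (N_t/K_N)/(1 + P_f/K_N)
#' + (C_t/K_C)/(1 + P_f/K_C))`, which is strictly increasing in `P_f`.
#'
#' @param protein_total,probe_total,comp_total total concentrations.
#' @param kd_probe,kd_comp dissociation constants (> 0).
#' @param tol relative tolerance of the mass-balance solve.
#' @return List with `bound_probe`, `bound_comp`, `free_protein`,
#'   `free_probe`, `free_comp`, and `residual` (worst relative mass-balance
#'   error across the three species).
#' @export
equilibrium_competition <- function(protein_total, probe_total, comp_total,
                                    kd_probe, kd_comp, tol = 1e-10) {
  stopifnot(protein_total > 0, probe_total >= 0, comp_total >= 0,
            kd_probe > 0, kd_comp > 0)
  g <- function(pf) {
    fn <- probe_total / (1 + pf / kd_probe)
    fc <- comp_total / (1 + pf / kd_comp)
    pf * (1 + fn / kd_probe + fc / kd_comp) - protein_total
  }
  dg <- function(pf) {
    1 + probe_total * kd_probe / (kd_probe + pf)^2 +
      comp_total * kd_comp / (kd_comp + pf)^2
  }
  sol <- uniroot(g, interval = c(0, protein_total),
                 tol = tol * max(protein_total, 1))
  pf <- sol$root
  # Newton polish: the mass-balance slope is steep for tight binders, so
  # the bracketing tolerance alone can leave too large a residual
  for (i in 1:50) {
    step <- g(pf) / dg(pf)
    pf_new <- min(max(pf - step, 0), protein_total)
    if (abs(g(pf_new)) >= abs(g(pf))) break
    pf <- pf_new
    if (abs(g(pf)) <= 1e-13 * max(protein_total, 1)) break
  }
  fn <- probe_total / (1 + pf / kd_probe)
  fc <- comp_total / (1 + pf / kd_comp)
  bn <- pf * fn / kd_probe
  bc <- pf * fc / kd_comp
  tots <- c(protein_total, max(probe_total, .Machine$double.eps),
            max(comp_total, .Machine$double.eps))
  resid <- max(abs(c(pf + bn + bc - protein_total,
                     fn + bn - probe_total,
                     fc + bc - comp_total)) / tots)
  if (resid > 1e-8) {
    stop("numerical error: competition equilibrium did not converge ",
         "(relative mass-balance residual ", format(resid), ")",
         call. = FALSE)
  }
  list(bound_probe = bn, bound_comp = bc, free_protein = pf,
       free_probe = fn, free_comp = fc, residual = resid)
}

#' Simulate fluorescence titration curves
#'
#' In `saturation` mode the probe is titrated into protein and fluorescence
#' is proportional to the probe-protein complex computed from the exact 1:1
#' quadratic equilibrium. In `competition` mode the probe is held at
#' `probe_conc` while a competitor is titrated and the coupled equilibria
#' are solved numerically. Fluorescence is `scale * [bound probe] +
#' baseline`, multiplied by mean-one lognormal noise of coefficient of
#' variation `noise_cv`. The generating parameters are retained in the
#' returned object as an oracle for recovery tests.
#'
#' @param protein_conc total protein concentration (micromolar).
#' @param probe_kd probe dissociation constant (micromolar).
#' @param probe_concs probe totals for the saturation series (ignored if
#'   `competitor_concs` is supplied). Default 2-16 micromolar.
#' @param competitor_kd competitor dissociation constant, or `NULL` for a
#'   saturation experiment.
#' @param competitor_concs competitor totals for the competition series
#'   (should start at 0 so the first point defines F0).
#' @param probe_conc total probe concentration in competition mode.
#' @param noise_cv lognormal noise coefficient of variation (0 = exact).
#' @param scale,baseline fluorescence units per micromolar bound, and
#'   signal offset.
#' @param micelle_onset,micelle_slope optional high-concentration additive
#'   artifact emulating competitor micelle fluorescence: above
#'   `micelle_onset` the signal gains `micelle_slope * (conc - onset)`.
#' @param seed integer seed.
#' @return A `titration_curve`: list with `mode`, `protein_conc`,
#'   `probe_conc`, `points` (data.frame `conc`, `fluorescence`), and
#'   `truth` (generating parameters and exact bound concentrations).
#' @export
#' @examples
#' tc <- simulate_titration(2, 2, probe_concs = seq(2, 16, 2), seed = 1)
#' head(tc$points)
simulate_titration <- function(protein_conc, probe_kd,
                               probe_concs = seq(2, 16, by = 2),
                               competitor_kd = NULL,
                               competitor_concs = NULL,
                               probe_conc = 2,
                               noise_cv = 0,
                               scale = 1000, baseline = 0,
                               micelle_onset = Inf, micelle_slope = 0,
                               seed = 1L) {
  stopifnot(protein_conc > 0, probe_kd > 0, noise_cv >= 0)
  competition <- !is.null(competitor_kd)
  if (competition) {
    stopifnot(competitor_kd > 0, !is.null(competitor_concs),
              all(competitor_concs >= 0), probe_conc > 0)
    conc <- competitor_concs
    bound <- vapply(conc, function(ct)
      equilibrium_competition(protein_conc, probe_conc, ct,
                              probe_kd, competitor_kd)$bound_probe, 0)
  } else {
    stopifnot(all(probe_concs > 0))
    conc <- probe_concs
    bound <- equilibrium_bound(protein_conc, conc, probe_kd)
  }
  f <- scale * bound + baseline
  if (is.finite(micelle_onset) && micelle_slope > 0) {
    f <- f + micelle_slope * pmax(0, conc - micelle_onset)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    f <- with_seed(seed, f * exp(rnorm(length(f), -sdlog^2 / 2, sdlog)))
  }
  structure(list(mode = if (competition) "competition" else "saturation",
                 protein_conc = protein_conc,
                 probe_conc = if (competition) probe_conc else NA_real_,
                 points = data.frame(conc = conc, fluorescence = f),
                 truth = list(probe_kd = probe_kd,
                              competitor_kd = competitor_kd,
                              bound = bound, scale = scale,
                              baseline = baseline, noise_cv = noise_cv)),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("titration_curve (", x$mode, "): protein ", x$protein_conc,
      " uM, ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}
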
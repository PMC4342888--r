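#' Probe dissociation constant from a saturation titration (Scatchard)
#'
#' Converts fluorescence to bound probe assuming a fully active protein
#' with 1:1 stoichiometry at saturation (`bound = F / F_sat *
#' protein_conc`), computes free ligand as total minus bound, and fits the
#' Scatchard linearization `bound/free ~ bound` whose slope is `-1/K_d`.
#' Because the saturation plateau `F_sat` is itself unknown, it is
#' iterated to a fixed point: from the current plateau estimate the
#' Scatchard line yields a binding-capacity estimate `Bmax =
#' -intercept/slope`, and the plateau is rescaled by `Bmax / protein_conc`
#' until the relative change is below `tol` (at the fixed point the
#' capacity equals the total protein, i.e. the 100%-activity assumption is
#' self-consistent).
#'
#' @param curve a saturation-mode `titration_curve`.
#' @param tol relative fixed-point tolerance on `F_sat`.
#' @param max_iter iteration cap.
#' @return List (`binding_result`): `k_probe` (K_d of the probe, same
#'   units as the concentrations), `fit_r2` (R^2 of the final Scatchard
#'   line), `f_sat`, `b_max`, `n_iter`, `converged`, `method_notes`.
#' @export
fit_saturation <- function(curve, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$mode != "saturation") {
    stop("fit_saturation expects a saturation-mode curve", call. = FALSE)
  }
  pts <- curve$points
  if (nrow(pts) < 4) stop("need >= 4 titration points", call. = FALSE)
  f <- pts$fluorescence - min(0, min(pts$fluorescence))  # guard tiny negatives
  L <- pts$conc
  P <- curve$protein_conc
  notes <- character()
  if (any(diff(f) < 0)) notes <- c(notes, "non-monotone fluorescence")
  if (diff(range(f)) <= .Machine$double.eps * max(abs(f))) {
    stop("no-binding: fluorescence is constant across the titration",
         call. = FALSE)
  }
  # start above the largest observed signal so initial bound < protein
  f_sat <- max(f) * 1.5
  kd <- NA_real_
  r2 <- NA_real_
  b_max <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    bound <- f / f_sat * P
    free <- L - bound
    if (any(free <= 0)) {
      stop("data inconsistency: bound exceeds total ligand at point(s) ",
           paste(which(free <= 0), collapse = ","), call. = FALSE)
    }
    sc <- lm(I(bound / free) ~ bound)
    slope <- coef(sc)[2]; inter <- coef(sc)[1]
    if (!is.finite(slope) || slope >= 0) {
      stop("no-binding: Scatchard slope is non-negative", call. = FALSE)
    }
    kd <- -1 / slope
    b_max <- unname(-inter / slope)
    r2 <- summary(sc)$r.squared
    f_new <- f_sat * b_max / P
    if (!is.finite(f_new) || f_new <= 0) {
      stop("numerical error: plateau update left the feasible range",
           call. = FALSE)
    }
    # damped update keeps bound < total ligand along the way
    f_new <- max(f_new, max(f) * 1.0000001)
    if (abs(f_new - f_sat) <= tol * f_sat) {
      f_sat <- f_new
      converged <- TRUE
      break
    }
    f_sat <- f_new
  }
  if (!converged) notes <- c(notes, "plateau fixed point not converged")
  structure(list(k_probe = unname(kd), fit_r2 = r2, f_sat = unname(f_sat),
                 b_max = b_max, n_iter = it, converged = converged,
                 method_notes = paste(notes, collapse = "; ")),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  flds <- names(x)
  for (f in flds) {
    v <- x[[f]]
    if (is.numeric(v)) v <- format(v, digits = 5)
    cat(" ", f, ": ", v, "\n", sep = "")
  }
  invisible(x)
}

#' IC50 from a competition titration
#'
#' The competitor concentration at which fluorescence falls to half the
#' initial value F0 (the first point, normally at competitor 0). The
#' crossing is located by log-linear interpolation between the bracketing
#' measured points (linear in concentration when the bracket includes 0).
#' If fluorescence never falls below F0/2 within the tested range, the
#' IC50 is censored and reported as the largest tested concentration
#' (a lower bound).
#'
#' @param curve a competition-mode `titration_curve`.
#' @return List with `ic50`, `censored`, `f0`, `notes`.
#' @export
find_ic50 <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$mode != "competition") {
    stop("find_ic50 expects a competition-mode curve", call. = FALSE)
  }
  pts <- curve$points
  if (nrow(pts) < 3) stop("need >= 3 titration points", call. = FALSE)
  f0 <- pts$fluorescence[1]
  if (!is.finite(f0) || f0 <= 0) stop("data error: F0 <= 0", call. = FALSE)
  target <- f0 / 2
  below <- pts$fluorescence <= target
  notes <- character()
  if (!any(below)) {
    return(list(ic50 = max(pts$conc), censored = TRUE, f0 = f0,
                notes = "no crossing within tested range: lower bound"))
  }
  i2 <- which(below)[1]
  crossings <- sum(diff(below) != 0)
  if (crossings > 1) notes <- c(notes, "multiple crossings: first used")
  if (i2 == 1) {
    # already at/below half at the first point: cannot bracket
    return(list(ic50 = pts$conc[1], censored = TRUE, f0 = f0,
                notes = "first point already below F0/2: upper bound"))
  }
  c1 <- pts$conc[i2 - 1]; c2 <- pts$conc[i2]
  f1 <- pts$fluorescence[i2 - 1]; f2 <- pts$fluorescence[i2]
  ic50 <- if (f2 == f1) c2 else if (c1 > 0) {
    exp(log(c1) + (target - f1) * (log(c2) - log(c1)) / (f2 - f1))
  } else {
    c1 + (target - f1) * (c2 - c1) / (f2 - f1)
  }
  list(ic50 = unname(ic50), censored = FALSE, f0 = f0,
       notes = paste(notes, collapse = "; "))
}

#' Competitor dissociation constant from an IC50 (closed form)
#'
#' The classical correction `K_d = IC50 / (1 + [probe]/K_probe)`, with
#' `[probe]` the free probe concentration. In the limit of no probe
#' competition (`probe_free_conc -> 0`) the K_d equals the IC50. The
#' closed form assumes the competitor is not depleted by binding; see
#' [fit_competitor()] for the exact alternative.
#'
#' @param ic50 half-displacement competitor concentration.
#' @param probe_free_conc free probe concentration.
#' @param k_probe probe dissociation constant.
#' @return Competitor dissociation constant.
#' @export
#' @examples
#' kd_from_ic50(4, 2, 2)  # 2
kd_from_ic50 <- function(ic50, probe_free_conc, k_probe) {
  stopifnot(all(ic50 > 0), all(probe_free_conc >= 0), all(k_probe > 0))
  ic50 / (1 + probe_free_conc / k_probe)
}

#' Full competitor pipeline: IC50 plus K_d
#'
#' Extracts the IC50 from a competition curve, then converts it to the
#' competitor dissociation constant. Two conversions are available:
#' \describe{
#'   \item{`exact` (default)}{solves the coupled probe/competitor 1:1
#'     equilibria for the `K_d` at which the probe-protein complex at
#'     competitor total = IC50 is half its competitor-free value. This is
#'     scale-free (only the fluorescence *ratio* enters) and accounts for
#'     competitor and probe depletion, which is substantial when protein,
#'     probe and K_d are of comparable magnitude.}
#'   \item{`cheng_prusoff`}{the closed form [kd_from_ic50()], using the
#'     estimated free probe concentration at half displacement
#'     (`probe_total - bound0/2`); switch `probe_conc_mode = "total"` to
#'     use the total probe concentration instead.}
#' }
#'
#' @param curve a competition-mode `titration_curve`.
#' @param k_probe probe dissociation constant (from [fit_saturation()]).
#' @param method conversion method, see Details.
#' @param probe_conc_mode for `cheng_prusoff`: use the estimated free
#'   (`"free"`, default) or the total (`"total"`) probe concentration.
#' @param interval log10 search interval for the exact `K_d` solve.
#' @return List (`binding_result`): `ic50`, `censored`, `k_d`, `method`,
#'   `method_notes`.
#' @export
fit_competitor <- function(curve, k_probe,
                           method = c("exact", "cheng_prusoff"),
                           probe_conc_mode = c("free", "total"),
                           interval = c(-4, 3)) {
  method <- match.arg(method)
  probe_conc_mode <- match.arg(probe_conc_mode)
  stopifnot(inherits(curve, "titration_curve"), k_probe > 0)
  ic <- find_ic50(curve)
  P <- curve$protein_conc
  N <- curve$probe_conc
  bound0 <- equilibrium_bound(P, N, k_probe)
  if (method == "exact") {
    g <- function(log10_kc) {
      eq <- equilibrium_competition(P, N, ic$ic50, k_probe, 10^log10_kc)
      eq$bound_probe / bound0 - 0.5
    }
    lo <- g(interval[1]); hi <- g(interval[2])
    if (lo * hi > 0) {
      # IC50 outside the solvable range for this bracket: widen once
      interval <- c(interval[1] - 3, interval[2] + 3)
      lo <- g(interval[1]); hi <- g(interval[2])
      if (lo * hi > 0) {
        stop("no-binding: exact K_d solve has no root in the search range",
             call. = FALSE)
      }
    }
    kd <- 10^uniroot(g, interval, tol = 1e-12)$root
    notes <- "exact coupled-equilibrium inversion at the IC50 point"
  } else {
    probe_free <- if (probe_conc_mode == "free") N - bound0 / 2 else N
    kd <- kd_from_ic50(ic$ic50, probe_free, k_probe)
    notes <- sprintf("Cheng-Prusoff closed form (%s probe concentration)",
                     probe_conc_mode)
  }
  if (ic$censored) notes <- paste(notes, "; IC50 censored: K_d is a bound")
  structure(list(ic50 = ic$ic50, censored = ic$censored, f0 = ic$f0,
                 k_d = unname(kd), k_probe = k_probe, method = method,
                 method_notes = notes),
            class = "binding_result")
}
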
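#' Colony-level expression summaries from a quantification matrix
#'
#' Averages each protein's (standardized) values over the colony's
#' replicate samples, using the assignment to map (block, label) cells to
#' colonies. This is the per-colony protein level used by the
#' dam/sire heritability regression.
#'
#' @param matrix a [quant_matrix()].
#' @param assignment the matching `block_assignment`.
#' @return `data.frame` with `protein_id`, `colony_id`, `value`, `n_samples`.
#' @export
colony_expression <- function(matrix, assignment) {
  b <- assignment$blocks
  d <- matrix$data
  i <- match(paste(d$block, d$label), paste(b$block_id, b$label))
  if (anyNA(i)) {
    stop("matrix contains cells not covered by the assignment", call. = FALSE)
  }
  colony <- b$colony_id[i]
  agg <- aggregate(list(value = d$intensity),
                   by = list(protein_id = d$protein, colony_id = colony),
                   mean)
  n <- aggregate(list(n_samples = d$intensity),
                 by = list(protein_id = d$protein, colony_id = colony),
                 length)
  out <- merge(agg, n, by = c("protein_id", "colony_id"))
  out[order(out$protein_id, out$colony_id), ]
}

#' Dam/sire regression of offspring expression on parental expression
#'
#' For each protein, regresses the level observed in F1 daughter colonies
#' on the levels observed in their dam and sire colonies:
#' `offspring ~ dam + sire`. Under an additive genetic model the two
#' slopes each estimate half the narrow-sense heritability of the
#' (colony-level) expression, so their sum estimates `h2`. The joint
#' p-value is the F test of both slopes against the intercept-only model.
#'
#' Trios require the offspring and both parents to be quantified; proteins
#' with fewer than `min_trios` complete trios are reported with `NA`
#' slopes and a note.
#'
#' @param expr colony-level expression (from [colony_expression()]), or
#'   a row-bound combination from several datasets (values should be on a
#'   comparable standardized scale).
#' @param pedigree `data.frame` with `colony_id`, `dam_id`, `sire_id` for
#'   the offspring colonies.
#' @param min_trios minimum complete trios for a reported fit.
#' @return `data.frame` with `protein_id`, `slope_dam`, `slope_sire`,
#'   `joint_p`, `n_trios`, `notes`.
#' @export
fit_heritability <- function(expr, pedigree, min_trios = 3L) {
  stopifnot(all(c("protein_id", "colony_id", "value") %in% names(expr)),
            all(c("colony_id", "dam_id", "sire_id") %in% names(pedigree)))
  ped <- pedigree[!is.na(pedigree$dam_id) & !is.na(pedigree$sire_id), ]
  out <- lapply(split(expr, expr$protein_id), function(e) {
    v <- setNames(e$value, e$colony_id)
    off <- v[ped$colony_id]; dam <- v[ped$dam_id]; sire <- v[ped$sire_id]
    ok <- !is.na(off) & !is.na(dam) & !is.na(sire)
    n <- sum(ok)
    base <- data.frame(protein_id = e$protein_id[1],
                       slope_dam = NA_real_, slope_sire = NA_real_,
                       joint_p = NA_real_, n_trios = n, notes = "",
                       stringsAsFactors = FALSE)
    if (n < max(min_trios, 3L)) {
      base$notes <- sprintf("too few trios (%d < %d)", n, max(min_trios, 3L))
      return(base)
    }
    fit <- lm(off[ok] ~ dam[ok] + sire[ok])
    if (anyNA(coef(fit))) {
      base$notes <- "collinear parental values"
      return(base)
    }
    fit0 <- lm(off[ok] ~ 1)
    a <- anova(fit0, fit)
    base$slope_dam <- unname(coef(fit)[2])
    base$slope_sire <- unname(coef(fit)[3])
    base$joint_p <- a[["Pr(>F)"]][2]
    base
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Heritability factor from a dam/sire regression fit
#'
#' `max(0, slope_dam + slope_sire) * w(joint_p)`, with a step weighting
#' `w(p) = weights[1]` for `p < p_breaks[1]`, `weights[2]` for
#' `p < p_breaks[2]`, else `weights[3]`. Proteins without a valid fit
#' (absent pedigree data, too few trios, `NA` slopes) receive factor 0.
#'
#' @param fits result of [fit_heritability()] (or a compatible data.frame).
#' @param weights,p_breaks step weighting of the slope sum by the joint
#'   p-value.
#' @return Numeric vector of heritability factors, one per row of `fits`,
#'   named by `protein_id`.
#' @export
#' @examples
#' heritability_factor(data.frame(protein_id = "P1", slope_dam = 0.3,
#'   slope_sire = 0.2, joint_p = 0.01, n_trios = 20))
heritability_factor <- function(fits, weights = c(1, 0.5, 0.25),
                                p_breaks = c(0.05, 0.5)) {
  stopifnot(length(weights) == 3, length(p_breaks) == 2,
            !is.unsorted(p_breaks))
  s <- fits$slope_dam + fits$slope_sire
  w <- ifelse(fits$joint_p < p_breaks[1], weights[1],
              ifelse(fits$joint_p < p_breaks[2], weights[2], weights[3]))
  f <- pmax(0, s) * w
  f[is.na(f) | fits$n_trios < 3] <- 0
  setNames(f, fits$protein_id)
}
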
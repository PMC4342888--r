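#' Ground truth for a simulated quantification experiment
#'
#' Encodes everything the quantification simulator needs and everything a
#' test harness must know to score recovery: which proteins are planted
#' markers and their standardized effect sizes, the heritability and
#' variance components of colony-level expression, per-(protein,
#' population) offsets, and the block-level missingness mechanism.
#'
#' Effect sizes (`beta`) are expressed in units of the per-sample response
#' SD (`sqrt(sigma_colony^2 + sigma_resid^2)`) per SD of the latent
#' hygienic propensity, so a planted `beta` is on the same scale as the
#' slope estimated from the normalized matrix.
#'
#' @param n_proteins number of simulated proteins.
#' @param populations character vector of population labels the experiment
#'   may contain (rows of `pop_effects` are proteins, columns populations).
#' @param n_markers number of planted marker proteins (ignored when
#'   `marker_ids` is given).
#' @param marker_ids optional explicit marker protein ids.
#' @param beta standardized marker effect size(s); recycled over markers.
#' @param h2 narrow-sense heritability of colony-level expression, scalar
#'   or per-protein vector in \[0, 1\].
#' @param sigma_colony SD of the colony random effect (genetic +
#'   environmental) on the log-intensity scale.
#' @param sigma_resid residual SD per sample on the log-intensity scale.
#' @param sigma_block,sigma_label SDs of run-level block and label offsets.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log-intensities (wide `baseline_sd` emulates the large abundance range
#'   of an antennal proteome).
#' @param pop_effect_sd,pop_effect_fraction a random `pop_effect_fraction`
#'   of proteins receive N(0, `pop_effect_sd`) offsets per population.
#' @param missing_model list with `rate` (target overall fraction of
#'   missing (protein, block) triples), `mcar` (flat completely-at-random
#'   component, part of `rate`), and `abundance_weight` (logistic
#'   dependence of missingness on low abundance).
#' @param seed integer seed for the truth draws (baselines, marker choice,
#'   population offsets).
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(n_proteins,
                         populations,
                         n_markers = 0L,
                         marker_ids = NULL,
                         beta = 0.6,
                         h2 = 0.3,
                         sigma_colony = 0.45,
                         sigma_resid = 0.6,
                         sigma_block = 0.3,
                         sigma_label = 0.15,
                         baseline_mean = 13.8,
                         baseline_sd = 1.5,
                         pop_effect_sd = 0.15,
                         pop_effect_fraction = 0.1,
                         missing_model = list(rate = 0.25, mcar = 0.05,
                                              abundance_weight = 1),
                         seed = 1L) {
  stopifnot(n_proteins >= 1, all(h2 >= 0), all(h2 <= 1),
            sigma_colony >= 0, sigma_resid >= 0, sigma_block >= 0,
            sigma_label >= 0, pop_effect_sd >= 0)
  rate <- missing_model$rate %||% 0
  mcar <- missing_model$mcar %||% 0
  stopifnot(rate >= 0, rate < 1, mcar >= 0, mcar <= rate)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  with_seed(seed, {
    if (is.null(marker_ids)) {
      marker_ids <- if (n_markers > 0) sort(sample(proteins, n_markers)) else character()
    } else {
      marker_ids <- as.character(marker_ids)
    }
    if (!all(marker_ids %in% proteins)) {
      stop("marker_ids must be a subset of the simulated protein set",
           call. = FALSE)
    }
    beta <- setNames(rep_len(beta, length(marker_ids)), marker_ids)
    baseline <- rnorm(n_proteins, baseline_mean, baseline_sd)
    pop_effects <- matrix(0, n_proteins, length(populations),
                          dimnames = list(proteins, populations))
    if (pop_effect_sd > 0 && pop_effect_fraction > 0) {
      aff <- runif(n_proteins) < pop_effect_fraction
      pop_effects[aff, ] <- rnorm(sum(aff) * length(populations), 0,
                                  pop_effect_sd)
    }
    structure(list(proteins = proteins,
                   marker_ids = marker_ids,
                   beta = beta,
                   h2 = rep_len(h2, n_proteins),
                   sigma_colony = sigma_colony,
                   sigma_resid = sigma_resid,
                   sigma_block = sigma_block,
                   sigma_label = sigma_label,
                   baseline = setNames(baseline, proteins),
                   pop_effects = pop_effects,
                   missing_model = list(rate = rate, mcar = mcar,
                                        abundance_weight =
                                          missing_model$abundance_weight %||% 1),
                   seed = seed),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$proteins), "proteins,",
      length(x$marker_ids), "planted markers; h2 mean",
      round(mean(x$h2), 3), "; missing rate", x$missing_model$rate, "\n")
  invisible(x)
}

#' Simulate colony additive-genetic expression values over a pedigree
#'
#' Founders receive independent N(0, h2 * sigma_colony^2) additive values
#' per protein; offspring receive the midparent mean plus Mendelian
#' segregation noise of variance h2 * sigma_colony^2 / 2, so the additive
#' variance is stationary across generations and the expected
#' offspring-midparent regression slope equals `h2` when the environmental
#' variance is `(1 - h2) * sigma_colony^2`.
#'
#' @param pedigree `data.frame` with `colony_id`, `dam_id`, `sire_id`
#'   (NA parents = founder). Parents must precede offspring or at least be
#'   resolvable; rows are processed in dependency order.
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @return Matrix (protein x colony) of additive-genetic values.
#' @export
simulate_genetic_values <- function(pedigree, truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  ids <- pedigree$colony_id
  if (anyDuplicated(ids)) stop("duplicated colony ids in pedigree", call. = FALSE)
  np <- length(truth$proteins)
  sd_founder <- sqrt(truth$h2) * truth$sigma_colony
  a <- matrix(NA_real_, np, length(ids), dimnames = list(truth$proteins, ids))
  with_seed(seed, {
    done <- rep(FALSE, length(ids))
    for (pass in seq_along(ids)) {
      todo <- which(!done)
      if (!length(todo)) break
      progressed <- FALSE
      for (i in todo) {
        d <- pedigree$dam_id[i]; s <- pedigree$sire_id[i]
        founder <- is.na(d) || is.na(s)
        if (founder) {
          a[, i] <- rnorm(np, 0, sd_founder)
        } else {
          if (!(d %in% ids) || !(s %in% ids)) {
            stop("pedigree error: parent(s) of '", ids[i],
                 "' not in pedigree", call. = FALSE)
          }
          di <- match(d, ids); si <- match(s, ids)
          if (!done[di] || !done[si]) next
          a[, i] <- (a[, di] + a[, si]) / 2 +
            rnorm(np, 0, sd_founder / sqrt(2))
        }
        done[i] <- TRUE; progressed <- TRUE
      }
      if (!progressed) stop("pedigree error: cycle or unresolvable order",
                            call. = FALSE)
    }
  })
  a
}

#' Simulate a block-structured protein quantification matrix
#'
#' Produces raw intensities for every (protein, block, label) cell of the
#' assignment, from the generative model: log-intensity = protein baseline
#' + population offset + planted HB effect (beta x standardized latent
#' propensity) + colony effect (additive genetic + environmental) + block
#' offset + label offset + residual. Whole (protein, block) triples are
#' then removed by an abundance-dependent plus completely-at-random
#' missingness mechanism.
#'
#' @param colonies colony frame covering every colony in the assignment.
#' @param assignment a `block_assignment` from [build_design()].
#' @param truth a [ground_truth()]; its `populations` must cover the
#'   colonies' populations.
#' @param seed integer seed.
#' @param genetic_values optional precomputed protein x colony matrix from
#'   [simulate_genetic_values()] (lets several datasets share the genetic
#'   values of colonies in a multi-generation study). Defaults to values
#'   drawn from the pedigree inside `colonies`.
#' @return A [quant_matrix()] in `raw` state with elements `truth` (the
#'   `ground_truth`) and `truth_components` (per-colony standardized
#'   propensity and colony effects) attached.
#' @export
simulate_quant <- function(colonies, assignment, truth, seed = 1L,
                           genetic_values = NULL) {
  stopifnot(inherits(assignment, "block_assignment"),
            inherits(truth, "ground_truth"))
  b <- assignment$blocks
  if (!setequal(b$colony_id, colonies$colony_id)) {
    stop("consistency error: assignment and colony frame cover different ",
         "colony sets", call. = FALSE)
  }
  bad_pop <- setdiff(colonies$population, colnames(truth$pop_effects))
  if (length(bad_pop)) {
    stop("truth has no population effects for: ",
         paste(bad_pop, collapse = ", "), call. = FALSE)
  }
  np <- length(truth$proteins)
  nc <- nrow(colonies)
  seeds <- split_seeds(seed, 4L)
  if (is.null(genetic_values)) {
    genetic_values <- simulate_genetic_values(
      colonies[, c("colony_id", "dam_id", "sire_id")], truth, seeds[1])
  }
  if (!all(colonies$colony_id %in% colnames(genetic_values))) {
    stop("genetic_values missing columns for some colonies", call. = FALSE)
  }
  a <- genetic_values[, colonies$colony_id, drop = FALSE]

  hb <- colonies$hb_true
  z <- if (sd(hb) > 0) (hb - mean(hb)) / sd(hb) else rep(0, nc)
  sigma_unit <- sqrt(truth$sigma_colony^2 + truth$sigma_resid^2)
  beta_full <- setNames(numeric(np), truth$proteins)
  beta_full[names(truth$beta)] <- truth$beta

  with_seed(seeds[2], {
    env <- matrix(rnorm(np * nc, 0,
                        sqrt(pmax(0, 1 - truth$h2)) * truth$sigma_colony),
                  np, nc)
    colony_eff <- a + env
    blocks <- sort(unique(b$block_id))
    block_off <- setNames(rnorm(length(blocks), 0, truth$sigma_block), blocks)
    label_off <- setNames(rnorm(3, 0, truth$sigma_label), LABELS)

    ci <- match(b$colony_id, colonies$colony_id)
    n_cells <- nrow(b)
    # log-intensity matrix: proteins x sample slots
    li <- matrix(truth$baseline, np, n_cells) +
      truth$pop_effects[, colonies$population[ci], drop = FALSE] +
      outer(beta_full * sigma_unit, z[ci]) +
      colony_eff[, ci, drop = FALSE] +
      matrix(block_off[b$block_id], np, n_cells, byrow = TRUE) +
      matrix(label_off[b$label], np, n_cells, byrow = TRUE) +
      matrix(rnorm(np * n_cells, 0, truth$sigma_resid), np, n_cells)

    # block-level missingness: whole triples, abundance-dependent + MCAR
    mm <- truth$missing_model
    keep <- matrix(TRUE, np, length(blocks), dimnames = list(truth$proteins, blocks))
    if (mm$rate > 0) {
      zb <- as.numeric(scale(truth$baseline))
      base_rate <- (mm$rate - mm$mcar) / (1 - mm$mcar)
      p_logit <- if (base_rate > 0) {
        plogis(qlogis(base_rate) - mm$abundance_weight * zb)
      } else rep(0, np)
      p_miss <- mm$mcar + (1 - mm$mcar) * p_logit
      keep[] <- matrix(runif(np * length(blocks)), np) >=
        matrix(p_miss, np, length(blocks))
    }

    long <- data.frame(
      protein = rep(truth$proteins, times = n_cells),
      block = rep(b$block_id, each = np),
      label = rep(b$label, each = np),
      intensity = exp(as.vector(li)),
      stringsAsFactors = FALSE
    )
    present <- keep[cbind(match(long$protein, truth$proteins),
                          match(long$block, blocks))]
    qm <- quant_matrix(long[present, ], blocks = blocks, state = "raw",
                       provenance = sprintf(
                         "simulated: %d proteins x %d blocks, seed %s",
                         np, length(blocks), format(seed)))
    qm$truth <- truth
    qm$truth_components <- list(
      z_hb = setNames(z, colonies$colony_id),
      colony_effect = colony_eff,
      genetic_values = a,
      sigma_unit = sigma_unit)
    qm
  })
}
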
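#' Simulate peptide-spectrum matches with a target-decoy score mixture
#'
#' Generates a PSM table emulating a database-search result: target
#' proteins with several peptides each, a fraction of peptides shared
#' between two proteins, a few proteins whose peptide sets are subsets of
#' another protein's (exercising parsimony absorption), continuous scores
#' from a two-component correct/incorrect mixture, and decoy PSMs drawn
#' only from the incorrect component. The hidden correctness label of each
#' PSM is returned so realized false-discovery proportions can be scored.
#'
#' By default the decoy count matches the expected number of incorrect
#' target PSMs (`decoy_fraction = (1 - prop_correct) / (2 - prop_correct)`),
#' the standard premise of concatenated target-decoy search that makes the
#' decoy count an unbiased estimate of incorrect targets.
#'
#' @param n_target_proteins number of target proteins.
#' @param peptides_per_protein peptides per target protein.
#' @param decoy_fraction fraction of all PSM rows that are decoys.
#' @param score_model list with `mean_correct`, `sd_correct`,
#'   `mean_incorrect`, `sd_incorrect`, `prop_correct` (mixture weight of
#'   the correct component among target PSMs).
#' @param shared_peptide_rate fraction of peptides mapped to a second
#'   random protein.
#' @param subset_protein_rate fraction of proteins replaced by "subset"
#'   proteins whose peptides are a strict subset of another protein's.
#' @param block block id stamped on the table (a block is one MS run).
#' @param seed integer seed.
#' @return `data.frame` with columns `psm_id`, `peptide_id`, `protein_ids`
#'   (`;`-separated accessions), `score`, `decoy`, `correct` (ground
#'   truth), `block`, `intensity_light`, `intensity_medium`,
#'   `intensity_heavy`.
#' @export
simulate_psms <- function(n_target_proteins,
                          peptides_per_protein = 5L,
                          decoy_fraction = NULL,
                          score_model = list(mean_correct = 45, sd_correct = 8,
                                             mean_incorrect = 15, sd_incorrect = 8,
                                             prop_correct = 0.75),
                          shared_peptide_rate = 0.1,
                          subset_protein_rate = 0.1,
                          block = "B001",
                          seed = 1L) {
  pc <- score_model$prop_correct %||% 0.75
  stopifnot(n_target_proteins >= 1, peptides_per_protein >= 1,
            pc >= 0, pc <= 1,
            shared_peptide_rate >= 0, shared_peptide_rate <= 1,
            subset_protein_rate >= 0, subset_protein_rate <= 1)
  if (is.null(decoy_fraction)) decoy_fraction <- (1 - pc) / (2 - pc)
  stopifnot(decoy_fraction >= 0, decoy_fraction <= 1)

  with_seed(seed, {
    prot <- sprintf("TP%03d", seq_len(n_target_proteins))
    pep_of <- lapply(seq_len(n_target_proteins), function(i)
      sprintf("pep_%03d_%02d", i, seq_len(peptides_per_protein)))
    # subset proteins: protein i's peptides become a strict subset of i-1's
    if (n_target_proteins >= 2 && subset_protein_rate > 0 &&
        peptides_per_protein >= 2) {
      subs <- which(runif(n_target_proteins) < subset_protein_rate)
      subs <- setdiff(subs, 1L)
      for (i in subs) {
        donor <- i - 1L
        if (length(pep_of[[donor]]) < 2L) next  # donor already a singleton
        k <- sample(seq_len(length(pep_of[[donor]]) - 1L), 1L)
        pep_of[[i]] <- sample(pep_of[[donor]], k)
      }
    }
    map <- data.frame(peptide_id = unlist(pep_of),
                      protein = rep(prot, lengths(pep_of)),
                      stringsAsFactors = FALSE)
    # collapse duplicated (peptide within protein) and build peptide->proteins
    map <- unique(map)
    pep_ids <- unique(map$peptide_id)
    prot_of_pep <- split(map$protein, map$peptide_id)[pep_ids]
    # shared peptides: add a second protein mapping
    share <- runif(length(pep_ids)) < shared_peptide_rate
    for (i in which(share)) {
      others <- setdiff(prot, prot_of_pep[[i]])
      if (length(others)) {
        prot_of_pep[[i]] <- sort(c(prot_of_pep[[i]], sample(others, 1L)))
      }
    }
    n_target <- length(pep_ids)
    n_decoy <- if (decoy_fraction >= 1) stop("decoy_fraction must be < 1") else
      round(n_target * decoy_fraction / (1 - decoy_fraction))

    correct_t <- runif(n_target) < pc
    sc_t <- ifelse(correct_t,
                   rnorm(n_target, score_model$mean_correct %||% 45,
                         score_model$sd_correct %||% 8),
                   rnorm(n_target, score_model$mean_incorrect %||% 15,
                         score_model$sd_incorrect %||% 8))
    sc_d <- rnorm(n_decoy, score_model$mean_incorrect %||% 15,
                  score_model$sd_incorrect %||% 8)

    ratios <- exp(matrix(rnorm(3 * (n_target + n_decoy), 10, 1),
                         ncol = 3))
    out <- data.frame(
      psm_id = sprintf("PSM%05d", seq_len(n_target + n_decoy)),
      peptide_id = c(pep_ids, sprintf("dec_pep_%04d", seq_len(n_decoy))),
      protein_ids = c(vapply(prot_of_pep, paste, "", collapse = ";"),
                      sprintf("DECOY_TP%03d",
                              sample.int(n_target_proteins, n_decoy,
                                         replace = TRUE))),
      score = c(sc_t, sc_d),
      decoy = rep(c(FALSE, TRUE), c(n_target, n_decoy)),
      correct = c(correct_t, rep(FALSE, n_decoy)),
      block = block,
      intensity_light = ratios[, 1],
      intensity_medium = ratios[, 2],
      intensity_heavy = ratios[, 3],
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}
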
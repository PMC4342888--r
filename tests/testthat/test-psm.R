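test_that("zero decoys: threshold is the score gate, all gated targets pass", {
  psms <- simulate_psms(10, 4, decoy_fraction = 0, seed = 1)
  expect_equal(sum(psms$decoy), 0L)
  out <- decoy_fdr_filter(psms, fdr = 0.01, min_score = 25)
  expect_equal(out$thresholds$threshold, 25)
  expect_setequal(out$psms$psm_id, psms$psm_id[psms$score >= 25])
})

test_that("fully separated score components accept every correct PSM", {
  psms <- simulate_psms(20, 5,
                        score_model = list(mean_correct = 100, sd_correct = 1,
                                           mean_incorrect = 10, sd_incorrect = 1,
                                           prop_correct = 0.7),
                        seed = 2)
  out <- decoy_fdr_filter(psms, fdr = 0.01, min_score = 25)
  expect_setequal(out$psms$peptide_id,
                  psms$peptide_id[psms$correct])
})

test_that("threshold equals the exhaustive scan oracle", {
  for (s in 1:5) {
    psms <- simulate_psms(30, 4, seed = s,
                          score_model = list(mean_correct = 40, sd_correct = 10,
                                             mean_incorrect = 20, sd_incorrect = 10,
                                             prop_correct = 0.6))
    t_pkg <- decoy_fdr_filter(psms, fdr = 0.05, min_score = 0)$thresholds$threshold
    t_orc <- fdr_threshold_oracle(psms$score, psms$decoy, 0.05)
    expect_equal(t_pkg, max(t_orc, 0))
  }
})

test_that("decoy-dominated tables yield an empty set with a warning", {
  psms <- data.frame(psm_id = sprintf("p%d", 1:11),
                     peptide_id = sprintf("pep%d", 1:11),
                     protein_ids = "TP001",
                     score = c(30:39, 50),
                     decoy = c(rep(FALSE, 10), TRUE),
                     block = "B001", stringsAsFactors = FALSE)
  expect_warning(out <- decoy_fdr_filter(psms, fdr = 0.01), "accepting nothing")
  expect_equal(nrow(out$psms), 0L)
})

test_that("realized FDP stays near nominal over repeated simulations", {
  fdp <- vapply(1:25, function(s) {
    psms <- simulate_psms(120, 5, seed = 100 + s)
    acc <- decoy_fdr_filter(psms, fdr = 0.01, min_score = 0)$psms
    if (nrow(acc) == 0) return(0)
    sum(!acc$correct) / nrow(acc)
  }, 0)
  expect_lte(mean(fdp), 0.02)
})

test_that("per-block thresholds are independent", {
  p1 <- simulate_psms(20, 4, block = "B001", seed = 3)
  p2 <- simulate_psms(20, 4, block = "B002", seed = 4,
                      score_model = list(mean_correct = 60, sd_correct = 5,
                                         mean_incorrect = 30, sd_incorrect = 5,
                                         prop_correct = 0.8))
  out <- decoy_fdr_filter(rbind(p1, p2), fdr = 0.05, min_score = 0)
  expect_equal(nrow(out$thresholds), 2L)
  expect_false(out$thresholds$threshold[1] == out$thresholds$threshold[2])
})

test_that("parsimony absorbs subset and identical-set proteins", {
  mk <- function(pep, prot) data.frame(
    psm_id = paste0("m", seq_along(pep)), peptide_id = pep,
    protein_ids = prot, score = 50, decoy = FALSE, block = "B001",
    intensity_light = 2, intensity_medium = 4, intensity_heavy = 8,
    stringsAsFactors = FALSE)
  # A{p1,p2}, B{p2}: single group led by A, B absorbed
  out <- parsimony_group(mk(c("p1", "p2"), c("A", "A;B")))
  expect_equal(nrow(out$groups), 1L)
  expect_equal(out$groups$lead_protein, "A")
  expect_match(out$groups$proteins, "B")
  # disjoint: two groups
  out2 <- parsimony_group(mk(c("p1", "p2"), c("A", "B")))
  expect_equal(nrow(out2$groups), 2L)
  # identical sets merge
  out3 <- parsimony_group(mk(c("p1", "p2"), c("A;B", "A;B")))
  expect_equal(nrow(out3$groups), 1L)
  expect_equal(out3$groups$proteins, "A;B")
  # log-ratio averaging: log(4/2), log(8/2), log(8/4)
  expect_equal(out$ratios$log_ratio_ml, log(2), tolerance = 1e-12)
  expect_equal(out$ratios$log_ratio_hl, log(4), tolerance = 1e-12)
  expect_equal(out$ratios$log_ratio_hm, log(2), tolerance = 1e-12)
})

test_that("parsimony group count equals the exact set-cover optimum", {
  for (s in 1:30) {
    psms <- simulate_psms(sample(6:12, 1), sample(2:4, 1),
                          decoy_fraction = 0,
                          shared_peptide_rate = 0.3,
                          subset_protein_rate = 0.3, seed = 200 + s)
    out <- parsimony_group(psms)
    sets <- strsplit(psms$protein_ids, ";", fixed = TRUE)
    pairs <- unique(data.frame(
      pep = rep(psms$peptide_id, lengths(sets)), prot = unlist(sets)))
    pep_sets <- lapply(split(pairs$pep, pairs$prot), unique)
    expect_equal(nrow(out$groups), set_cover_min(pep_sets))
    # coverage: the selected leads' peptide sets explain every peptide
    covered_peps <- unique(unlist(pep_sets[out$groups$lead_protein]))
    expect_true(all(pairs$pep %in% covered_peps))
  }
})

test_that("parsimony output is invariant to input row order", {
  psms <- simulate_psms(10, 4, decoy_fraction = 0, seed = 5,
                        shared_peptide_rate = 0.3, subset_protein_rate = 0.3)
  out1 <- parsimony_group(psms)
  out2 <- parsimony_group(psms[rev(seq_len(nrow(psms))), ])
  expect_equal(out1$groups, out2$groups)
  expect_equal(out1$ratios, out2$ratios)
})

test_that("no shared peptides and no subsets: every protein is its own group", {
  psms <- simulate_psms(12, 3, decoy_fraction = 0, shared_peptide_rate = 0,
                        subset_protein_rate = 0, seed = 6)
  out <- parsimony_group(psms)
  expect_equal(nrow(out$groups), 12L)
})
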
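test_that("dataset HB factor follows the declared formula", {
  # s = -log10(0.1) = 1, b = 0, agreeing sign: 1 * 1 * (1+0)/2 = 0.5
  expect_equal(dataset_hb_factor(0.1, 0, 1), 0.5)
  # p = 1: statistical factor 0 regardless of effect
  expect_equal(dataset_hb_factor(1, 5, 1), 0)
  # sign symmetry: flipping the reference negates the factor
  f1 <- dataset_hb_factor(0.01, 0.5, 1)
  f2 <- dataset_hb_factor(0.01, 0.5, -1)
  expect_equal(f1, -f2)
  # caps: p = 0 uses the stat cap; huge effects cap at bio_cap
  expect_equal(dataset_hb_factor(0, 0, 1), 10 * 0.5)
  expect_equal(dataset_hb_factor(0.1, 100, 1), 1 * (1 + 2) / 2)
  # NA propagates as exclusion
  expect_true(is.na(dataset_hb_factor(NA, 1, 1)))
  expect_true(is.na(dataset_hb_factor(0.5, NA, 1)))
})

test_that("overall score is the factor mean plus the heritability factor", {
  s <- overall_score(c(5, 5, 5, 5), heritability = 1)
  expect_equal(s$correlation_score, 6)
  expect_true(s$eligible)
  s2 <- overall_score(c(1, 2, NA, NA, NA, NA), heritability = 0)
  expect_equal(s2$n_datasets_quantified, 2L)
  expect_false(s2$eligible)  # fewer than 4 of 6 datasets
  expect_equal(overall_score(rep(0, 6), 0)$correlation_score, 0)
  expect_error(overall_score(c(NA_real_, NA_real_)), "no dataset")
})

test_that("heritability factor weights the slope sum by the joint p", {
  fits <- data.frame(protein_id = c("A", "B", "C", "D"),
                     slope_dam = c(0.3, -0.4, 0.3, 0.3),
                     slope_sire = c(0.2, 0.1, 0.2, 0.2),
                     joint_p = c(0.01, 0.01, 0.3, 0.7),
                     n_trios = c(20, 20, 20, 20))
  f <- heritability_factor(fits)
  expect_equal(unname(f), c(0.5 * 1, 0, 0.5 * 0.5, 0.5 * 0.25))
  # too few trios: factor 0
  fits$n_trios <- 2
  expect_equal(unname(heritability_factor(fits)), rep(0, 4))
})

test_that("dam/sire regression recovers constructed heritability exactly", {
  # offspring level = exact midparent mean: slopes 0.5 + 0.5
  set.seed(42)
  n <- 30
  dam <- rnorm(n); sire <- rnorm(n)
  expr <- data.frame(
    protein_id = "P1",
    colony_id = c(sprintf("D%d", 1:n), sprintf("S%d", 1:n),
                  sprintf("O%d", 1:n)),
    value = c(dam, sire, (dam + sire) / 2))
  ped <- data.frame(colony_id = sprintf("O%d", 1:n),
                    dam_id = sprintf("D%d", 1:n),
                    sire_id = sprintf("S%d", 1:n))
  fit <- fit_heritability(expr, ped)
  expect_equal(fit$slope_dam, 0.5, tolerance = 1e-10)
  expect_equal(fit$slope_sire, 0.5, tolerance = 1e-10)
  expect_lt(fit$joint_p, 1e-10)
  expect_equal(fit$n_trios, n)
  # missing parents shrink the trio count; below 3 the fit is withheld
  fit2 <- fit_heritability(expr[-(1:(2 * n - 2)), ], ped)
  expect_true(is.na(fit2$slope_dam))
  expect_match(fit2$notes, "too few trios")
})

test_that("simulated trios recover the generative heritability on average", {
  # colony-level expression via the additive model: E[slope sum] = h2
  h2 <- 0.6
  sums <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    n <- 60
    va <- h2; ve <- 1 - h2
    gd <- rnorm(n, 0, sqrt(va)); gs <- rnorm(n, 0, sqrt(va))
    xd <- gd + rnorm(n, 0, sqrt(ve)); xs <- gs + rnorm(n, 0, sqrt(ve))
    y <- (gd + gs) / 2 + rnorm(n, 0, sqrt(va / 2)) + rnorm(n, 0, sqrt(ve))
    expr <- data.frame(
      protein_id = "P1",
      colony_id = c(sprintf("D%d", 1:n), sprintf("S%d", 1:n),
                    sprintf("O%d", 1:n)),
      value = c(xd, xs, y))
    ped <- data.frame(colony_id = sprintf("O%d", 1:n),
                      dam_id = sprintf("D%d", 1:n),
                      sire_id = sprintf("S%d", 1:n))
    fit <- fit_heritability(expr, ped)
    fit$slope_dam + fit$slope_sire
  }, 0)
  expect_lt(abs(mean(sums) - h2), 0.1)
})

test_that("rank_markers is invariant to dataset and protein order", {
  mk_res <- function(prot, p, eff) data.frame(
    protein_id = prot, predictor = "r24", effect = eff, se = 0.1,
    p_value = p, q_value = p, n_obs = 90, converged = TRUE, notes = "",
    stringsAsFactors = FALSE)
  prot <- sprintf("P%02d", 1:6)
  set.seed(3)
  res <- list(d1 = mk_res(prot, runif(6), rnorm(6)),
              d2 = mk_res(prot, runif(6), rnorm(6)),
              d3 = mk_res(rev(prot), runif(6), rnorm(6)),
              d4 = mk_res(prot, runif(6), rnorm(6)))
  s1 <- rank_markers(res)
  s2 <- rank_markers(res[c(3, 1, 4, 2)])
  expect_equal(s1$correlation_score,
               s2$correlation_score[match(s1$protein_id, s2$protein_id)],
               tolerance = 1e-12)
  # shuffling rows within a dataset does not matter either
  res$d1 <- res$d1[sample(6), ]
  s3 <- rank_markers(res)
  expect_equal(s1$correlation_score,
               s3$correlation_score[match(s1$protein_id, s3$protein_id)],
               tolerance = 1e-12)
})

test_that("decreasing a p-value never decreases the correlation score", {
  mk_res <- function(p) data.frame(
    protein_id = "P1", predictor = "r24", effect = 0.5, se = 0.1,
    p_value = p, q_value = p, n_obs = 90, converged = TRUE, notes = "",
    stringsAsFactors = FALSE)
  base <- list(a = mk_res(0.02), b = mk_res(0.3))
  s_base <- rank_markers(base)$correlation_score
  for (p in c(0.1, 0.05, 0.01, 1e-4)) {
    s <- rank_markers(list(a = mk_res(0.02), b = mk_res(p)))$correlation_score
    if (p <= 0.3) expect_gte(s, s_base - 1e-12)
    s_base_step <- s
  }
})

test_that("selection routes apply the study thresholds", {
  prot <- c("P1", "P2", "P3", "P4")
  scores <- data.frame(protein_id = prot,
                       n_datasets_quantified = c(6, 5, 3, 6),
                       heritability_factor = 0,
                       correlation_score = c(5, 3, 10, 1),
                       eligible = c(TRUE, TRUE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
  ref <- data.frame(protein_id = prot, predictor = "r24",
                    effect = 1, se = 1,
                    p_value = c(2e-4, 0.03, 0.5, 0.2),
                    q_value = c(0.056, 0.09, 0.8, 0.4),
                    n_obs = 90, converged = TRUE, notes = "",
                    stringsAsFactors = FALSE)
  mk_site <- function(pvals) do.call(rbind, lapply(
    c("r24", "r48", "u24", "u48"), function(pr) data.frame(
      protein_id = prot, predictor = pr, effect = 1, se = 1,
      p_value = pvals, q_value = pvals, n_obs = 90, converged = TRUE,
      notes = "", stringsAsFactors = FALSE)))
  site1 <- mk_site(c(0.01, 0.06, 0.01, 0.2))
  site2 <- mk_site(c(0.02, 0.01, 0.01, 0.3))
  sel <- select_markers(scores, ref, list(site1, site2),
                        rules = list(top_k = 1))
  # P1: q = 0.056 < 0.1 (the study's reported Q for its two headline
  # proteins) and p < 5e-4 -> both reference tags; also all-parameter
  # two-site hit and the top score among eligible proteins
  expect_match(sel$rules_hit[sel$protein_id == "P1"], "reference_q")
  expect_match(sel$rules_hit[sel$protein_id == "P1"], "reference_strict_p")
  expect_match(sel$rules_hit[sel$protein_id == "P1"], "two_site")
  expect_match(sel$rules_hit[sel$protein_id == "P1"], "top_rank")
  # P2: q = 0.09 passes route (a) but p = 0.06 at site 1 fails route (b)
  expect_match(sel$rules_hit[sel$protein_id == "P2"], "reference_q")
  expect_false(grepl("two_site", sel$rules_hit[sel$protein_id == "P2"]))
  # P3: best score but ineligible (3 of 6 datasets) -> not top-ranked
  expect_false(sel$route_top_rank[sel$protein_id == "P3"])
  expect_false(sel$selected[sel$protein_id == "P4"])
  # missing reference dataset: route (a) skipped with a warning
  expect_warning(select_markers(scores, NULL, list(site1, site2)),
                 "skipped")
})
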
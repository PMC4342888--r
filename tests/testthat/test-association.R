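test_that("the fast block-absorbed fit matches lm with block dummies", {
  ds <- tiny_dataset(seed = 21)
  nm <- normalize_quant(ds$quant)
  res <- fit_protein_model(nm, "P0001", ds$assignment, ds$colonies)
  d <- nm$data[nm$data$protein == "P0001", ]
  st <- merge(d, ds$assignment$blocks, by.x = c("block", "label"),
              by.y = c("block_id", "label"))
  st$x <- ds$colonies$r24[match(st$colony_id, ds$colonies$colony_id)]
  ref <- summary(lm(intensity ~ x + factor(label) + factor(block),
                    data = st))$coefficients["x", ]
  expect_equal(res$effect, unname(ref[1]), tolerance = 1e-10)
  expect_equal(res$se, unname(ref[2]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ref[4]), tolerance = 1e-10)
})

test_that("a planted slope is recovered within sampling error", {
  ds <- tiny_dataset(n_per_pop = 16, pops = c("A", "B", "C", "D"),
                     n_proteins = 40, n_markers = 4, beta = 0.8,
                     sigma_colony = 0.1, seed = 22)
  nm <- normalize_quant(ds$quant)
  # regress on the exact standardized latent propensity: the generative
  # slope on the normalized scale is then beta * sigma_unit / label-MAD
  cols <- ds$colonies
  cols$z <- as.numeric(scale(cols$hb_true))
  res <- run_dataset(nm, ds$assignment, cols, predictors = "z")
  mk <- ds$truth$marker_ids
  hit <- res[res$protein_id %in% mk, ]
  expected <- 0.8 * ds$quant$truth_components$sigma_unit /
    mean(nm$label_stats$mad)
  expect_true(all(abs(hit$effect - expected) < 3 * hit$se))
  expect_true(all(hit$q_value < 0.05))
  # non-markers are centered on zero effect
  null_eff <- res$effect[!res$protein_id %in% mk & res$converged]
  expect_lt(abs(mean(null_eff / res$se[!res$protein_id %in% mk &
                                         res$converged])), 0.5)
})

test_that("p-values are uniform under a permuted predictor", {
  ds <- tiny_dataset(n_per_pop = 10, pops = c("A", "B", "C"),
                     n_proteins = 300, n_markers = 0, sigma_colony = 0,
                     seed = 23)
  cols <- ds$colonies
  set.seed(77)
  cols$r24 <- sample(cols$r24)  # break any accidental structure
  nm <- normalize_quant(ds$quant)
  res <- run_dataset(nm, ds$assignment, cols, predictors = "r24")
  ks <- suppressWarnings(stats::ks.test(res$p_value[res$converged], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate responses are reported, not fatal", {
  ds <- tiny_dataset(seed = 24)
  qm <- ds$quant
  # constant protein: zero-variance response
  qm$data$intensity[qm$data$protein == "P0001"] <- 100
  nm <- suppressWarnings(normalize_quant(qm))
  res <- fit_protein_model(nm, "P0001", ds$assignment, ds$colonies)
  expect_false(res$converged)
  expect_true(res$p_value == 1 || is.na(res$p_value))

  # constant predictor
  cols <- ds$colonies
  cols$r24 <- 0.4
  res2 <- fit_protein_model(nm, "P0002", ds$assignment, cols)
  expect_false(res2$converged)
  expect_match(res2$notes, "constant")
})

test_that("BH q-values match the hand-computed step-up values", {
  expect_equal(compute_qvalues(0.01), 0.01)
  expect_equal(compute_qvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(compute_qvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.9)
  expect_equal(compute_qvalues(p), bh_oracle(p))
  # invariants: q >= p and monotone in p
  set.seed(9)
  p2 <- runif(200)
  q2 <- compute_qvalues(p2)
  expect_true(all(q2 >= p2 - 1e-12))
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_error(compute_qvalues(c(0.5, 1.2)), "0, 1")
  expect_identical(compute_qvalues(numeric()), numeric())
})

test_that("consistently permuting label codes leaves p-values unchanged", {
  ds <- tiny_dataset(seed = 25)
  nm <- normalize_quant(ds$quant)
  res1 <- run_dataset(nm, ds$assignment, ds$colonies)
  swap <- function(v) c(light = "medium", medium = "light",
                        heavy = "heavy")[v]
  qm2 <- ds$quant
  qm2$data$label <- unname(swap(qm2$data$label))
  asg2 <- ds$assignment
  asg2$blocks$label <- unname(swap(asg2$blocks$label))
  res2 <- run_dataset(normalize_quant(qm2), asg2, ds$colonies)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-9)
  expect_equal(res1$effect, res2$effect, tolerance = 1e-9)
})

test_that("the mixed model engages on incomplete blocks and agrees with the
           fixed-effects path when the block component vanishes", {
  ds <- tiny_dataset(n_per_pop = 8, pops = c("A", "B", "C"),
                     n_proteins = 10, n_markers = 0, seed = 26)
  nm <- normalize_quant(ds$quant)
  # forcing lmm on complete-triple standardized data must fall back
  res_lmm <- fit_protein_model(nm, "P0003", ds$assignment, ds$colonies,
                               engine = "lmm")
  res_ols <- fit_protein_model(nm, "P0003", ds$assignment, ds$colonies,
                               engine = "ols")
  expect_match(res_lmm$notes, "fallback|ols")
  expect_equal(res_lmm$effect, res_ols$effect, tolerance = 1e-8)

  # genuinely incomplete blocks (cell-level missingness): lmm path runs
  qm <- ds$quant
  set.seed(5)
  qm$data <- qm$data[-sample(nrow(qm$data), round(0.2 * nrow(qm$data))), ]
  nm2 <- normalize_quant(qm)
  res3 <- fit_protein_model(nm2, "P0003", ds$assignment, ds$colonies,
                            engine = "lmm")
  expect_true(is.finite(res3$p_value))
})

test_that("population-adjusted and categorical-predictor fits work", {
  ds <- tiny_dataset(n_per_pop = 8, pops = c("A", "B", "C"),
                     n_proteins = 20, n_markers = 0, seed = 27,
                     pop_effect_sd = 0.5, pop_effect_fraction = 1)
  nm <- normalize_quant(ds$quant)
  radj <- run_dataset(nm, ds$assignment, ds$colonies, predictors = "r24",
                      adjust_population = TRUE)
  expect_true(all(is.finite(radj$p_value[radj$converged])))
  rpop <- run_dataset(nm, ds$assignment, ds$colonies,
                      predictors = "population")
  expect_true(all(is.finite(rpop$p_value[rpop$converged])))
  # strong planted population effects: population predictor is significant
  expect_lt(median(rpop$p_value, na.rm = TRUE), 0.05)
})

test_that("run_dataset handles empty matrices and logs a summary", {
  ds <- tiny_dataset(seed = 28)
  qm <- ds$quant
  qm$data <- qm$data[0, ]
  expect_warning(res <- run_dataset(qm, ds$assignment, ds$colonies),
                 "no proteins")
  expect_equal(nrow(res), 0L)
  nm <- normalize_quant(ds$quant)
  res2 <- run_dataset(nm, ds$assignment, ds$colonies,
                      predictors = c("r24", "u48"))
  expect_match(attr(res2, "log"), "2 predictor")
  # q-values computed per predictor, each monotone
  for (pr in c("r24", "u48")) {
    sub <- res2[res2$predictor == pr & !is.na(res2$p_value), ]
    expect_true(all(diff(sub$q_value[order(sub$p_value)]) >= -1e-12))
  }
})
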
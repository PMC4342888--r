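# Small fixture builders shared across test files.

colony_frame <- function(x, pop, site = "S", year = "Y1") {
  n <- length(x)
  data.frame(colony_id = sprintf("C%02d", seq_len(n)), site = site,
             year = year, population = pop, hb_true = x,
             r24 = x, r48 = x, u24 = x, u48 = x,
             dam_id = NA_character_, sire_id = NA_character_,
             stringsAsFactors = FALSE)
}

# a small complete simulated dataset: colonies + design + raw matrix
tiny_dataset <- function(n_per_pop = 4, pops = c("A", "B", "C"),
                         n_proteins = 30, n_markers = 2, beta = 0.8,
                         missing_rate = 0, seed = 1,
                         sigma_colony = 0.45, sigma_resid = 0.6, ...) {
  s <- hbmarkers::split_seeds(seed, 4)
  cols <- simulate_colonies(n_per_pop, pops, seed = s[1])
  asg <- build_design(cols, n_restarts = 2, seed = s[2])
  tr <- ground_truth(n_proteins, pops, n_markers = n_markers, beta = beta,
                     sigma_colony = sigma_colony, sigma_resid = sigma_resid,
                     missing_model = list(rate = missing_rate,
                                          mcar = min(0.05, missing_rate)),
                     seed = s[3], ...)
  qm <- simulate_quant(cols, asg, tr, seed = s[4])
  list(colonies = cols, assignment = asg, truth = tr, quant = qm)
}
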
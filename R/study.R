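#' Simulate a two-site, three-year marker-discovery study
#'
#' Generates the full structure the discovery pipeline consumes: six
#' datasets (two breeding sites x three years), where first-year colonies
#' come from several source populations, and second- and third-year
#' colonies are F1 generations bred by partial diallel crosses from the
#' previous year's colonies at the same site. Every dataset gets its own
#' optimized triplex block design and quantification matrix; protein
#' expression shares one ground truth (markers, heritability, variance
#' components), and colony additive-genetic values are transmitted through
#' the pedigree so parent and offspring datasets carry heritable signal.
#'
#' @param n_colonies colonies per dataset.
#' @param n_proteins simulated proteins.
#' @param n_markers planted markers.
#' @param beta standardized marker effect size.
#' @param h2 narrow-sense heritability of colony-level expression.
#' @param missing_rate target fraction of missing (protein, block) triples.
#' @param h2_behavior heritability of the behavior itself (F1 propensity).
#' @param populations_y1 named list with per-site character vectors of
#'   first-year source populations.
#' @param design_restarts restarts of the block-design search per dataset.
#' @param seed integer master seed.
#' @param truth optional pre-built [ground_truth()] (overrides the
#'   marker/variance arguments).
#' @return List (`hb_study`): `datasets` (named list; each has `colonies`,
#'   `assignment`, `quant`), `pedigree` (all colonies, all datasets),
#'   `truth`, `genetic_values`.
#' @export
simulate_study <- function(n_colonies = 36L,
                           n_proteins = 500L,
                           n_markers = 5L,
                           beta = 0.6,
                           h2 = 0.3,
                           missing_rate = 0.25,
                           h2_behavior = 0.6,
                           populations_y1 = list(
                             BL = c("ON", "CA1", "CA2", "Ch", "SK"),
                             GF = c("LOCAL", "MN", "VSH", "CDN")),
                           design_restarts = 2L,
                           seed = 1L,
                           truth = NULL) {
  sites <- names(populations_y1)
  stopifnot(length(sites) == 2, n_colonies >= 9)
  all_pops <- unique(c(unlist(populations_y1), "HIGH", "LOW", "HYB"))
  seeds <- split_seeds(seed, 40L)
  si <- 0L
  nxt <- function() {
    si <<- si + 1L
    seeds[si]
  }
  if (is.null(truth)) {
    truth <- ground_truth(n_proteins, all_pops, n_markers = n_markers,
                          beta = beta, h2 = h2,
                          missing_model = list(rate = missing_rate,
                                               mcar = min(0.05, missing_rate),
                                               abundance_weight = 1),
                          seed = nxt())
  } else {
    nxt()
  }

  colonies <- list()
  for (s in sites) {
    pops <- populations_y1[[s]]
    y1 <- simulate_colonies(ceiling(n_colonies / length(pops)), pops,
                            site = s, year = "Y1", seed = nxt())
    y1 <- y1[seq_len(n_colonies), ]
    cr2 <- make_diallel_crosses(y1, n_colonies, seed = nxt())
    y2 <- simulate_diallel(y1, cr2, h2_behavior = h2_behavior,
                           site = s, year = "Y2", seed = nxt())
    cr3 <- make_diallel_crosses(y2, n_colonies, seed = nxt())
    y3 <- simulate_diallel(y2, cr3, h2_behavior = h2_behavior,
                           site = s, year = "Y3", seed = nxt())
    colonies[[paste0(s, "-Y1")]] <- y1
    colonies[[paste0(s, "-Y2")]] <- y2
    colonies[[paste0(s, "-Y3")]] <- y3
  }
  pedigree <- do.call(rbind, c(colonies, make.row.names = FALSE))
  gv <- simulate_genetic_values(
    pedigree[, c("colony_id", "dam_id", "sire_id")], truth, seed = nxt())

  datasets <- lapply(names(colonies), function(nm) {
    cols <- colonies[[nm]]
    asg <- build_design(cols, hb_variable = "r24",
                        n_restarts = design_restarts, seed = nxt())
    qm <- simulate_quant(cols, asg, truth, seed = nxt(),
                         genetic_values = gv)
    list(colonies = cols, assignment = asg, quant = qm)
  })
  names(datasets) <- names(colonies)
  structure(list(datasets = datasets, pedigree = pedigree, truth = truth,
                 genetic_values = gv, seed = seed),
            class = "hb_study")
}

#' @export
print.hb_study <- function(x, ...) {
  cat("hb_study:", length(x$datasets), "datasets (",
      paste(names(x$datasets), collapse = ", "), ")\n")
  cat("  ", nrow(x$pedigree), "colonies;", length(x$truth$proteins),
      "proteins;", length(x$truth$marker_ids), "planted markers\n")
  invisible(x)
}

#' Run the full marker-discovery analysis on a simulated study
#'
#' For each dataset: detection-filter and normalize the quantification
#' matrix and fit the per-protein association with the HB predictor
#' (adjusting for population in the multi-population reference dataset).
#' Then: fit all four field parameters in the two first-year datasets (the
#' two-site route), estimate per-protein heritability from the pedigree
#' (offspring on dam/sire expression across dataset generations), rank
#' proteins by the overall HB correlation score, and apply the selection
#' rules.
#'
#' @param study an `hb_study` from [simulate_study()].
#' @param predictor HB field variable for the per-dataset association.
#' @param reference name of the reference dataset (route a; population-
#'   adjusted).
#' @param field_parameters predictors for the two-site route.
#' @param min_block_fraction detection filter threshold.
#' @param rules selection-rule thresholds, see [select_markers()].
#' @param engine association engine, see [fit_protein_model()].
#' @return List (`hb_analysis`): `assoc` (per dataset), `two_site`,
#'   `herit_fits`, `scores`, `selection`, `normalized` (per dataset).
#' @export
analyze_study <- function(study,
                          predictor = "r24",
                          reference = "BL-Y1",
                          field_parameters = c("r24", "r48", "u24", "u48"),
                          min_block_fraction = 0.25,
                          rules = list(),
                          engine = "auto") {
  stopifnot(inherits(study, "hb_study"))
  norm <- lapply(study$datasets, function(ds)
    normalize_quant(detection_filter(ds$quant, min_block_fraction)))
  assoc <- lapply(names(study$datasets), function(nm) {
    ds <- study$datasets[[nm]]
    run_dataset(norm[[nm]], ds$assignment, ds$colonies,
                predictors = predictor,
                adjust_population = (nm == reference),
                engine = engine,
                min_block_fraction = min_block_fraction)
  })
  names(assoc) <- names(study$datasets)

  y1 <- grep("-Y1$", names(study$datasets), value = TRUE)
  two_site <- lapply(y1, function(nm) {
    ds <- study$datasets[[nm]]
    run_dataset(norm[[nm]], ds$assignment, ds$colonies,
                predictors = field_parameters,
                adjust_population = (nm == reference),
                engine = engine,
                min_block_fraction = min_block_fraction)
  })
  names(two_site) <- y1

  expr <- do.call(rbind, lapply(names(study$datasets), function(nm)
    colony_expression(norm[[nm]], study$datasets[[nm]]$assignment)))
  herit <- fit_heritability(expr, study$pedigree)

  scores <- rank_markers(assoc, herit_fits = herit)
  selection <- select_markers(scores,
                              reference_results = assoc[[reference]],
                              two_site_results = two_site,
                              rules = rules)
  structure(list(assoc = assoc, two_site = two_site, herit_fits = herit,
                 scores = scores, selection = selection, normalized = norm),
            class = "hb_analysis")
}

#' @export
print.hb_analysis <- function(x, ...) {
  sel <- x$selection[x$selection$selected, ]
  cat("hb_analysis:", length(x$assoc), "datasets;",
      nrow(x$scores), "proteins scored;", nrow(sel), "selected\n")
  if (nrow(sel)) {
    cat("top selections:\n")
    print(head(sel[, c("protein_id", "correlation_score", "rules_hit")], 10))
  }
  invisible(x)
}
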
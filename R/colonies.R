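#' Simulate founder colonies with hygienic-behavior phenotypes
#'
#' Generates colony records for one or more source populations. Each colony
#' receives a latent hygienic propensity `hb_true` drawn from the chosen
#' distribution, and observed freeze-killed-brood phenotypes (proportion of
#' killed cells uncapped, U, and removed, R, at 24 h and 48 h) from two
#' field tests performed a week apart, averaged.
#'
#' Each test perturbs the colony's propensity on the logit scale
#' (independent test-retest noise of SD `test_sd`), then draws cell counts
#' sequentially so the assay's logical ordering holds by construction:
#' removed cells are a subset of uncapped cells (`u24 >= r24`,
#' `u48 >= r48`) and counts are non-decreasing from 24 h to 48 h
#' (`r48 >= r24`, `u48 >= u24`).
#'
#' @param n_per_population colonies per population (>= 1, or 0 for an empty
#'   frame).
#' @param populations character vector of population labels.
#' @param hb_dist distribution of `hb_true`: `list(type = "beta", shape1,
#'   shape2)`, `list(type = "fixed", value)`, or `list(type = "uniform",
#'   min, max)`. Default is a wide Beta(1.5, 1.5) spanning \[0, 1\].
#' @param n_cells_per_test sealed cells scored per field test.
#' @param test_sd SD of the logit-scale test-retest perturbation
#'   (0 disables test noise).
#' @param extra_uncap_rate probability that an unremoved cell is
#'   nevertheless uncapped by 24 h, scaled by the colony's propensity.
#' @param progress_rate probability that a pending cell progresses
#'   (to removed/uncapped) between 24 h and 48 h, scaled by propensity.
#' @param site,year categorical annotations stamped on every record.
#' @param seed integer seed.
#' @return A `data.frame` of colony records with columns `colony_id`,
#'   `site`, `year`, `population`, `hb_true`, `r24`, `r48`, `u24`, `u48`,
#'   `dam_id`, `sire_id` (NA for founders).
#' @export
#' @examples
#' head(simulate_colonies(5, c("ON", "SK", "CA1"), seed = 1))
simulate_colonies <- function(n_per_population,
                              populations,
                              hb_dist = list(type = "beta", shape1 = 1.5, shape2 = 1.5),
                              n_cells_per_test = 100,
                              test_sd = 0.3,
                              extra_uncap_rate = 0.3,
                              progress_rate = 0.5,
                              site = "S1",
                              year = "Y1",
                              seed = 1L) {
  stopifnot(length(populations) >= 1, n_per_population >= 0,
            n_cells_per_test >= 1, test_sd >= 0)
  n <- n_per_population * length(populations)
  if (n == 0L) return(empty_colony_frame())
  with_seed(seed, {
    pop <- rep(populations, each = n_per_population)
    hb <- draw_hb(n, hb_dist)
    ids <- sprintf("%s-%s-C%03d", site, year, seq_len(n))
    ph <- phenotype_colonies(hb, n_cells_per_test, test_sd,
                             extra_uncap_rate, progress_rate)
    data.frame(colony_id = ids, site = site, year = year, population = pop,
               hb_true = hb, ph,
               dam_id = NA_character_, sire_id = NA_character_,
               stringsAsFactors = FALSE)
  })
}

empty_colony_frame <- function() {
  data.frame(colony_id = character(), site = character(), year = character(),
             population = character(), hb_true = numeric(),
             r24 = numeric(), r48 = numeric(), u24 = numeric(), u48 = numeric(),
             dam_id = character(), sire_id = character(),
             stringsAsFactors = FALSE)
}

draw_hb <- function(n, hb_dist) {
  type <- hb_dist$type %||% "beta"
  hb <- switch(type,
    beta = {
      s1 <- hb_dist$shape1; s2 <- hb_dist$shape2
      if (is.null(s1) || is.null(s2) || s1 <= 0 || s2 <= 0) {
        stop("beta hb_dist requires positive shape1 and shape2", call. = FALSE)
      }
      rbeta(n, s1, s2)
    },
    fixed = {
      v <- hb_dist$value
      if (is.null(v) || v < 0 || v > 1) {
        stop("fixed hb_dist requires a value in [0, 1]", call. = FALSE)
      }
      rep(v, n)
    },
    uniform = {
      lo <- hb_dist$min %||% 0; hi <- hb_dist$max %||% 1
      if (lo < 0 || hi > 1 || lo >= hi) {
        stop("uniform hb_dist requires 0 <= min < max <= 1", call. = FALSE)
      }
      runif(n, lo, hi)
    },
    stop("unknown hb_dist type: ", type, call. = FALSE)
  )
  hb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two freeze-killed-brood tests a week apart, averaged. Count construction
# guarantees u >= r at each time and monotonicity in time.
phenotype_colonies <- function(hb, n_cells, test_sd, extra_uncap_rate,
                               progress_rate) {
  n <- length(hb)
  acc <- matrix(0, n, 4, dimnames = list(NULL, c("r24", "r48", "u24", "u48")))
  for (test in 1:2) {
    p <- plogis(qlogis(hb) + if (test_sd > 0) rnorm(n, 0, test_sd) else 0)
    p[hb == 0] <- 0; p[hb == 1] <- 1   # degenerate propensities stay exact
    r24 <- rbinom(n, n_cells, p)
    u24 <- r24 + rbinom(n, n_cells - r24, extra_uncap_rate * p)
    r48 <- r24 + rbinom(n, u24 - r24, progress_rate * p)
    u48p <- pmax(u24, r48)
    u48 <- u48p + rbinom(n, n_cells - u48p, progress_rate * p)
    acc <- acc + cbind(r24, r48, u24, u48) / n_cells
  }
  as.data.frame(acc / 2)
}

#' Simulate an F1 generation from a partial diallel cross
#'
#' Crosses dam and sire colonies per a cross table. Offspring latent
#' hygienic propensity regresses toward the parental mean with heritability
#' `h2_behavior`: `hb_F1 = mu + h2 * (midparent - mu) + e`, where `mu` is
#' the mean propensity of the parent pool and `e` is segregation noise of
#' SD `segregation_sd`, truncated to \[0, 1\]. Observed phenotypes are
#' produced by the same two-test freeze-killed-brood machinery as
#' [simulate_colonies()].
#'
#' @param parents colony frame containing every referenced dam and sire.
#' @param crosses `data.frame` with columns `dam_id` and `sire_id` (one row
#'   per F1 colony).
#' @param h2_behavior narrow-sense heritability of the behavior in \[0, 1\].
#' @param segregation_sd SD of segregation noise on the propensity scale.
#' @param n_cells_per_test,test_sd,extra_uncap_rate,progress_rate as in
#'   [simulate_colonies()].
#' @param site,year annotations for the F1 records.
#' @param seed integer seed.
#' @return Colony frame of F1 records with `dam_id`/`sire_id` filled in.
#' @export
#' @examples
#' p <- simulate_colonies(4, c("A", "B", "C"), seed = 1)
#' cr <- data.frame(dam_id = p$colony_id[1:3], sire_id = p$colony_id[10:12])
#' simulate_diallel(p, cr, h2_behavior = 0.8, seed = 2)
simulate_diallel <- function(parents, crosses,
                             h2_behavior = 0.6,
                             segregation_sd = 0.05,
                             n_cells_per_test = 100,
                             test_sd = 0.3,
                             extra_uncap_rate = 0.3,
                             progress_rate = 0.5,
                             site = unique(parents$site)[1],
                             year = "Y3",
                             seed = 1L) {
  stopifnot(is.data.frame(crosses), all(c("dam_id", "sire_id") %in% names(crosses)),
            h2_behavior >= 0, h2_behavior <= 1, segregation_sd >= 0)
  missing_ref <- setdiff(c(crosses$dam_id, crosses$sire_id), parents$colony_id)
  if (length(missing_ref)) {
    stop("pedigree error: cross table references unknown parent(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  n <- nrow(crosses)
  if (n == 0L) return(empty_colony_frame())
  with_seed(seed, {
    hb_parent <- setNames(parents$hb_true, parents$colony_id)
    mid <- (hb_parent[crosses$dam_id] + hb_parent[crosses$sire_id]) / 2
    mu <- mean(hb_parent)
    noise <- if (segregation_sd > 0) rnorm(n, 0, segregation_sd) else 0
    hb <- pmin(1, pmax(0, mu + h2_behavior * (mid - mu) + noise))
    ids <- sprintf("%s-%s-F%03d", site, year, seq_len(n))
    ph <- phenotype_colonies(hb, n_cells_per_test, test_sd,
                             extra_uncap_rate, progress_rate)
    data.frame(colony_id = ids, site = site, year = year,
               population = cross_group(hb_parent, crosses,
                                        median(hb_parent)),
               hb_true = unname(hb), ph,
               dam_id = crosses$dam_id, sire_id = crosses$sire_id,
               stringsAsFactors = FALSE)
  })
}

# Breeding-group label for F1 colonies: high x high, low x low, or hybrid,
# judged against the parental median (so pools split at the median map to
# groups consistently). Serves as the "population" category for the
# block-design constraint in later generations.
cross_group <- function(hb_parent, crosses, mu) {
  dam_high <- hb_parent[crosses$dam_id] >= mu
  sire_high <- hb_parent[crosses$sire_id] >= mu
  ifelse(dam_high & sire_high, "HIGH",
         ifelse(!dam_high & !sire_high, "LOW", "HYB"))
}

#' Build a partial-diallel cross table from a parent pool
#'
#' Splits the parents at their median latent propensity into high and low
#' pools and draws crosses in fixed proportions: one third high x high,
#' one third low x low, the rest high x low (hybrids). Parents may be
#' reused (each cross takes a distinct dam and sire), emulating an
#' incomplete diallel grid; group sizes are balanced so downstream block
#' designs (which forbid same-group pairs in a block) stay feasible.
#'
#' @param parents colony frame of candidate parents.
#' @param n_crosses number of F1 colonies to plan.
#' @param seed integer seed.
#' @return `data.frame` with `dam_id`, `sire_id`.
#' @export
make_diallel_crosses <- function(parents, n_crosses, seed = 1L) {
  stopifnot(nrow(parents) >= 4, n_crosses >= 3)
  with_seed(seed, {
    med <- median(parents$hb_true)
    hi <- parents$colony_id[parents$hb_true >= med]
    lo <- parents$colony_id[parents$hb_true < med]
    if (length(hi) < 2 || length(lo) < 2) {
      stop("parent pool cannot be split at the median", call. = FALSE)
    }
    n_hh <- floor(n_crosses / 3); n_ll <- floor(n_crosses / 3)
    n_hy <- n_crosses - n_hh - n_ll
    pick2 <- function(pool) sample(pool, 2)
    hh <- t(replicate(n_hh, pick2(hi)))
    ll <- t(replicate(n_ll, pick2(lo)))
    hy <- cbind(sample(hi, n_hy, replace = TRUE),
                sample(lo, n_hy, replace = TRUE))
    m <- rbind(hh, ll, hy)
    data.frame(dam_id = m[, 1], sire_id = m[, 2], stringsAsFactors = FALSE)
  })
}
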
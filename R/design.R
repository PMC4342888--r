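#' Randomized incomplete block design for triplex labeling
#'
#' Assigns three replicate samples per colony to blocks of three, each block
#' carrying one light, one medium and one heavy isotopic label, under the
#' study constraints: no block holds two samples from the same colony, no
#' block holds two colonies from the same population, and each colony uses
#' each label exactly once across its three replicates. Among
#' constraint-satisfying designs, the optimizer minimizes the sampling
#' variance of the block-and-label-adjusted hygienic-behavior effect
#' estimator, `1 / SSX` where `SSX` is the block-centered sum of squares of
#' the HB covariate over all sample slots (equivalently, it maximizes the
#' within-block HB spread; see [design_information()]).
#'
#' Internally a design is three permutations mapping colonies to blocks (one
#' per label); the search is random feasible initialization followed by
#' pairwise slot-swap hill climbing, repeated over `n_restarts` restarts,
#' keeping the best objective. Since `SSX = sum(x^2) - (1/3) * sum(S_b^2)`
#' with `S_b` the block sums of the covariate, swaps are evaluated in O(1).
#'
#' @param colonies colony frame (as from [simulate_colonies()]).
#' @param hb_variable phenotype column used as the design covariate.
#' @param n_restarts random restarts of the local search.
#' @param seed integer seed.
#' @param objective `"estimator_variance"` (default; minimize `1/SSX`) or
#'   `"within_block_variance"` (literal alternative: minimize the summed
#'   within-block variance of the covariate).
#' @param local_search if `FALSE`, return the best random feasible
#'   initialization without hill climbing (used e.g. as a random-design
#'   baseline).
#' @param relax_population allow fewer than 3 populations (drops the
#'   distinct-population constraint); intended for toy instances only.
#' @return A `block_assignment`: list with `blocks` (data.frame `block_id`,
#'   `slot`, `colony_id`, `replicate`, `label`), `objective_value`,
#'   `objective`, `hb_variable`, `seed`.
#' @export
#' @examples
#' cols <- simulate_colonies(3, c("A", "B", "C"), seed = 1)
#' d <- build_design(cols, n_restarts = 5, seed = 2)
#' d$objective_value
build_design <- function(colonies, hb_variable = "r24", n_restarts = 3L,
                         seed = 1L, objective = c("estimator_variance",
                                                  "within_block_variance"),
                         local_search = TRUE, relax_population = FALSE) {
  objective <- match.arg(objective)
  n <- nrow(colonies)
  if (n < 3) stop("infeasible: need at least 3 colonies", call. = FALSE)
  pop <- as.integer(factor(colonies$population))
  if (!relax_population && length(unique(pop)) < 3) {
    stop("infeasible: fewer than 3 populations (constraint: no two ",
         "same-population colonies per block); set relax_population = TRUE ",
         "to drop the population constraint", call. = FALSE)
  }
  tab <- table(pop)
  if (!relax_population && max(tab) > n / 3) {
    stop("infeasible: population '",
         levels(factor(colonies$population))[which.max(tab)],
         "' holds more than one third of colonies (", max(tab), " of ", n,
         "): its samples cannot avoid sharing blocks", call. = FALSE)
  }
  x <- colonies[[hb_variable]]
  if (is.null(x) || !is.numeric(x)) {
    stop("hb_variable '", hb_variable, "' is not a numeric colony column",
         call. = FALSE)
  }
  if (relax_population) pop <- seq_len(n)  # all-distinct: constraint vacuous

  seeds <- split_seeds(seed, max(1L, n_restarts))
  best <- NULL
  for (s in seeds) {
    cand <- with_seed(s, {
      perms <- random_feasible_perms(pop)
      if (local_search) perms <- swap_descent(perms, x, pop, objective)
      perms
    })
    val <- perms_objective(cand, x, objective)
    sig <- perms_signature(cand, colonies$colony_id)
    if (is.null(best) || val < best$val - 1e-12 ||
        (abs(val - best$val) <= 1e-12 && sig < best$sig)) {
      best <- list(perms = cand, val = val, sig = sig)
    }
  }
  assignment_from_perms(best$perms, colonies, hb_variable, best$val,
                        objective, seed)
}

LABELS <- c("light", "medium", "heavy")

# A design as three block->colony maps (columns light/medium/heavy).
# Feasible iff every row (block) has 3 distinct colonies and populations.
random_feasible_perms <- function(pop, max_tries = 200L) {
  n <- length(pop)
  for (try in seq_len(max_tries)) {
    m <- cbind(sample.int(n), sample.int(n), sample.int(n))
    m <- repair_perms(m, pop)
    if (!is.null(m)) return(m)
  }
  stop("could not construct a feasible design by randomized repair; ",
       "instance may be near-infeasible", call. = FALSE)
}

# Resolve block conflicts by swapping slot values between blocks.
repair_perms <- function(m, pop, max_passes = 500L) {
  n <- nrow(m)
  for (pass in seq_len(max_passes)) {
    bad <- which(block_conflict(m, pop))
    if (!length(bad)) return(m)
    for (b in bad) {
      col <- sample(2:3, 1L)            # keep light fixed; perturb M/H
      b2 <- sample.int(n, 1L)
      m2 <- m
      m2[c(b, b2), col] <- m2[c(b2, b), col]
      if (sum(block_conflict(m2[c(b, b2), , drop = FALSE],
                             pop)) <= sum(block_conflict(m[c(b, b2), , drop = FALSE], pop))) {
        m <- m2
      }
    }
  }
  NULL
}

block_conflict <- function(m, pop) {
  dup_col <- (m[, 1] == m[, 2]) | (m[, 1] == m[, 3]) | (m[, 2] == m[, 3])
  p1 <- pop[m[, 1]]; p2 <- pop[m[, 2]]; p3 <- pop[m[, 3]]
  dup_pop <- (p1 == p2) | (p1 == p3) | (p2 == p3)
  dup_col | dup_pop
}

# Objective evaluation. Every colony appears once per column, so the
# block-centered SSX over all slots is 3*sum(x^2) - sum(S_b^2)/3 where S_b
# is the block sum of the covariate.
perms_objective <- function(m, x, objective) {
  S <- x[m[, 1]] + x[m[, 2]] + x[m[, 3]]
  ssx <- 3 * sum(x^2) - sum(S^2) / 3
  if (objective == "estimator_variance") {
    if (ssx <= 1e-12) return(Inf)
    1 / ssx
  } else {
    ssx / (3 * nrow(m))  # mean within-block variance (divisor 3)
  }
}

# Greedy hill climbing over slot swaps: for each label column, swapping the
# colonies of two blocks changes only those two block sums.
swap_descent <- function(m, x, pop, objective, max_sweeps = 100L) {
  n <- nrow(m)
  minimize_ssq <- objective == "estimator_variance"
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    S <- x[m[, 1]] + x[m[, 2]] + x[m[, 3]]
    for (col in 1:3) {
      ord <- sample.int(n)
      for (i in seq_len(n - 1)) {
        b1 <- ord[i]
        xi <- x[m[b1, col]]
        for (j in (i + 1):n) {
          b2 <- ord[j]
          xj <- x[m[b2, col]]
          if (xi == xj) next
          d1 <- S[b1] - xi + xj; d2 <- S[b2] - xj + xi
          # change in sum(S_b^2) from the swap; SSX moves opposite to it
          delta_ssq <- (d1^2 + d2^2) - (S[b1]^2 + S[b2]^2)
          better <- if (minimize_ssq) delta_ssq < -1e-12 else delta_ssq > 1e-12
          if (!better) next
          # feasibility of the swap in both touched blocks
          m2r <- m[c(b1, b2), , drop = FALSE]
          m2r[1, col] <- m[b2, col]; m2r[2, col] <- m[b1, col]
          if (any(block_conflict(m2r, pop))) next
          tmp <- m[b1, col]; m[b1, col] <- m[b2, col]; m[b2, col] <- tmp
          S[b1] <- d1; S[b2] <- d2
          xi <- x[m[b1, col]]
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  m
}

# Deterministic tie-break signature: blocks canonicalized and sorted.
perms_signature <- function(m, ids) {
  rows <- apply(m, 1, function(r) paste(sort(ids[r]), collapse = "|"))
  paste(sort(rows), collapse = ";")
}

assignment_from_perms <- function(m, colonies, hb_variable, val, objective,
                                  seed) {
  n <- nrow(m)
  ids <- colonies$colony_id
  # canonical block order for determinism
  ord <- order(apply(m, 1, function(r) paste(sort(ids[r]), collapse = "|")))
  m <- m[ord, , drop = FALSE]
  # Latin-square label rotation: replicate r of colony i carries label
  # (i + r) mod 3, so replicate indices are balanced over labels.
  rep_of <- function(ci, lab_idx) ((lab_idx - 1L - (ci - 1L)) %% 3L) + 1L
  blocks <- data.frame(
    block_id = rep(sprintf("B%03d", seq_len(n)), each = 3),
    slot = rep(1:3, n),
    colony_id = ids[as.vector(t(m))],
    replicate = as.vector(vapply(seq_len(n), function(b)
      rep_of(m[b, ], 1:3), integer(3))),
    label = rep(LABELS, n),
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, objective_value = val,
                 objective = objective, hb_variable = hb_variable,
                 seed = seed),
            class = "block_assignment")
}

#' @export
print.block_assignment <- function(x, ...) {
  nb <- length(unique(x$blocks$block_id))
  cat("Triplex block assignment:", nb, "blocks,",
      length(unique(x$blocks$colony_id)), "colonies\n")
  cat("  objective (", x$objective, ", on '", x$hb_variable, "'): ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Validate a block assignment against the design constraints
#'
#' Report-only check of every structural invariant: three slots with three
#' distinct labels per block, no duplicated colony within a block, no
#' duplicated population within a block, each colony in exactly three blocks
#' with each label and each replicate exactly once.
#'
#' @param assignment a `block_assignment` (or its `blocks` data.frame).
#' @param colonies colony frame supplying the population of each colony.
#' @return List with `ok` (all checks passed) and `checks`, a data.frame of
#'   per-constraint pass/fail with offending block/colony ids.
#' @export
validate_design <- function(assignment, colonies) {
  b <- if (inherits(assignment, "block_assignment")) assignment$blocks else assignment
  pop <- setNames(colonies$population, colonies$colony_id)
  by_block <- split(b, b$block_id)
  bad_size <- names(by_block)[vapply(by_block, nrow, 0L) != 3L]
  bad_label <- names(by_block)[vapply(by_block, function(d)
    length(unique(d$label)) != 3L, TRUE)]
  bad_col <- names(by_block)[vapply(by_block, function(d)
    anyDuplicated(d$colony_id) > 0L, TRUE)]
  bad_pop <- names(by_block)[vapply(by_block, function(d)
    anyDuplicated(pop[d$colony_id]) > 0L, TRUE)]
  by_col <- split(b, b$colony_id)
  bad_reps <- names(by_col)[vapply(by_col, function(d)
    nrow(d) != 3L || anyDuplicated(d$label) > 0L ||
      anyDuplicated(d$replicate) > 0L ||
      anyDuplicated(d$block_id) > 0L, TRUE)]
  unknown <- setdiff(b$colony_id, colonies$colony_id)
  checks <- data.frame(
    check = c("block_size_3", "distinct_labels", "distinct_colonies",
              "distinct_populations", "colony_replicates_balanced",
              "colonies_known"),
    pass = c(!length(bad_size), !length(bad_label), !length(bad_col),
             !length(bad_pop), !length(bad_reps), !length(unknown)),
    offenders = c(paste(bad_size, collapse = ","),
                  paste(bad_label, collapse = ","),
                  paste(bad_col, collapse = ","),
                  paste(bad_pop, collapse = ","),
                  paste(bad_reps, collapse = ","),
                  paste(unknown, collapse = ",")),
    stringsAsFactors = FALSE
  )
  list(ok = all(checks$pass), checks = checks)
}

#' Design information criterion for the HB effect
#'
#' Sampling variance (up to the residual variance) of the hygienic-behavior
#' effect estimator under the block-and-label-adjusted linear model:
#' `1 / SSX`, where `SSX` is the block-centered sum of squares of the HB
#' covariate over all sample slots. Lower is better. If the covariate has no
#' within-block variation anywhere, the effect is inestimable and `Inf` is
#' returned with a warning.
#'
#' @param assignment a `block_assignment`.
#' @param colonies colony frame.
#' @param hb_variable phenotype column to evaluate.
#' @return Scalar criterion value.
#' @export
design_information <- function(assignment, colonies,
                               hb_variable = assignment$hb_variable) {
  b <- assignment$blocks
  x <- setNames(colonies[[hb_variable]], colonies$colony_id)[b$colony_id]
  xc <- x - ave(x, b$block_id)
  ssx <- sum(xc^2)
  if (ssx <= 1e-12) {
    warning("no within-block variation in '", hb_variable,
            "': HB effect inestimable (criterion = Inf)")
    return(Inf)
  }
  1 / ssx
}
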
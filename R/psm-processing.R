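#' Filter PSMs at a target-decoy false discovery rate
#'
#' Within each block (MS run), finds the smallest score threshold `t` such
#' that `#decoys >= t` divided by `#targets >= t` is at most `fdr` — the
#' plain decoy/target count ratio, with no +1 correction. Target PSMs at or
#' above the threshold are accepted; independently, PSMs scoring below
#' `min_score` are dropped from quantification (the ions-score gate). If no
#' threshold attains the FDR in a block, that block's accepted set is empty
#' and a warning is raised.
#'
#' @param psms PSM `data.frame` (as from [simulate_psms()]) with at least
#'   `score`, `decoy`, and optionally `block` (absent = one block).
#' @param fdr nominal within-block FDR, in (0, 1).
#' @param min_score quantification score gate (ions score >= 25 by
#'   default).
#' @return List with `psms` (accepted target PSMs) and `thresholds`
#'   (data.frame `block`, `threshold`, `n_accepted`, `n_decoy_at_t`,
#'   `fdp_estimate`). The reported threshold is `max(t, min_score)`.
#' @export
decoy_fdr_filter <- function(psms, fdr = 0.01, min_score = 25) {
  stopifnot(is.data.frame(psms), nrow(psms) > 0, fdr > 0, fdr < 1,
            all(c("score", "decoy") %in% names(psms)))
  if (!all(is.finite(psms$score))) stop("non-finite PSM scores", call. = FALSE)
  if (is.null(psms$block)) psms$block <- "B001"
  res <- lapply(split(psms, psms$block), function(d) {
    t_star <- fdr_threshold(d$score, d$decoy, fdr)
    if (is.na(t_star)) {
      warning("no score threshold attains FDR <= ", fdr, " in block ",
              d$block[1], "; accepting nothing", call. = FALSE)
      return(list(acc = d[0, ], thr = data.frame(
        block = d$block[1], threshold = NA_real_, n_accepted = 0L,
        n_decoy_at_t = NA_integer_, fdp_estimate = NA_real_)))
    }
    thr <- max(t_star, min_score)
    acc <- d[!d$decoy & d$score >= thr, , drop = FALSE]
    nd <- sum(d$decoy & d$score >= thr)
    nt <- nrow(acc)
    list(acc = acc, thr = data.frame(
      block = d$block[1], threshold = thr, n_accepted = nt,
      n_decoy_at_t = nd,
      fdp_estimate = if (nt > 0) nd / nt else 0))
  })
  accepted <- do.call(rbind, lapply(res, `[[`, "acc"))
  rownames(accepted) <- NULL
  list(psms = accepted,
       thresholds = do.call(rbind, c(lapply(res, `[[`, "thr"),
                                     make.row.names = FALSE)))
}

# Smallest threshold t (a unique observed score) with
# #decoy(score >= t) / #target(score >= t) <= fdr; NA if none qualifies.
fdr_threshold <- function(score, decoy, fdr) {
  ts <- sort(unique(score))
  for (t in ts) {
    nt <- sum(!decoy & score >= t)
    nd <- sum(decoy & score >= t)
    if (nt > 0 && nd / nt <= fdr) return(t)
  }
  NA_real_
}

#' Parsimony protein inference with per-block ratio averaging
#'
#' Minimal set cover over accepted target PSMs (Occam's razor): proteins
#' with identical peptide sets are merged into one group; a minimal set of
#' proteins explaining every accepted peptide is selected; proteins whose
#' peptide sets are subsets of a selected protein's set are absorbed into
#' that group. On instances with at most `exact_limit` distinct candidate
#' peptide sets the cover is solved exactly by branch and bound (greedy
#' cover as the initial bound, candidates explored in lexicographic
#' accession order, so the result is deterministic); larger instances use
#' the greedy cover (repeatedly select the protein explaining the most
#' unexplained peptides, ties broken by lexicographic accession order),
#' which is near-optimal in practice but not guaranteed minimal.
#'
#' For every group and block the label-pair ratios medium/light,
#' heavy/light and heavy/medium are the arithmetic means of the peptide
#' log-ratios.
#'
#' @param accepted_psms accepted target PSM `data.frame` (e.g. the `psms`
#'   element of [decoy_fdr_filter()]) with `peptide_id`, `protein_ids`
#'   (`;`-separated), `block`, and `intensity_light/medium/heavy`.
#' @param exact_limit largest candidate count solved exactly (set to 0 to
#'   force the greedy cover).
#' @return List with `groups` (data.frame `group_id`, `lead_protein`,
#'   `proteins` (`;`-joined members), `n_peptides`) and `ratios`
#'   (data.frame `group_id`, `block`, `log_ratio_ml`, `log_ratio_hl`,
#'   `log_ratio_hm`, `n_peptides`).
#' @export
parsimony_group <- function(accepted_psms, exact_limit = 25L) {
  stopifnot(is.data.frame(accepted_psms))
  if (nrow(accepted_psms) == 0) {
    return(list(groups = data.frame(group_id = character(),
                                    lead_protein = character(),
                                    proteins = character(),
                                    n_peptides = integer()),
                ratios = data.frame(group_id = character(),
                                    block = character(),
                                    log_ratio_ml = numeric(),
                                    log_ratio_hl = numeric(),
                                    log_ratio_hm = numeric(),
                                    n_peptides = integer())))
  }
  d <- accepted_psms
  if (is.null(d$block)) d$block <- "B001"
  prot_lists <- strsplit(d$protein_ids, ";", fixed = TRUE)
  pairs <- data.frame(peptide = rep(d$peptide_id, lengths(prot_lists)),
                      protein = unlist(prot_lists),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pep_sets <- lapply(split(pairs$peptide, pairs$protein), function(p)
    sort(unique(p)))

  # merge identical peptide sets
  sig <- vapply(pep_sets, paste, "", collapse = "\r")
  merged <- split(names(pep_sets), sig)
  cand <- lapply(merged, function(members) {
    members <- sort(members)
    list(lead = members[1], members = members,
         peps = pep_sets[[members[1]]])
  })
  names(cand) <- vapply(cand, `[[`, "", "lead")
  cand <- cand[order(names(cand))]

  universe <- sort(unique(pairs$peptide))
  sets <- lapply(cand, `[[`, "peps")
  sel_names <- if (length(cand) <= exact_limit) {
    exact_cover(sets, universe)
  } else {
    greedy_cover(sets, universe)
  }
  selected <- cand[sel_names]
  cand[sel_names] <- NULL
  selected <- selected[order(names(selected))]
  # absorb unselected proteins whose sets are subsets of a selected set
  for (nm in names(cand)) {
    for (snm in names(selected)) {
      if (all(cand[[nm]]$peps %in% selected[[snm]]$peps)) {
        selected[[snm]]$members <- sort(c(selected[[snm]]$members,
                                          cand[[nm]]$members))
        break
      }
    }
  }
  selected <- selected[order(names(selected))]
  groups <- data.frame(
    group_id = names(selected),
    lead_protein = vapply(selected, `[[`, "", "lead"),
    proteins = vapply(selected, function(s) paste(s$members, collapse = ";"), ""),
    n_peptides = vapply(selected, function(s) length(s$peps), 0L),
    stringsAsFactors = FALSE, row.names = NULL)

  # per (group, block) mean peptide log-ratios; shared peptides contribute
  # to every group containing them
  pep2group <- do.call(rbind, lapply(names(selected), function(g)
    data.frame(peptide_id = selected[[g]]$peps, group_id = g,
               stringsAsFactors = FALSE)))
  dd <- merge(d, pep2group, by = "peptide_id")
  if (!all(c("intensity_light", "intensity_medium", "intensity_heavy") %in%
           names(dd))) {
    return(list(groups = groups, ratios = NULL))
  }
  dd$log_ratio_ml <- log(dd$intensity_medium / dd$intensity_light)
  dd$log_ratio_hl <- log(dd$intensity_heavy / dd$intensity_light)
  dd$log_ratio_hm <- log(dd$intensity_heavy / dd$intensity_medium)
  agg <- aggregate(dd[, c("log_ratio_ml", "log_ratio_hl", "log_ratio_hm")],
                   by = list(group_id = dd$group_id, block = dd$block), mean)
  cnt <- aggregate(list(n_peptides = dd$peptide_id),
                   by = list(group_id = dd$group_id, block = dd$block),
                   function(p) length(unique(p)))
  ratios <- merge(agg, cnt, by = c("group_id", "block"))
  ratios <- ratios[order(ratios$group_id, ratios$block), ]
  rownames(ratios) <- NULL
  list(groups = groups, ratios = ratios)
}

# greedy set cover: largest gain first, lexicographic names break ties
greedy_cover <- function(sets, universe) {
  sets <- sets[order(names(sets))]
  uncovered <- universe
  picked <- character()
  while (length(uncovered)) {
    gain <- vapply(sets, function(s) length(intersect(s, uncovered)), 0L)
    best <- names(sets)[which.max(gain)]
    if (gain[[best]] == 0L) break
    picked <- c(picked, best)
    uncovered <- setdiff(uncovered, sets[[best]])
    sets[[best]] <- NULL
  }
  picked
}

# exact minimum set cover by branch and bound: greedy solution as the
# initial upper bound; branch on an uncovered element with the fewest
# covering candidates, candidates in lexicographic order (deterministic)
exact_cover <- function(sets, universe) {
  sets <- sets[order(names(sets))]
  idx <- lapply(sets, function(s) match(s, universe))
  nmv <- names(sets)
  n_u <- length(universe)
  covers_of <- lapply(seq_len(n_u), function(e)
    which(vapply(idx, function(s) e %in% s, TRUE)))
  best <- greedy_cover(sets, universe)
  best_k <- length(best)
  recurse <- function(uncov, chosen) {
    if (!length(uncov)) {
      if (length(chosen) < best_k) {
        best_k <<- length(chosen)
        best <<- nmv[sort(chosen)]
      }
      return(invisible())
    }
    # any completion uses >= 1 more set; prune if that cannot improve
    if (length(chosen) + 1L >= best_k) return(invisible())
    # branch on the uncovered element with the fewest covering candidates
    ncov <- vapply(uncov, function(e)
      length(setdiff(covers_of[[e]], chosen)), 0L)
    e <- uncov[which.min(ncov)]
    for (ci in setdiff(covers_of[[e]], chosen)) {
      recurse(setdiff(uncov, idx[[ci]]), c(chosen, ci))
    }
    invisible()
  }
  recurse(seq_len(n_u), integer())
  best
}
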
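#' Per-dataset hygienic-behavior factor for one protein
#'
#' Combines a statistical factor `s = min(-log10(p), stat_cap)` (p = 0 uses
#' the cap) and a biological factor `b = min(|effect| / pooled_sd,
#' bio_cap)` into `sign_agreement * s * (1 + b) / 2`, where
#' `sign_agreement` is +1 when the effect direction matches the protein's
#' cross-dataset majority direction (`direction_reference`), -1 otherwise
#' (zero effects count as agreeing). On a standardized matrix the pooled
#' response SD is ~1, so `b` is essentially the standardized effect
#' magnitude.
#'
#' @param p_value,effect association statistics for the protein in one
#'   dataset (vectorized).
#' @param direction_reference reference sign (+1/-1) for the protein.
#' @param pooled_sd pooled response SD used to standardize the effect.
#' @param stat_cap cap on `-log10(p)`.
#' @param bio_cap cap on the standardized effect magnitude.
#' @return Signed HB factor (NA when `p_value` or `effect` is NA — the
#'   dataset is then excluded from the protein's average).
#' @export
#' @examples
#' dataset_hb_factor(0.1, 0, 1)  # 0.5
dataset_hb_factor <- function(p_value, effect, direction_reference,
                              pooled_sd = 1, stat_cap = 10, bio_cap = 2) {
  s <- pmin(-log10(pmax(p_value, 10^(-stat_cap))), stat_cap)
  b <- pmin(abs(effect) / pooled_sd, bio_cap)
  agree <- ifelse(sign(effect) * sign(direction_reference) >= 0, 1, -1)
  out <- agree * s * (1 + b) / 2
  out[is.na(p_value) | is.na(effect)] <- NA_real_
  out
}

#' Overall HB correlation score for one protein
#'
#' The mean of the per-dataset HB factors over the datasets where the
#' protein was quantified, plus the heritability factor. Proteins
#' quantified in fewer than `min_datasets` datasets are flagged ineligible
#' for the ranked list (but still scored).
#'
#' @param per_dataset numeric vector of per-dataset HB factors (NA =
#'   not quantified in that dataset).
#' @param heritability heritability factor (>= 0).
#' @param min_datasets minimum datasets for ranking eligibility.
#' @return List with `correlation_score`, `n_datasets_quantified`,
#'   `eligible`.
#' @export
#' @examples
#' overall_score(c(5, 5, 5, 5), heritability = 1)
overall_score <- function(per_dataset, heritability = 0, min_datasets = 4L) {
  nq <- sum(!is.na(per_dataset))
  if (nq == 0) stop("no dataset factors present", call. = FALSE)
  list(correlation_score = mean(per_dataset, na.rm = TRUE) + heritability,
       n_datasets_quantified = nq,
       eligible = nq >= min_datasets)
}

#' Rank proteins by the overall HB correlation score across datasets
#'
#' Assembles the per-dataset HB factors (with the majority effect
#' direction across datasets as each protein's sign reference; ties count
#' as positive), adds the heritability factor from the dam/sire
#' regression, and returns one row per protein with the overall
#' correlation score and eligibility.
#'
#' @param assoc named list of association result data.frames (one per
#'   dataset, single predictor; as from [run_dataset()]).
#' @param herit_fits optional [fit_heritability()] result; proteins absent
#'   from it get heritability factor 0.
#' @param min_datasets minimum datasets quantified for eligibility.
#' @param stat_cap,bio_cap,pooled_sd passed to [dataset_hb_factor()].
#' @param herit_weights,herit_p_breaks passed to [heritability_factor()].
#' @return `data.frame` with `protein_id`, one `factor_<dataset>` column
#'   per dataset, `n_datasets_quantified`, `heritability_factor`,
#'   `correlation_score`, `eligible`; sorted by decreasing score.
#' @export
rank_markers <- function(assoc, herit_fits = NULL, min_datasets = 4L,
                         stat_cap = 10, bio_cap = 2, pooled_sd = 1,
                         herit_weights = c(1, 0.5, 0.25),
                         herit_p_breaks = c(0.05, 0.5)) {
  stopifnot(is.list(assoc), length(assoc) >= 1)
  if (is.null(names(assoc)) || any(!nzchar(names(assoc)))) {
    names(assoc) <- sprintf("dataset%d", seq_along(assoc))
  }
  proteins <- sort(unique(unlist(lapply(assoc, `[[`, "protein_id"))))
  get_mat <- function(col) {
    m <- sapply(assoc, function(a) {
      v <- setNames(a[[col]], a$protein_id)[proteins]
      v[!is.finite(v)] <- NA
      v
    })
    matrix(m, nrow = length(proteins),
           dimnames = list(proteins, names(assoc)))
  }
  eff <- get_mat("effect")
  pv <- get_mat("p_value")
  # majority direction across quantified datasets; ties -> positive
  dir_ref <- apply(eff, 1, function(e) {
    s <- sum(sign(e), na.rm = TRUE)
    if (s >= 0) 1 else -1
  })
  fac <- matrix(NA_real_, length(proteins), length(assoc),
                dimnames = list(proteins, names(assoc)))
  for (j in seq_along(assoc)) {
    fac[, j] <- dataset_hb_factor(pv[, j], eff[, j], dir_ref,
                                  pooled_sd, stat_cap, bio_cap)
  }
  nq <- rowSums(!is.na(fac))
  hf <- setNames(rep(0, length(proteins)), proteins)
  if (!is.null(herit_fits) && nrow(herit_fits)) {
    hv <- heritability_factor(herit_fits, herit_weights, herit_p_breaks)
    hf[intersect(names(hv), proteins)] <-
      hv[intersect(names(hv), proteins)]
  }
  score <- rowMeans(fac, na.rm = TRUE) + hf
  score[nq == 0] <- NA_real_
  out <- data.frame(protein_id = proteins, fac,
                    n_datasets_quantified = nq,
                    heritability_factor = unname(hf),
                    correlation_score = unname(score),
                    eligible = nq >= min_datasets,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1 + seq_along(assoc)] <- paste0("factor_", names(assoc))
  out <- out[order(-out$correlation_score, out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Apply the marker-selection rules
#'
#' Three selection routes, each tagged in the output:
#' \describe{
#'   \item{`reference_q`}{q-value below `rules$q_ref` in the designated
#'     reference dataset (with an additional `reference_strict_p` tag when
#'     p is also below `rules$p_strict`).}
#'   \item{`two_site`}{p below `rules$p_two_site` for *all* field
#'     parameters in *both* first-year datasets (a protein missing any
#'     parameter at either site fails the route).}
#'   \item{`top_rank`}{among eligible proteins, the `rules$top_k` largest
#'     overall correlation scores.}
#' }
#' The selected set is the union of the three routes.
#'
#' @param scores result of [rank_markers()].
#' @param reference_results association results of the reference dataset
#'   (single HB predictor); `NULL` skips the route with a warning.
#' @param two_site_results list of two association result data.frames
#'   (one per site), each covering all field parameters (multiple
#'   predictors stacked, as from [run_dataset()] with several predictors);
#'   `NULL` skips the route.
#' @param rules list of thresholds: `q_ref` (0.1), `p_strict` (5e-4),
#'   `p_two_site` (0.05), `top_k` (10).
#' @return `scores` augmented with logical route columns, `selected`, and
#'   a `rules_hit` string.
#' @export
select_markers <- function(scores, reference_results = NULL,
                           two_site_results = NULL,
                           rules = list()) {
  rules <- utils::modifyList(list(q_ref = 0.1, p_strict = 5e-4,
                                  p_two_site = 0.05, top_k = 10L), rules)
  prot <- scores$protein_id
  hit_ref <- hit_strict <- hit_two <- rep(FALSE, length(prot))

  if (is.null(reference_results)) {
    warning("reference dataset results missing: reference-q route skipped")
  } else {
    q <- setNames(reference_results$q_value, reference_results$protein_id)[prot]
    p <- setNames(reference_results$p_value, reference_results$protein_id)[prot]
    hit_ref <- !is.na(q) & q < rules$q_ref
    hit_strict <- hit_ref & !is.na(p) & p < rules$p_strict
  }
  if (!is.null(two_site_results)) {
    stopifnot(length(two_site_results) == 2)
    per_site <- lapply(two_site_results, function(res) {
      sapply(split(res, res$predictor), function(d) {
        p <- setNames(d$p_value, d$protein_id)[prot]
        !is.na(p) & p < rules$p_two_site
      })
    })
    hit_two <- Reduce(`&`, lapply(per_site, function(m) apply(m, 1, all)))
  }
  elig <- scores$eligible & !is.na(scores$correlation_score)
  k <- min(rules$top_k, sum(elig))
  hit_top <- rep(FALSE, length(prot))
  if (k > 0) {
    ord <- order(-scores$correlation_score, scores$protein_id)
    hit_top[head(ord[elig[ord]], k)] <- TRUE
  }
  tags <- mapply(function(a, s, b, c) {
    paste(c(if (a) "reference_q", if (s) "reference_strict_p",
            if (b) "two_site", if (c) "top_rank"), collapse = ";")
  }, hit_ref, hit_strict, hit_two, hit_top)
  out <- scores
  out$route_reference_q <- hit_ref
  out$route_two_site <- unname(hit_two)
  out$route_top_rank <- hit_top
  out$selected <- hit_ref | hit_two | hit_top
  out$rules_hit <- unname(tags)
  out
}
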
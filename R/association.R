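#' Sample table of a block assignment
#'
#' One row per sample slot: block, label, colony, replicate, plus the
#' colony's phenotypes and population. Internal join used by the
#' association and ranking stages.
#'
#' @param assignment a `block_assignment`.
#' @param colonies colony frame.
#' @return `data.frame` keyed by (block, label).
#' @keywords internal
sample_table <- function(assignment, colonies) {
  b <- assignment$blocks
  i <- match(b$colony_id, colonies$colony_id)
  if (anyNA(i)) {
    stop("assignment references colonies absent from the colony frame",
         call. = FALSE)
  }
  cbind(b, colonies[i, setdiff(names(colonies), "colony_id"), drop = FALSE],
        row.names = NULL)
}

#' Per-protein association of expression with a colony predictor
#'
#' Fits `expression ~ predictor + label (+ population) + block` for one
#' protein of a normalized quantification matrix, where block enters as a
#' random intercept (lme4) and the remaining terms are fixed; the slope of
#' the predictor is tested (Wald). When the block variance component
#' collapses to the boundary, or for standardized matrices whose blocks
#' are complete triples (where the component is on the boundary by
#' construction), the model falls back to a fixed-effects least-squares
#' fit in which block is absorbed as a fixed factor by within-block
#' demeaning, giving an exact t test with correct residual degrees of
#' freedom.
#'
#' Categorical predictors (e.g. population of origin) are tested jointly
#' (F test) with `effect`/`se` reported as `NA`.
#'
#' @param matrix a [quant_matrix()] (normally `standardized`).
#' @param protein_id protein to fit.
#' @param assignment the `block_assignment` that produced the matrix.
#' @param colonies colony frame with the predictor column.
#' @param predictor colony column name (default `"r24"`).
#' @param adjust_population include population as a fixed covariate (the
#'   rule used for the multi-population reference dataset).
#' @param engine `"auto"` (default), `"lmm"` (force lme4), or `"ols"`
#'   (force the block-absorbed fixed-effects fit).
#' @param min_block_fraction minimum fraction of blocks the protein must be
#'   present in; below it the fit is skipped with a recorded reason.
#' @return One-row `data.frame`: `protein_id`, `predictor`, `effect`, `se`,
#'   `p_value`, `n_obs`, `converged`, `notes` (no q-value; see
#'   [compute_qvalues()]).
#' @export
fit_protein_model <- function(matrix, protein_id, assignment, colonies,
                              predictor = "r24", adjust_population = FALSE,
                              engine = c("auto", "lmm", "ols"),
                              min_block_fraction = 0.25) {
  engine <- match.arg(engine)
  st <- sample_table(assignment, colonies)
  d <- matrix$data[matrix$data$protein == protein_id, , drop = FALSE]
  fit_protein_rows(d, st, matrix, protein_id, predictor, adjust_population,
                   engine, min_block_fraction)
}

# core fitter on the protein's rows; split out so run_dataset can loop
# without re-deriving the sample table
fit_protein_rows <- function(d, st, matrix, protein_id, predictor,
                             adjust_population, engine, min_block_fraction) {
  skip <- function(note) data.frame(
    protein_id = protein_id, predictor = predictor, effect = NA_real_,
    se = NA_real_, p_value = NA_real_, n_obs = nrow(d), converged = FALSE,
    notes = note, stringsAsFactors = FALSE)
  need <- ceiling(min_block_fraction * length(matrix$blocks))
  if (length(unique(d$block)) < max(need, 2L)) {
    return(skip(sprintf("skipped: present in %d blocks (< %d required)",
                        length(unique(d$block)), max(need, 2L))))
  }
  i <- match(paste(d$block, d$label), paste(st$block_id, st$label))
  if (anyNA(i)) return(skip("skipped: cells not covered by the assignment"))
  y <- d$intensity
  xv <- st[[predictor]][i]
  if (is.null(st[[predictor]])) {
    stop("predictor '", predictor, "' is not a colony column", call. = FALSE)
  }
  if (anyNA(xv)) return(skip("skipped: predictor undefined for some colonies"))
  categorical <- is.character(xv) || is.factor(xv)
  if (!categorical && var(xv) == 0) {
    return(skip("inestimable: predictor constant across contributing colonies"))
  }
  lab <- factor(d$label, levels = LABELS)
  pop <- if (adjust_population) factor(st$population[i]) else NULL
  blk <- factor(d$block)

  complete_triples <- all(table(blk) == 3L)
  use_ols <- engine == "ols" ||
    (engine == "auto" && matrix$state == "standardized" && complete_triples)

  if (!use_ols) {
    res <- try(fit_lmm(y, xv, lab, pop, blk, categorical), silent = TRUE)
    if (!inherits(res, "try-error") && !isTRUE(res$singular)) {
      res$row$protein_id <- protein_id
      res$row$predictor <- predictor
      return(res$row)
    }
    note <- if (inherits(res, "try-error")) "fallback: mixed fit failed" else
      "fallback: block variance on boundary"
  } else {
    note <- "ols: block absorbed as fixed factor"
  }
  out <- fit_ols_blocked(y, xv, lab, pop, blk, categorical)
  out$notes <- paste(note, out$notes, sep = ifelse(nzchar(out$notes), "; ", ""))
  cbind(data.frame(protein_id = protein_id, predictor = predictor,
                   stringsAsFactors = FALSE), out)
}

# lme4 random-intercept fit; Wald normal p for the slope
fit_lmm <- function(y, xv, lab, pop, blk, categorical) {
  df <- data.frame(y = y, x = if (categorical) factor(xv) else xv,
                   lab = lab, blk = blk)
  form <- y ~ x + lab + (1 | blk)
  if (!is.null(pop)) {
    df$pop <- pop
    form <- y ~ x + lab + pop + (1 | blk)
  }
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  if (lme4::isSingular(fit, tol = 1e-4)) return(list(singular = TRUE))
  cf <- coef(summary(fit))
  if (categorical) {
    # Wald chi-square over all levels of x
    ix <- grep("^x", rownames(cf))
    b <- cf[ix, 1]
    V <- as.matrix(vcov(fit))[ix, ix, drop = FALSE]
    w <- as.numeric(t(b) %*% solve(V, b))
    p <- stats::pchisq(w, df = length(ix), lower.tail = FALSE)
    row <- data.frame(effect = NA_real_, se = NA_real_, p_value = p,
                      n_obs = length(y), converged = TRUE,
                      notes = "lmm; categorical predictor: Wald chi-square",
                      stringsAsFactors = FALSE)
  } else {
    est <- cf["x", 1]; se <- cf["x", 2]
    p <- 2 * pnorm(-abs(est / se))
    row <- data.frame(effect = est, se = se, p_value = p,
                      n_obs = length(y), converged = TRUE,
                      notes = "lmm: block random intercept",
                      stringsAsFactors = FALSE)
  }
  list(singular = FALSE, row = row)
}

# Fixed-effects fit with block absorbed by within-block demeaning
# (Frisch-Waugh): exact t (or F for categorical predictors) with residual
# df = n - n_blocks - rank(other covariates). Single pivoted QR.
fit_ols_blocked <- function(y, xv, lab, pop, blk, categorical) {
  n <- length(y)
  blk <- droplevels(blk)
  gi <- as.integer(blk)
  nb <- nlevels(blk)
  gs <- tabulate(gi, nb)
  Z_adj <- model.matrix(~lab)[, -1, drop = FALSE]
  if (!is.null(pop) && nlevels(droplevels(pop)) > 1) {
    Z_adj <- cbind(Z_adj, model.matrix(~droplevels(pop))[, -1, drop = FALSE])
  }
  X_pred <- if (categorical) {
    model.matrix(~factor(xv))[, -1, drop = FALSE]
  } else {
    matrix(xv, ncol = 1, dimnames = list(NULL, "x"))
  }
  Z <- cbind(X_pred, Z_adj)
  Zd <- Z - (rowsum(Z, gi) / gs)[gi, , drop = FALSE]
  yd <- y - (rowsum(y, gi)[, 1] / gs)[gi]
  qr_full <- qr(Zd)
  df_res <- n - nb - qr_full$rank
  if (df_res <= 0) {
    return(data.frame(effect = NA_real_, se = NA_real_, p_value = NA_real_,
                      n_obs = n, converged = FALSE,
                      notes = "inestimable: no residual degrees of freedom",
                      stringsAsFactors = FALSE))
  }
  cf <- qr.coef(qr_full, yd)
  resid <- qr.resid(qr_full, yd)
  rss <- sum(resid^2)
  s2 <- rss / df_res
  npred <- ncol(X_pred)
  if (anyNA(cf[seq_len(npred)])) {
    return(data.frame(effect = NA_real_, se = NA_real_, p_value = NA_real_,
                      n_obs = n, converged = FALSE,
                      notes = "inestimable: predictor collinear with block/label",
                      stringsAsFactors = FALSE))
  }
  if (s2 < 1e-28) {
    return(data.frame(effect = unname(cf[1]), se = NA_real_,
                      p_value = 1, n_obs = n, converged = FALSE,
                      notes = "degenerate: zero-variance response",
                      stringsAsFactors = FALSE))
  }
  if (categorical) {
    fit0 <- lm.fit(Zd[, -seq_len(npred), drop = FALSE], yd)
    rss0 <- sum(fit0$residuals^2)
    Fst <- ((rss0 - rss) / npred) / s2
    p <- stats::pf(Fst, npred, df_res, lower.tail = FALSE)
    data.frame(effect = NA_real_, se = NA_real_, p_value = p, n_obs = n,
               converged = TRUE, notes = "categorical predictor: F test",
               stringsAsFactors = FALSE)
  } else {
    r <- qr_full$rank
    R <- qr.R(qr_full)[seq_len(r), seq_len(r), drop = FALSE]
    XtXinv <- chol2inv(R)
    piv <- qr_full$pivot %||% seq_len(ncol(Zd))
    k <- match(1L, piv)  # position of the predictor column after pivoting
    se <- sqrt(s2 * XtXinv[k, k])
    est <- unname(cf[1])
    tstat <- est / se
    data.frame(effect = est, se = se,
               p_value = 2 * pt(-abs(tstat), df_res), n_obs = n,
               converged = TRUE, notes = "", stringsAsFactors = FALSE)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted values with enforced monotonicity, order-preserving
#' with the input; `NA` p-values yield `NA` q-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
#' @examples
#' compute_qvalues(c(0.01, 0.02, 0.03, 0.04))
compute_qvalues <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Fit every retained protein of a dataset against one or more predictors
#'
#' Applies [fit_protein_model()] to each protein of the matrix for each
#' predictor, then computes Benjamini-Hochberg q-values per predictor over
#' the successfully fitted proteins. Skipped proteins stay in the output
#' with their reason and `NA` statistics. Never aborts on a single
#' protein's failure.
#'
#' @inheritParams fit_protein_model
#' @param predictors character vector of colony columns to test.
#' @return `data.frame` of association results (one row per protein x
#'   predictor, ordered by predictor then protein), with columns
#'   `protein_id`, `predictor`, `effect`, `se`, `p_value`, `q_value`,
#'   `n_obs`, `converged`, `notes`. A summary log is attached as attribute
#'   `"log"`.
#' @export
run_dataset <- function(matrix, assignment, colonies, predictors = "r24",
                        adjust_population = FALSE,
                        engine = c("auto", "lmm", "ols"),
                        min_block_fraction = 0.25) {
  engine <- match.arg(engine)
  st <- sample_table(assignment, colonies)
  proteins <- sort(unique(matrix$data$protein))
  if (!length(proteins)) {
    warning("no proteins in matrix; empty result")
    return(data.frame(protein_id = character(), predictor = character(),
                      effect = numeric(), se = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      n_obs = integer(), converged = logical(),
                      notes = character(), stringsAsFactors = FALSE))
  }
  by_prot <- split(matrix$data, matrix$data$protein)
  out <- vector("list", length(predictors))
  for (k in seq_along(predictors)) {
    rows <- lapply(proteins, function(p)
      fit_protein_rows(by_prot[[p]], st, matrix, p, predictors[k],
                       adjust_population, engine, min_block_fraction))
    res <- do.call(rbind, rows)
    res$q_value <- compute_qvalues(res$p_value)
    out[[k]] <- res[, c("protein_id", "predictor", "effect", "se",
                        "p_value", "q_value", "n_obs", "converged", "notes")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_skip <- sum(!res$converged & grepl("^skipped", res$notes))
  n_fb <- sum(grepl("^fallback", res$notes))
  attr(res, "log") <- sprintf(
    "run_dataset: %d proteins x %d predictor(s); %d fits, %d fallbacks, %d skips",
    length(proteins), length(predictors), sum(res$converged), n_fb, n_skip)
  res
}
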
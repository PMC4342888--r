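#' Construct a protein quantification matrix
#'
#' Long-format container for per-protein intensities over (block, label)
#' cells. Cells absent from `data` are missing. The object tracks its
#' processing `state`, which may only advance through
#' `raw -> log -> block_centered -> standardized`; each processing step
#' appends to the provenance log.
#'
#' @param data `data.frame` with columns `protein`, `block`, `label`,
#'   `intensity` (one row per present cell).
#' @param blocks character vector of all blocks in the experiment (defaults
#'   to the blocks observed in `data`; supply explicitly when some blocks
#'   detected nothing, since detection filtering is relative to the full
#'   block count).
#' @param state processing state of the supplied intensities.
#' @param provenance character vector of processing-log lines.
#' @return A `quant_matrix` object.
#' @export
quant_matrix <- function(data, blocks = NULL, state = "raw",
                         provenance = character()) {
  need <- c("protein", "block", "label", "intensity")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("`data` must have columns protein, block, label, intensity",
         call. = FALSE)
  }
  data <- data[, need]
  data$protein <- as.character(data$protein)
  data$block <- as.character(data$block)
  data$label <- as.character(data$label)
  bad_lab <- setdiff(unique(data$label), LABELS)
  if (length(bad_lab)) {
    stop("unknown label(s): ", paste(bad_lab, collapse = ", "),
         " (expected light/medium/heavy)", call. = FALSE)
  }
  if (anyDuplicated(data[, c("protein", "block", "label")])) {
    stop("duplicated (protein, block, label) cells", call. = FALSE)
  }
  states <- c("raw", "log", "block_centered", "standardized")
  state <- match.arg(state, states)
  structure(list(data = data,
                 blocks = sort(unique(c(blocks, data$block))),
                 state = state,
                 provenance = provenance),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix:", length(unique(x$data$protein)), "proteins x",
      length(x$blocks), "blocks (", nrow(x$data), "present cells ),",
      "state:", x$state, "\n")
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (line in x$provenance) cat(" -", line, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.quant_matrix <- function(x, ...) x$data

qm_advance <- function(qm, new_state, note) {
  states <- c("raw", "log", "block_centered", "standardized")
  if (match(new_state, states) <= match(qm$state, states)) {
    stop("invalid state transition: ", qm$state, " -> ", new_state,
         call. = FALSE)
  }
  qm$state <- new_state
  qm$provenance <- c(qm$provenance, note)
  qm
}

# wide protein x (block.label) view used by tests and summaries
qm_wide <- function(qm) {
  d <- qm$data
  key <- paste(d$block, d$label, sep = ".")
  prot <- sort(unique(d$protein))
  cols <- as.vector(outer(sort(unique(d$block)), LABELS, paste, sep = "."))
  m <- matrix(NA_real_, length(prot), length(cols),
              dimnames = list(prot, cols))
  m[cbind(match(d$protein, prot), match(key, cols))] <- d$intensity
  m
}
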
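#' Read and write the pipeline's tabular formats
#'
#' Plain-text interchange: colony phenotype tables (CSV), block-design
#' tables (TSV), long-format quantification matrices (TSV with `#key:
#' value` header lines carrying the processing state), PSM tables (TSV)
#' and titration curves (CSV with a `#` header block for mode and
#' concentrations). All writers produce files the matching readers
#' round-trip.
#'
#' @param colonies,assignment,matrix,psms,curve object to write.
#' @param path file path.
#' @name hbmarkers-io
NULL

#' @rdname hbmarkers-io
#' @export
write_colony_csv <- function(colonies, path) {
  cols <- c("colony_id", "site", "year", "population", "dam_id", "sire_id",
            "r24", "r48", "u24", "u48", "hb_true")
  cols <- intersect(cols, names(colonies))
  write.csv(colonies[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hbmarkers-io
#' @export
read_colony_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(colony_id = "character"))
}

#' @rdname hbmarkers-io
#' @export
write_design_tsv <- function(assignment, path) {
  b <- if (inherits(assignment, "block_assignment")) assignment$blocks else assignment
  write.table(b, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hbmarkers-io
#' @export
read_design_tsv <- function(path) {
  b <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(block_id = "character",
                                 colony_id = "character"))
  structure(list(blocks = b, objective_value = NA_real_,
                 objective = NA_character_, hb_variable = NA_character_,
                 seed = NA_integer_),
            class = "block_assignment")
}

#' @rdname hbmarkers-io
#' @export
write_quant_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "quant_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#state: %s", matrix$state), con)
  writeLines(sprintf("#blocks: %s", paste(matrix$blocks, collapse = ",")), con)
  for (line in matrix$provenance) writeLines(paste0("#log: ", line), con)
  write.table(matrix$data, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hbmarkers-io
#' @export
read_quant_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  d <- read.delim(text = paste(body, collapse = "\n"),
                  stringsAsFactors = FALSE)
  grab <- function(key) sub(paste0("^#", key, ": "), "",
                            grep(paste0("^#", key, ": "), hdr, value = TRUE))
  blocks <- strsplit(grab("blocks"), ",", fixed = TRUE)[[1]]
  state <- grab("state")
  prov <- sub("^#log: ", "", grep("^#log: ", hdr, value = TRUE))
  quant_matrix(d, blocks = blocks,
               state = if (length(state)) state else "raw",
               provenance = prov)
}

#' @rdname hbmarkers-io
#' @export
write_psm_tsv <- function(psms, path) {
  write.table(psms, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hbmarkers-io
#' @export
read_psm_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname hbmarkers-io
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#mode: %s", curve$mode),
               sprintf("#protein_conc: %.10g", curve$protein_conc),
               sprintf("#probe_conc: %.10g", curve$probe_conc)), con)
  write.csv(curve$points, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hbmarkers-io
#' @export
read_titration_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  grab <- function(key) sub(paste0("^#", key, ": "), "",
                            grep(paste0("^#", key, ": "), hdr, value = TRUE))
  pts <- read.csv(text = paste(body, collapse = "\n"),
                  stringsAsFactors = FALSE)
  structure(list(mode = grab("mode"),
                 protein_conc = as.numeric(grab("protein_conc")),
                 probe_conc = as.numeric(grab("probe_conc")),
                 points = pts, truth = NULL),
            class = "titration_curve")
}

#' Write a ground-truth sidecar in a structured text format
#'
#' Flat `key: value` text (vectors comma-joined, matrices as per-row
#' lines) so simulation ground truth can travel next to the generated
#' tables without binary formats.
#'
#' @param truth a [ground_truth()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(key, val) writeLines(sprintf("%s: %s", key,
                                             paste(val, collapse = ",")), con)
  w("n_proteins", length(truth$proteins))
  w("marker_ids", truth$marker_ids)
  w("beta", sprintf("%.10g", truth$beta))
  w("h2", sprintf("%.10g", unique(truth$h2)))
  w("sigma_colony", truth$sigma_colony)
  w("sigma_resid", truth$sigma_resid)
  w("sigma_block", truth$sigma_block)
  w("sigma_label", truth$sigma_label)
  w("missing_rate", truth$missing_model$rate)
  w("missing_mcar", truth$missing_model$mcar)
  w("seed", truth$seed)
  invisible(path)
}
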
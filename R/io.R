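# Single TSV dialect used by every stage: tab-separated, '#'-prefixed
# comment/provenance lines before the header row.

# polynomial rolling hash of a deparsed object, for provenance lines
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

.provenance <- function(seed = NA, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("dielscan")),
                  error = function(e) "dev")
  sprintf("# dielscan %s | seed=%s | config=%s | %s",
          ver, seed, .config_hash(config), format(Sys.time(), "%Y-%m-%d"))
}

.write_tsv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression time-course TSV
#'
#' First column: gene ID; remaining columns headed by the sampling hour.
#' '#'-prefixed lines are skipped. Genes with missing values are dropped
#' with a message.
#'
#' @param path Path to the TSV.
#' @param condition Condition label to attach.
#' @return A [timecourse_matrix()].
#' @export
read_timecourse <- function(path, condition = "unspecified") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("time-course TSV needs >= 2 time points")
  times <- suppressWarnings(as.numeric(sub("^[Xt]?", "", names(tab)[-1])))
  if (anyNA(times)) stop("column headers after the first must be hours")
  vals <- as.matrix(tab[, -1])
  rownames(vals) <- tab[[1]]
  timecourse_matrix(vals, times, condition = condition)
}

#' Write an expression time-course TSV
#'
#' @param matrix_tc A [timecourse_matrix()].
#' @param path Output path.
#' @param seed,config Provenance fields for the header comment.
#' @return The path, invisibly.
#' @export
write_timecourse <- function(matrix_tc, path, seed = NA, config = NULL) {
  df <- data.frame(gene_id = matrix_tc$gene_ids,
                   matrix_tc$values, check.names = FALSE)
  names(df)[-1] <- matrix_tc$times_h
  .write_tsv(df, path, seed, config)
}

#' Write cycling calls as TSV
#'
#' Columns: gene_id, condition, shape, phase, r, p, fdr, is_cycling.
#'
#' @param calls A `cycling_calls` data.frame.
#' @param path Output path.
#' @param seed,config Provenance fields.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path, seed = NA, config = NULL) {
  .write_tsv(calls, path, seed, config)
}

#' Read cycling calls written by [write_calls()]
#'
#' @param path Path to the TSV.
#' @return A `cycling_calls` data.frame.
#' @export
read_calls <- function(path) {
  calls <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  class(calls) <- c("cycling_calls", "data.frame")
  calls
}

#' Write promoters as FASTA
#'
#' @param promoters A `promoter_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
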
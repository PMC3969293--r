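# Plain-text readers/writers for the pipeline's tabular artifacts.

#' Write a trial table as CSV
#'
#' Columns: `subject_id,trial,n_yellow,n_blue,response,correct,rt_ms`.
#'
#' @param trials Trial data frame (see [simulate_population_sessions()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  cols <- c("subject_id", "trial", "n_yellow", "n_blue", "response",
            "correct", "rt_ms")
  stopifnot(all(cols %in% names(trials)))
  out <- trials[, cols]
  out$correct <- as.integer(out$correct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial CSV
#'
#' @param path File written by [write_trials_csv()].
#' @return Trial data frame with a logical `correct` column.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  d$correct <- as.logical(d$correct)
  d
}

#' Write a twin phenotype table as TSV
#'
#' Columns: `family_id,twin,zygosity,sex,age,pheno_accuracy,pheno_weber`
#' (phenotype columns present if found in the input). In opposite-sex
#' pairs twin 1 is the male.
#'
#' @param dataset Twin data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pheno_tsv <- function(dataset, path) {
  cols <- intersect(c("family_id", "twin", "zygosity", "sex", "age",
                      "group", "pheno", "pheno_accuracy", "pheno_weber",
                      "pheno_resid", "pheno_accuracy_resid",
                      "pheno_weber_resid"),
                    names(dataset))
  utils::write.table(dataset[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a twin phenotype TSV
#'
#' @param path File written by [write_pheno_tsv()].
#' @return Twin data frame.
#' @export
read_pheno_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write per-subject scores as TSV
#'
#' Columns: `subject_id,accuracy,weber,n_kept,sse`.
#'
#' @param scores Output of [score_subjects()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write generative ground truth as a plain-text key-value file
#'
#' @param truth Named list of generative parameters.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_file <- function(truth, path) {
  lines <- vapply(names(truth), function(k) {
    paste0(k, "\t", paste(format(truth[[k]], digits = 10), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
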
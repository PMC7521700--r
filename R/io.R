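#' Write and read peak lists and sample sheets
#'
#' Peak lists are CSV with columns `sample_id`, `mz`, `intensity`; the
#' sample sheet is CSV with `sample_id`, `isolate_id`, `condition`
#' (15N/14N) and `replicate`.
#'
#' @param sim a `peak_sim` from [simulate_peak_lists()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`peaks.csv`, `samples.csv`,
#'   `truth.csv`).
#' @export
write_peak_lists <- function(sim, dir) {
  stopifnot(inherits(sim, "peak_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("peaks.csv", "samples.csv", "truth.csv"))
  write.csv(sim$peaks, paths[1], row.names = FALSE)
  write.csv(sim$samples, paths[2], row.names = FALSE)
  write.csv(sim$truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_peak_lists
#' @param peaks_csv,samples_csv paths to the peak-list and sample-sheet
#'   CSV files.
#' @return for `read_peak_lists`: list with `peaks` and `samples`
#'   data.frames.
#' @export
read_peak_lists <- function(peaks_csv, samples_csv) {
  list(peaks = read.csv(peaks_csv, stringsAsFactors = FALSE),
       samples = read.csv(samples_csv, stringsAsFactors = FALSE,
                          colClasses = c(condition = "character")))
}

#' Write a feature matrix to CSV
#'
#' Rows are features (with a leading `mz` column), columns are samples.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(feature = rownames(fm$intensities), mz = fm$mz,
                   fm$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' @rdname write_feature_matrix
#' @param samples sample sheet data.frame matching the matrix columns.
#' @return for `read_feature_matrix`: a `feature_matrix`.
#' @export
read_feature_matrix <- function(path, samples) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(mat) <- df$feature
  stopifnot(all(colnames(mat) %in% samples$sample_id))
  structure(list(mz = df$mz, intensities = mat,
                 samples = samples[match(colnames(mat),
                                         samples$sample_id), ,
                                   drop = FALSE]),
            class = "feature_matrix")
}

#' Write a similarity matrix to CSV
#'
#' @param jsi symmetric matrix from [compare_sketches()].
#' @param path output CSV (genome ids as first column and header).
#' @export
write_similarity_matrix <- function(jsi, path) {
  write.csv(data.frame(genome_id = rownames(jsi), jsi,
                       check.names = FALSE), path, row.names = FALSE)
}

#' Run the biomarker assay from CSV inputs
#'
#' Convenience end-to-end wrapper for shell-driven use: reads a
#' peak-list CSV and sample sheet, aligns peaks, runs the BNF assay and
#' (optionally) writes the biomarker table, per-isolate results and
#' group summary as CSV next to a record of the parameters used.
#'
#' @inheritParams read_peak_lists
#' @inheritParams align_peaks
#' @inheritParams bnf_assay
#' @param out_dir optional output directory for
#'   `biomarkers.csv`, `bnf_results.csv`, `bnf_summary.csv`,
#'   `parameters.yaml`.
#' @return the `bnf_result`, invisibly when writing.
#' @export
run_bnf_pipeline <- function(peaks_csv, samples_csv, tolerance = 0.01,
                             q_threshold = 0.05, fc_threshold = 1,
                             log_transform = FALSE, include_all = FALSE,
                             out_dir = NULL) {
  inp <- read_peak_lists(peaks_csv, samples_csv)
  fm <- align_peaks(inp$peaks, inp$samples, tolerance = tolerance)
  res <- bnf_assay(fm, q_threshold = q_threshold,
                   fc_threshold = fc_threshold,
                   log_transform = log_transform,
                   include_all = include_all)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$biomarkers, file.path(out_dir, "biomarkers.csv"),
              row.names = FALSE)
    write.csv(res$results, file.path(out_dir, "bnf_results.csv"),
              row.names = FALSE)
    write.csv(res$summary, file.path(out_dir, "bnf_summary.csv"),
              row.names = FALSE)
    yaml::write_yaml(
      list(peaks_csv = peaks_csv, samples_csv = samples_csv,
           tolerance = tolerance, q_threshold = q_threshold,
           fc_threshold = fc_threshold, log_transform = log_transform,
           include_all = include_all,
           diazokit_version =
             as.character(utils::packageVersion("diazokit"))),
      file.path(out_dir, "parameters.yaml"))
    return(invisible(res))
  }
  res
}
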
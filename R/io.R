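#' Read a per-run spreadsheet of single-cell depletion data
#'
#' Reads the supplementary spreadsheet layout used for the microfluidic
#' depletion assays: one sheet per microscope run. Each sheet is expected to
#' hold a time column (minutes) in its first column and one FI column per
#' cell; sheet names (or the `runs` table) supply the depletion time. The
#' result maps onto the same fluorescence/budding/run tables produced by
#' [write_population_csvs()].
#'
#' Requires the `readxl` package. The spreadsheet itself is third-party
#' supplementary data and is not bundled; supply a local copy.
#'
#' @param path Path to the `.xlsx` file.
#' @param sheets Sheet names or indices to read (default: all).
#' @param runs Optional data frame (`sheet`, `depletion_time_hr`,
#'   `depletion_start_min`) describing each sheet; defaults to `NA`
#'   metadata.
#' @return List with `fluorescence` (long data frame: `run_id`, `cell_id`,
#'   `time_min`, `fi_au`) and `runs`.
#' @export
read_s1_dataset <- function(path, sheets = NULL, runs = NULL) {
  if (!file.exists(path))
    stop("spreadsheet not found: ", path,
         "\n(the supplementary single-cell dataset must be supplied locally)")
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("read_s1_dataset() requires the 'readxl' package")
  if (is.null(sheets)) sheets <- readxl::excel_sheets(path)
  fl <- list()
  for (sh in sheets) {
    d <- as.data.frame(readxl::read_excel(path, sheet = sh))
    if (ncol(d) < 2L) next
    time <- as.numeric(d[[1]])
    for (j in 2:ncol(d)) {
      fi <- suppressWarnings(as.numeric(d[[j]]))
      keep <- is.finite(time) & is.finite(fi)
      if (!any(keep)) next
      fl[[length(fl) + 1L]] <- data.frame(
        run_id = as.character(sh),
        cell_id = paste0(sh, "_", names(d)[j]),
        time_min = time[keep], fi_au = fi[keep])
    }
  }
  if (!length(fl)) stop("no numeric fluorescence columns found in ", path)
  if (is.null(runs))
    runs <- data.frame(sheet = as.character(sheets),
                       depletion_time_hr = NA_real_,
                       depletion_start_min = NA_real_)
  list(fluorescence = do.call(rbind, fl), runs = runs)
}
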
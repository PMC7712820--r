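#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample`, `karyotype`, `phenotype`
#' and `role`, one row per strain. `karyotype` must be `monokaryon` or
#' `dikaryon`; `phenotype` must be `B` (normal brown film), `AB` (abnormal
#' brown film) or `unknown` (allowed only for panel-scoring queries).
#' Gzip-compressed files are accepted.
#'
#' @param path path to the TSV sample sheet.
#' @return a [S4Vectors::DataFrame] with columns `name`, `karyotype`,
#'   `phenotype`, `role`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tkaryotype\tphenotype\trole",
#'              "P37-5\tmonokaryon\tAB\tP1"), tf)
#' readSampleSheet(tf)
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample", "karyotype", "phenotype", "role")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("sample sheet ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    return(S4Vectors::DataFrame(name = character(), karyotype = character(),
                                phenotype = character(), role = character()))
  }
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup))
    stop("duplicate sample name(s) in sheet: ", paste(unique(dup), collapse = ", "))
  badk <- which(!df$karyotype %in% .KARYOTYPES)
  if (length(badk))
    stop("row ", badk[1], " (sample '", df$sample[badk[1]],
         "'): unknown karyotype '", df$karyotype[badk[1]],
         "' (expected monokaryon/dikaryon)")
  badp <- which(!df$phenotype %in% .PHENOTYPES)
  if (length(badp))
    stop("row ", badp[1], " (sample '", df$sample[badp[1]],
         "'): unknown phenotype '", df$phenotype[badp[1]],
         "' (expected B/AB/unknown)")
  S4Vectors::DataFrame(name = df$sample, karyotype = df$karyotype,
                       phenotype = df$phenotype, role = df$role)
}

#' Write a sample sheet
#'
#' @param samples a data.frame / DataFrame with columns `name`, `karyotype`,
#'   `phenotype`, `role`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSampleSheet <- function(samples, path) {
  df <- as.data.frame(samples)
  out <- data.frame(sample = df$name, karyotype = df$karyotype,
                    phenotype = df$phenotype, role = df$role)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
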
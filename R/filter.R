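#' Record-level SNP filter criteria
#'
#' Encodes the record-level selection applied to called variants before any
#' co-segregation analysis: (i) biallelic SNP records only, (ii) minimum
#' per-call read depth, (iii) minimum per-call genotype quality, (iv) no
#' missing calls across samples. Thresholds are inclusive (a depth-10 call
#' passes `min_depth = 10`).
#'
#' @param require_biallelic reject records with more than one ALT allele.
#' @param min_depth minimum read depth per call (0 disables the check).
#' @param min_gq minimum Phred-scaled genotype quality per call (0 disables).
#' @param require_complete reject records with any missing call.
#' @param snps_only reject records whose REF or any ALT is not a single
#'   nucleotide.
#' @return a `FilterCriteria` list.
#' @export
filterCriteria <- function(require_biallelic = TRUE, min_depth = 10,
                           min_gq = 60, require_complete = TRUE,
                           snps_only = TRUE) {
  stopifnot(min_depth >= 0, min_gq >= 0)
  structure(list(require_biallelic = isTRUE(require_biallelic),
                 min_depth = as.numeric(min_depth),
                 min_gq = as.numeric(min_gq),
                 require_complete = isTRUE(require_complete),
                 snps_only = isTRUE(snps_only)),
            class = "FilterCriteria")
}

#' Apply record-level filters to genotype calls
#'
#' A site survives iff it satisfies every enabled criterion; a rejected site
#' is annotated with the *first* criterion it fails, in the fixed audit order
#' (i) biallelic SNP, (ii) depth, (iii) genotype quality, (iv) completeness.
#' Depth and quality thresholds apply per call across all samples — a single
#' failing call rejects the site — and are only evaluated on non-missing
#' calls (missing calls are criterion iv). A per-call `NA` depth/quality on a
#' non-missing genotype counts as failing its threshold; if the VCF carried
#' no DP (or GQ) field at all while the corresponding threshold is positive,
#' an error is raised rather than silently passing.
#'
#' @param x a [GenotypeCalls-class].
#' @param criteria a [filterCriteria()] object.
#' @return a list with elements `passed` (the surviving [GenotypeCalls-class]
#'   subset), `rejected` (data.frame `scaffold`, `position`, `reason`), and
#'   `reason` (full per-site character vector, `NA` for survivors).
#' @examples
#' # see ?filterCriteria for threshold semantics
#' @export
applyFilters <- function(x, criteria = filterCriteria()) {
  stopifnot(inherits(criteria, "FilterCriteria"))
  ns <- dim(x)[1]
  sites <- x@sites
  reason <- rep(NA_character_, ns)
  missing_call <- is.na(x@a1)

  if (criteria$min_depth > 0 && all(is.na(x@depth)) && any(!missing_call) && ns > 0)
    stop("min_depth > 0 but the genotype table carries no DP values")
  if (criteria$min_gq > 0 && all(is.na(x@gq)) && any(!missing_call) && ns > 0)
    stop("min_gq > 0 but the genotype table carries no GQ values")

  nalt <- lengths(S4Vectors::mcols(sites)$alt)
  ref <- S4Vectors::mcols(sites)$ref
  # (i) biallelic SNP
  if (criteria$require_biallelic) {
    bad <- nalt != 1L
    reason[is.na(reason) & bad] <- "not_biallelic"
  }
  if (criteria$snps_only) {
    alt_snv <- vapply(S4Vectors::mcols(sites)$alt,
                      function(a) all(nchar(a) == 1L) && length(a) > 0,
                      logical(1))
    bad <- nchar(ref) != 1L | !alt_snv
    reason[is.na(reason) & bad] <- "not_snp"
  }
  # (ii) read depth, per call, non-missing calls only
  if (criteria$min_depth > 0) {
    fail <- !missing_call & (is.na(x@depth) | x@depth < criteria$min_depth)
    bad <- rowSums(fail) > 0
    reason[is.na(reason) & bad] <- "low_depth"
  }
  # (iii) genotype quality
  if (criteria$min_gq > 0) {
    fail <- !missing_call & (is.na(x@gq) | x@gq < criteria$min_gq)
    bad <- rowSums(fail) > 0
    reason[is.na(reason) & bad] <- "low_gq"
  }
  # (iv) completeness
  if (criteria$require_complete) {
    bad <- rowSums(missing_call) > 0
    reason[is.na(reason) & bad] <- "missing_call"
  }
  keep <- is.na(reason)
  rejected <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(sites))[!keep],
    position = GenomicRanges::start(sites)[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE)
  list(passed = x[keep, ], rejected = rejected, reason = reason)
}
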
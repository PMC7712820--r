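#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start width
#' @importFrom Biostrings DNAString DNAStringSet GENETIC_CODE
NULL

.KARYOTYPES <- c("monokaryon", "dikaryon")
.PHENOTYPES <- c("B", "AB", "unknown")
.GENO_CLASSES <- c("DOM", "HET", "REC", "MISSING")

#' GeneModel: a strand-aware CDS model for coding-effect classification
#'
#' Holds the ordered coding intervals of one gene and its coding-strand
#' sequence. Intervals are stored in *translation order*: ascending genomic
#' coordinates on the plus strand, descending on the minus strand. The coding
#' sequence is the concatenation of the intervals read on the coding strand,
#' so for a minus-strand gene it is the reverse complement of the genomic
#' sequence of the intervals.
#'
#' @slot geneId gene identifier.
#' @slot scaffold scaffold/contig name the gene lies on.
#' @slot strand `"+"` or `"-"`.
#' @slot cdsIntervals [IRanges::IRanges] of 1-based inclusive genomic CDS
#'   intervals, in translation order.
#' @slot codingSeq [Biostrings::DNAString] coding-strand sequence; its length
#'   equals the summed interval widths and is a multiple of 3.
#'
#' @seealso [GeneModel()], [classifyEffect()], [genomicToCds()]
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    geneId = "character",
    scaffold = "character",
    strand = "character",
    cdsIntervals = "IRanges",
    codingSeq = "DNAString"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be a single string")
  if (length(object@scaffold) != 1L) msg <- c(msg, "scaffold must be a single string")
  if (!identical(length(object@strand), 1L) || !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  iv <- object@cdsIntervals
  if (length(iv) < 1L) msg <- c(msg, "at least one CDS interval required")
  if (length(iv) >= 1L) {
    st <- sort(IRanges::start(iv))
    en <- sort(IRanges::end(iv))
    if (any(en[-length(en)] >= st[-1L]))
      msg <- c(msg, "CDS intervals must not overlap")
    ord <- IRanges::start(iv)
    if (length(iv) > 1L) {
      if (object@strand == "+" && is.unsorted(ord, strictly = TRUE))
        msg <- c(msg, "plus-strand intervals must ascend (translation order)")
      if (object@strand == "-" && is.unsorted(rev(ord), strictly = TRUE))
        msg <- c(msg, "minus-strand intervals must descend (translation order)")
    }
    tot <- sum(IRanges::width(iv))
    if (tot %% 3L != 0L) msg <- c(msg, "total CDS length must be a multiple of 3")
    if (tot != length(object@codingSeq))
      msg <- c(msg, "codingSeq length must equal summed CDS interval widths")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeCalls: karyotype-aware SNP genotypes for a set of strains
#'
#' The central genotype container. Rows are variant sites (a [GRanges] with
#' `ref` and `alt` metadata columns, `alt` a [S4Vectors::CharacterList] so
#' multi-allelic records are carried intact and can be rejected auditable by
#' the filter); columns are strains described by a sample sheet
#' (name/karyotype/phenotype/role). Allele calls are stored as two integer
#' matrices: monokaryons use `a1` only (`a2` is `NA`), dikaryons use both,
#' normalized so `a1 <= a2` (unphased, order-free). A fully `NA` pair is a
#' missing call. `depth` and `gq` carry per-call DP and Phred-scaled GQ, with
#' `NA` where the VCF had no value.
#'
#' @slot sites [GenomicRanges::GRanges], width-1 positions with mcols `ref`
#'   (character) and `alt` (CharacterList).
#' @slot samples [S4Vectors::DataFrame] with columns `name`, `karyotype`
#'   (`monokaryon`/`dikaryon`), `phenotype` (`B`/`AB`/`unknown`), `role`.
#' @slot a1,a2 integer matrices of allele indices (0 = REF, k = k-th ALT).
#' @slot depth,gq integer matrices (read depth, genotype quality), NA allowed.
#'
#' @seealso [GenotypeCalls()], [readGenotypeVcf()], [applyFilters()]
#' @exportClass GenotypeCalls
setClass("GenotypeCalls",
  representation(
    sites = "GRanges",
    samples = "DataFrame",
    a1 = "matrix",
    a2 = "matrix",
    depth = "matrix",
    gq = "matrix"
  )
)

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  ns <- length(object@sites)
  nk <- nrow(object@samples)
  need <- c("name", "karyotype", "phenotype", "role")
  if (!all(need %in% colnames(object@samples)))
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@samples$name))
    msg <- c(msg, "sample names must be unique")
  if (!all(object@samples$karyotype %in% .KARYOTYPES))
    msg <- c(msg, "karyotype must be 'monokaryon' or 'dikaryon'")
  if (!all(object@samples$phenotype %in% .PHENOTYPES))
    msg <- c(msg, "phenotype must be 'B', 'AB' or 'unknown'")
  if (!all(c("ref", "alt") %in% colnames(mcols(object@sites))))
    msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
  for (sl in c("a1", "a2", "depth", "gq")) {
    m <- slot(object, sl)
    if (!identical(dim(m), c(ns, nk)))
      msg <- c(msg, sprintf("%s must be %d x %d", sl, ns, nk))
  }
  if (!length(msg)) {
    mono <- object@samples$karyotype == "monokaryon"
    if (any(mono) && any(!is.na(object@a2[, mono, drop = FALSE])))
      msg <- c(msg, "monokaryon calls must have a single allele (a2 = NA)")
    both <- !is.na(object@a1) & !is.na(object@a2)
    if (any(object@a1[both] > object@a2[both]))
      msg <- c(msg, "dikaryon allele pairs must be normalized (a1 <= a2)")
    if (any(is.na(object@a1) & !is.na(object@a2)))
      msg <- c(msg, "a2 set where a1 is missing")
    nalt <- lengths(mcols(object@sites)$alt)
    bad <- function(m) {
      ok <- is.na(m) | (m >= 0L & m <= nalt[row(m)])
      !all(ok)
    }
    if (ns > 0 && nk > 0 && (bad(object@a1) || bad(object@a2)))
      msg <- c(msg, "allele index out of range for site")
    if (any(object@depth < 0, na.rm = TRUE) || any(object@gq < 0, na.rm = TRUE))
      msg <- c(msg, "depth and gq must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SegregationTest: chi-square goodness-of-fit to a Mendelian ratio
#'
#' Result container for [chiSquareSegregation()].
#'
#' @slot observed named integer counts per phenotype class.
#' @slot ratio expected small-integer ratio per class (e.g. 3:1).
#' @slot expected real expected counts (sum equals observed total).
#' @slot chi2 the uncorrected Pearson chi-square statistic.
#' @slot df degrees of freedom (classes - 1).
#' @slot p upper-tail p-value from the chi-square distribution.
#' @exportClass SegregationTest
setClass("SegregationTest",
  representation(
    observed = "numeric",
    ratio = "numeric",
    expected = "numeric",
    chi2 = "numeric",
    df = "integer",
    p = "numeric"
  )
)

setValidity("SegregationTest", function(object) {
  msg <- character()
  k <- length(object@observed)
  if (length(object@ratio) != k || length(object@expected) != k)
    msg <- c(msg, "observed, ratio and expected must have equal length")
  if (!isTRUE(all.equal(sum(object@expected), sum(object@observed))))
    msg <- c(msg, "expected counts must sum to the observed total")
  if (object@df != k - 1L || object@df < 1L)
    msg <- c(msg, "df must equal classes - 1 and be >= 1")
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be >= 0")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
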
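#' Construct a GenotypeCalls object
#'
#' @param sites a [GenomicRanges::GRanges] of width-1 SNP positions with
#'   metadata columns `ref` (character) and `alt` (a
#'   [S4Vectors::CharacterList] or character vector of comma-joined ALTs).
#' @param samples a data.frame / [S4Vectors::DataFrame] with columns
#'   `name`, `karyotype`, `phenotype`, `role` (see [readSampleSheet()]).
#' @param a1,a2 integer matrices of allele indices (sites x samples);
#'   monokaryons use `a1` only. Dikaryon pairs are normalized to `a1 <= a2`.
#' @param depth,gq optional integer matrices of per-call read depth and
#'   Phred-scaled genotype quality; default all-`NA` (absent).
#' @return a [GenotypeCalls-class] object.
#' @export
GenotypeCalls <- function(sites, samples, a1, a2, depth = NULL, gq = NULL) {
  samples <- S4Vectors::DataFrame(as.data.frame(samples))
  alt <- S4Vectors::mcols(sites)$alt
  if (!is(alt, "CharacterList")) {
    S4Vectors::mcols(sites)$alt <- IRanges::CharacterList(strsplit(as.character(alt), ",", fixed = TRUE))
  }
  ns <- length(sites); nk <- nrow(samples)
  shape <- function(m, what) {
    if (is.null(m)) m <- matrix(NA_integer_, ns, nk)
    m <- matrix(as.integer(m), ns, nk)
    colnames(m) <- samples$name
    m
  }
  a1 <- shape(a1); a2 <- shape(a2)
  # normalize unphased dikaryon pairs
  both <- !is.na(a1) & !is.na(a2)
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  a1[both] <- lo[both]; a2[both] <- hi[both]
  new("GenotypeCalls", sites = sites, samples = samples,
      a1 = a1, a2 = a2, depth = shape(depth), gq = shape(gq))
}

#' @rdname GenotypeCalls
#' @export
setMethod("variantSites", "GenotypeCalls", function(x) x@sites)

#' @rdname GenotypeCalls
#' @export
setMethod("sampleInfo", "GenotypeCalls", function(x) x@samples)

#' @rdname GenotypeCalls
#' @export
setMethod("alleleCalls", "GenotypeCalls", function(x) list(a1 = x@a1, a2 = x@a2))

#' @rdname GenotypeCalls
#' @export
setMethod("readDepth", "GenotypeCalls", function(x) x@depth)

#' @rdname GenotypeCalls
#' @export
setMethod("genoQual", "GenotypeCalls", function(x) x@gq)

#' @rdname GenotypeCalls
#' @export
setMethod("dim", "GenotypeCalls", function(x) c(length(x@sites), nrow(x@samples)))

#' @rdname GenotypeCalls
#' @param i site index (numeric/logical).
#' @param j sample index (numeric/logical/character names).
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypeCalls", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(length(x@sites))
  if (missing(j)) j <- seq_len(nrow(x@samples))
  if (is.character(j)) j <- match(j, x@samples$name)
  if (anyNA(j)) stop("unknown sample name in subset")
  new("GenotypeCalls",
      sites = x@sites[i],
      samples = x@samples[j, , drop = FALSE],
      a1 = x@a1[i, j, drop = FALSE],
      a2 = x@a2[i, j, drop = FALSE],
      depth = x@depth[i, j, drop = FALSE],
      gq = x@gq[i, j, drop = FALSE])
})

setMethod("show", "GenotypeCalls", function(object) {
  d <- dim(object)
  cat("GenotypeCalls:", d[1], "site(s) x", d[2], "sample(s)\n")
  k <- table(factor(object@samples$karyotype, .KARYOTYPES))
  cat("  samples:", k["monokaryon"], "monokaryon,", k["dikaryon"], "dikaryon\n")
  ph <- table(factor(object@samples$phenotype, .PHENOTYPES))
  cat("  phenotypes: B =", ph["B"], ", AB =", ph["AB"],
      ", unknown =", ph["unknown"], "\n")
  if (d[1] > 0) {
    cat("  sites: ", as.character(GenomicRanges::seqnames(object@sites)[1]), ":",
        GenomicRanges::start(object@sites)[1], " ...\n", sep = "")
  }
})

#' Render genotype calls as VCF GT tokens
#'
#' Monokaryons yield single-allele tokens (`"1"`) unless
#' `dialect = "diploid"`, in which case they are written as homozygous
#' diploid tokens (`"1/1"`). Dikaryons always yield unphased diploid tokens
#' with alleles in ascending order. Missing calls yield `"."` / `"./."`.
#'
#' @param x a [GenotypeCalls-class].
#' @param dialect `"haploid"` (default) or `"diploid"` encoding for
#'   monokaryon samples.
#' @return character matrix of GT tokens (sites x samples).
#' @export
genotypeTokens <- function(x, dialect = c("haploid", "diploid")) {
  dialect <- match.arg(dialect)
  d <- dim(x)
  tok <- matrix(".", d[1], d[2], dimnames = list(NULL, x@samples$name))
  mono <- x@samples$karyotype == "monokaryon"
  for (j in seq_len(d[2])) {
    a1 <- x@a1[, j]; a2 <- x@a2[, j]
    if (mono[j]) {
      t <- ifelse(is.na(a1), if (dialect == "diploid") "./." else ".",
                  if (dialect == "diploid") paste0(a1, "/", a1) else as.character(a1))
    } else {
      t <- ifelse(is.na(a1), "./.", paste0(a1, "/", a2))
    }
    tok[, j] <- t
  }
  tok
}
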
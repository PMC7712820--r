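#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param scaffold scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param cdsIntervals an [IRanges::IRanges] of genomic CDS intervals
#'   (1-based inclusive). They may be given in any order; they are re-ordered
#'   into translation order for the given strand.
#' @param codingSeq the coding-strand sequence as a [Biostrings::DNAString]
#'   or character. If `reference` is supplied instead, the coding sequence is
#'   extracted from it (and reverse-complemented for minus-strand genes).
#' @param reference optional [Biostrings::DNAStringSet] reference used to
#'   derive `codingSeq`.
#' @return a [GeneModel-class] object.
#' @examples
#' gm <- GeneModel("g1", "s1", "+", IRanges::IRanges(101, 112),
#'                 codingSeq = "ATGAAACGTTAG")
#' cdsLength(gm)
#' @export
GeneModel <- function(geneId, scaffold, strand, cdsIntervals,
                      codingSeq = NULL, reference = NULL) {
  ord <- order(IRanges::start(cdsIntervals), decreasing = (strand == "-"))
  cdsIntervals <- cdsIntervals[ord]
  if (is.null(codingSeq)) {
    if (is.null(reference))
      stop("supply either codingSeq or a reference DNAStringSet")
    if (!scaffold %in% names(reference))
      stop("scaffold '", scaffold, "' not found in reference")
    chunks <- lapply(seq_along(cdsIntervals), function(i) {
      Biostrings::subseq(reference[[scaffold]],
                         IRanges::start(cdsIntervals)[i],
                         IRanges::end(cdsIntervals)[i])
    })
    # chunks are in translation order but each is genomic-strand sequence
    if (strand == "-") {
      chunks <- lapply(chunks, Biostrings::reverseComplement)
    }
    codingSeq <- do.call(Biostrings::xscat, chunks)
  }
  if (is.character(codingSeq)) codingSeq <- Biostrings::DNAString(codingSeq)
  new("GeneModel", geneId = geneId, scaffold = scaffold, strand = strand,
      cdsIntervals = cdsIntervals, codingSeq = codingSeq)
}

#' @rdname GeneModel
#' @export
setMethod("codingSeq", "GeneModel", function(x) x@codingSeq)

#' @rdname GeneModel
#' @export
setMethod("cdsIntervals", "GeneModel", function(x) x@cdsIntervals)

#' @rdname GeneModel
#' @export
setMethod("cdsLength", "GeneModel", function(x) sum(IRanges::width(x@cdsIntervals)))

#' @describeIn GeneModel gene identifier accessor.
#' @export
geneId <- function(x) x@geneId

#' @describeIn GeneModel scaffold accessor.
#' @export
geneScaffold <- function(x) x@scaffold

#' @describeIn GeneModel strand accessor.
#' @export
geneStrand <- function(x) x@strand

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@geneId, "on", object@scaffold,
      paste0("(", object@strand, ")"), "\n")
  cat("  CDS:", length(object@cdsIntervals), "interval(s),",
      cdsLength(object), "bp,",
      cdsLength(object) %/% 3L, "codons\n")
})

#' Read a gene model from GFF3 + FASTA
#'
#' Collects the `CDS` features of one gene from a GFF3 file and derives the
#' coding sequence from the reference FASTA. The strand is taken from the CDS
#' features, which must agree.
#'
#' @param gff3 path to a GFF3 file with CDS features.
#' @param fasta path to the reference FASTA.
#' @param gene optional gene identifier to select when the GFF3 holds several
#'   genes (matched against the CDS `Parent`/`ID` attributes).
#' @return a [GeneModel-class].
#' @export
readGeneModelGFF3 <- function(gff3, fasta, gene = NULL) {
  gr <- rtracklayer::import(gff3)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", gff3)
  parent <- as.character(if (!is.null(cds$Parent)) unlist(cds$Parent) else cds$ID)
  if (!is.null(gene)) {
    keep <- parent == gene | grepl(gene, parent, fixed = TRUE)
    if (!any(keep)) stop("gene '", gene, "' not found in ", gff3)
    cds <- cds[keep]
    parent <- parent[keep]
  } else if (length(unique(parent)) > 1L) {
    stop("GFF3 holds multiple genes; pass `gene=` to select one")
  }
  strand <- unique(as.character(GenomicRanges::strand(cds)))
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("CDS features must share a single +/- strand")
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  GeneModel(geneId = unique(parent)[1],
            scaffold = as.character(GenomicRanges::seqnames(cds))[1],
            strand = strand,
            cdsIntervals = IRanges::IRanges(GenomicRanges::start(cds),
                                            GenomicRanges::end(cds)),
            reference = ref)
}

#' Write a gene model as GFF3
#'
#' @param gene a [GeneModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelGFF3 <- function(gene, path) {
  iv <- gene@cdsIntervals
  gr <- GenomicRanges::GRanges(
    seqnames = gene@scaffold,
    ranges = IRanges::IRanges(sort(IRanges::start(iv)),
                              sort(IRanges::end(iv))),
    strand = gene@strand
  )
  n <- length(gr)
  gene_row <- GenomicRanges::GRanges(
    seqnames = gene@scaffold,
    ranges = IRanges::IRanges(min(IRanges::start(iv)), max(IRanges::end(iv))),
    strand = gene@strand
  )
  gene_row$type <- "gene"
  gene_row$ID <- gene@geneId
  gene_row$Parent <- NA_character_
  gr$type <- "CDS"
  gr$ID <- paste0(gene@geneId, ".cds", seq_len(n))
  gr$Parent <- gene@geneId
  # phase: bases to skip at the start of each interval, in translation order
  w <- IRanges::width(iv)
  phase_tr <- (3L - c(0L, cumsum(w))[seq_along(w)] %% 3L) %% 3L
  gene_row$phase <- NA_integer_
  gr$phase <- phase_tr[match(IRanges::start(gr), IRanges::start(iv))]
  out <- c(gene_row, gr)
  out$source <- "dikaryoMap"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
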
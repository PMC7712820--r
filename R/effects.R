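.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp1 <- function(base) unname(.COMPLEMENT[base])

#' Map a genomic position into CDS coordinates
#'
#' CDS positions are 1-based along the coding strand of the concatenated
#' coding sequence: for a plus-strand gene position 1 is the first genomic
#' base of the first interval; for a minus-strand gene it is the *last*
#' genomic base of the first (translation-order) interval. Positions outside
#' the CDS — including positions on another scaffold — map to `NA`
#' (noncoding), never an error.
#'
#' @param gene a [GeneModel-class].
#' @param scaffold scaffold of the query position(s).
#' @param position 1-based genomic position(s).
#' @return integer vector of CDS positions (`NA` = noncoding).
#' @seealso [cdsToGenomic()] for the inverse.
#' @export
genomicToCds <- function(gene, scaffold, position) {
  position <- as.integer(position)
  n <- length(position)
  scaffold <- rep_len(scaffold, n)
  out <- rep(NA_integer_, n)
  on_scaf <- scaffold == gene@scaffold
  if (!any(on_scaf)) return(out)
  iv <- gene@cdsIntervals
  st <- IRanges::start(iv); en <- IRanges::end(iv); w <- IRanges::width(iv)
  offset <- c(0L, cumsum(w))[seq_along(w)]
  for (k in seq_along(iv)) {
    inside <- on_scaf & position >= st[k] & position <= en[k]
    if (!any(inside)) next
    within <- if (gene@strand == "+") position[inside] - st[k] + 1L
              else en[k] - position[inside] + 1L
    out[inside] <- offset[k] + within
  }
  out
}

#' Map a CDS position back to genomic coordinates
#'
#' Inverse of [genomicToCds()].
#'
#' @param gene a [GeneModel-class].
#' @param cds_position 1-based CDS position(s).
#' @return integer vector of genomic positions.
#' @export
cdsToGenomic <- function(gene, cds_position) {
  cds_position <- as.integer(cds_position)
  total <- cdsLength(gene)
  if (anyNA(cds_position) || any(cds_position < 1L | cds_position > total))
    stop("cds_position out of range 1..", total)
  iv <- gene@cdsIntervals
  st <- IRanges::start(iv); en <- IRanges::end(iv); w <- IRanges::width(iv)
  offset <- c(0L, cumsum(w))
  # interval index k such that offset[k] < cds_position <= offset[k+1]
  k <- vapply(cds_position, function(p)
    which(p > offset[-length(offset)] & p <= offset[-1])[1], integer(1))
  within <- cds_position - offset[k]
  if (gene@strand == "+") st[k] + within - 1L else en[k] - within + 1L
}

#' Classify the coding effect of a SNP against a gene model
#'
#' Substitutes the (strand-adjusted) alternate base at the SNP's CDS
#' position, translates the affected codon with the standard genetic code,
#' and classifies the substitution: `synonymous` (amino acids equal —
#' including a stop codon replaced by another stop), `nonsense` (alternate
#' codon is a stop where the reference is not), `stop_loss` (reference codon
#' is the stop, alternate is not), `start_loss` (codon 1 no longer ATG), else
#' `missense`. Each SNP is classified independently against the reference
#' coding sequence; co-occurring SNPs in the same codon are *not* combined.
#' Noncoding positions return effect `noncoding` with empty codon fields.
#'
#' @param gene a [GeneModel-class].
#' @param scaffold,position genomic location of the SNP.
#' @param ref,alt reference and alternate bases *on the genomic plus strand*
#'   (as in a VCF record). They are complemented internally for
#'   minus-strand genes.
#' @return a one-row data.frame with columns `scaffold`, `position`,
#'   `ref`, `alt`, `cds_position`, `codon_number`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `effect`, `label`.
#' @examples
#' gm <- GeneModel("g", "s1", "+", IRanges::IRanges(1, 12),
#'                 codingSeq = "ATGAAACGTTAG")
#' classifyEffect(gm, "s1", 4, "A", "C")$effect  # missense (Lys -> Gln)
#' @export
classifyEffect <- function(gene, scaffold, position, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("classifyEffect handles single-nucleotide substitutions only")
  if (ref == alt) stop("alt allele equals ref allele")
  cds_pos <- genomicToCds(gene, scaffold, position)
  row <- data.frame(scaffold = scaffold, position = as.integer(position),
                    ref = ref, alt = alt,
                    cds_position = cds_pos, codon_number = NA_integer_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    effect = "noncoding", label = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.na(cds_pos)) return(row)
  minus <- gene@strand == "-"
  ref_c <- if (minus) .revcomp1(ref) else ref
  alt_c <- if (minus) .revcomp1(alt) else alt
  cds <- as.character(gene@codingSeq)
  if (substr(cds, cds_pos, cds_pos) != ref_c)
    stop("reference allele mismatch: gene model has ",
         substr(cds, cds_pos, cds_pos), " at CDS position ", cds_pos,
         " but ref (coding strand) is ", ref_c)
  codon_number <- (cds_pos - 1L) %/% 3L + 1L
  cstart <- 3L * (codon_number - 1L) + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - cstart + 1L, cds_pos - cstart + 1L) <- alt_c
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  effect <-
    if (ref_aa == alt_aa) "synonymous"
    else if (codon_number == 1L && alt_codon != "ATG") "start_loss"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  row$cds_position <- cds_pos
  row$codon_number <- codon_number
  row$ref_codon <- ref_codon
  row$alt_codon <- alt_codon
  row$ref_aa <- ref_aa
  row$alt_aa <- alt_aa
  row$effect <- effect
  row$label <- sprintf("%d %s > %s", cds_pos, ref_c, alt_c)
  row
}

#' Render the coding-position name of a classified SNP
#'
#' Labels follow the `"612 C > A"` convention: CDS position, then reference
#' and alternate bases on the coding strand.
#'
#' @param effect a one-row data.frame from [classifyEffect()].
#' @return the label string.
#' @export
nameVariant <- function(effect) {
  if (is.na(effect$cds_position) || effect$effect == "noncoding")
    stop("cannot name a noncoding variant")
  effect$label
}

#' Classify coding effects for a table of SNP sites
#'
#' Vectorized driver over [classifyEffect()]. Multi-allelic records yield one
#' row per alternate allele.
#'
#' @param gene a [GeneModel-class].
#' @param sites a [GenomicRanges::GRanges] with `ref`/`alt` mcols (as in
#'   [variantSites()]) or a data.frame with `scaffold`, `position`, `ref`,
#'   `alt` columns.
#' @return data.frame of effect calls, one row per (site, alt allele).
#' @export
annotateEffects <- function(gene, sites) {
  if (is(sites, "GRanges")) {
    df <- data.frame(scaffold = as.character(GenomicRanges::seqnames(sites)),
                     position = GenomicRanges::start(sites),
                     ref = S4Vectors::mcols(sites)$ref,
                     stringsAsFactors = FALSE)
    alt <- S4Vectors::mcols(sites)$alt
    alt <- lapply(alt, as.character)
  } else {
    df <- sites[, c("scaffold", "position", "ref")]
    alt <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    for (a in alt[[i]]) {
      rows[[length(rows) + 1L]] <-
        classifyEffect(gene, df$scaffold[i], df$position[i], df$ref[i], a)
    }
  }
  if (!length(rows)) {
    return(classifyEffect(GeneModel("g", "s", "+", IRanges::IRanges(1, 3),
                                    codingSeq = "ATG"), "s", 1, "A", "G")[0, ])
  }
  do.call(rbind, rows)
}
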
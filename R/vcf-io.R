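#' Read a VCF into the karyotype-aware genotype model
#'
#' Parses a VCF 4.2 file (plain or gzip) with `vcfR` and interprets each GT
#' token under the sample's karyotype from the sample sheet:
#'
#' * monokaryon: a separator-free token (`"1"`) is a one-allele call; a
#'   homozygous diploid token (`"1/1"`) is collapsed to one allele; a
#'   heterozygous diploid token is a genotype-model violation and raises an
#'   error.
#' * dikaryon: `"/"`- or `"|"`-separated tokens yield two unordered alleles
#'   (`"1/0"` and `"0/1"` parse identically; phasing is ignored). A
#'   separator-free token on a dikaryon is rejected.
#' * any token containing `"."` is a missing call.
#'
#' DP and GQ are recorded per call when present and left `NA` when absent —
#' they are never imputed. Multi-allelic records are parsed intact (rejected
#' later, auditable, by [applyFilters()]).
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @param samples sample metadata from [readSampleSheet()]; every sheet
#'   sample must be present in the VCF header, and genotype columns are
#'   returned in sheet order.
#' @return a [GenotypeCalls-class].
#' @export
readGenotypeVcf <- function(path, samples) {
  samples <- S4Vectors::DataFrame(as.data.frame(samples))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  vcf_samples <- colnames(gt)[-1]
  absent <- setdiff(samples$name, vcf_samples)
  if (length(absent))
    stop("sample(s) in sheet but not in VCF: ", paste(absent, collapse = ", "))
  ns <- nrow(fix)
  if (is.null(ns)) ns <- 0L
  sites <- GenomicRanges::GRanges(
    seqnames = if (ns) fix[, "CHROM"] else character(),
    ranges = IRanges::IRanges(start = if (ns) as.integer(fix[, "POS"]) else integer(),
                              width = 1)
  )
  alt_raw <- if (ns) fix[, "ALT"] else character()
  alt_raw[is.na(alt_raw)] <- ""
  S4Vectors::mcols(sites)$ref <- if (ns) fix[, "REF"] else character()
  S4Vectors::mcols(sites)$alt <- IRanges::CharacterList(strsplit(alt_raw, ",", fixed = TRUE))

  nk <- nrow(samples)
  a1 <- a2 <- dp <- gq <- matrix(NA_integer_, ns, nk)
  colnames(a1) <- colnames(a2) <- colnames(dp) <- colnames(gq) <- samples$name
  if (ns > 0) {
    fmt_keys <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
    nalt <- lengths(S4Vectors::mcols(sites)$alt)
    for (j in seq_len(nk)) {
      col <- gt[, samples$name[j]]
      karyo <- samples$karyotype[j]
      toks <- strsplit(ifelse(is.na(col), ".", col), ":", fixed = TRUE)
      for (i in seq_len(ns)) {
        keys <- fmt_keys[[i]]
        vals <- toks[[i]]
        g <- vals[match("GT", keys)]
        di <- match("DP", keys); qi <- match("GQ", keys)
        if (!is.na(di) && di <= length(vals) && vals[di] != ".")
          dp[i, j] <- as.integer(vals[di])
        if (!is.na(qi) && qi <= length(vals) && vals[qi] != ".")
          gq[i, j] <- as.integer(vals[qi])
        if (is.na(g) || grepl(".", g, fixed = TRUE)) next # missing call
        parts <- strsplit(g, "[/|]")[[1]]
        al <- suppressWarnings(as.integer(parts))
        if (anyNA(al))
          stop("unparseable GT token '", g, "' for sample ", samples$name[j],
               " at ", fix[i, "CHROM"], ":", fix[i, "POS"])
        if (any(al < 0L | al > nalt[i]))
          stop("allele index out of range in GT '", g, "' for sample ",
               samples$name[j], " at ", fix[i, "CHROM"], ":", fix[i, "POS"])
        if (karyo == "monokaryon") {
          if (length(al) == 1L) {
            a1[i, j] <- al
          } else if (length(al) == 2L && al[1] == al[2]) {
            a1[i, j] <- al[1] # diploid-homozygous dialect, collapsed
          } else {
            stop("heterozygous diploid genotype '", g,
                 "' on monokaryon sample ", samples$name[j], " at ",
                 fix[i, "CHROM"], ":", fix[i, "POS"],
                 ": genotype-model violation")
          }
        } else {
          if (length(al) != 2L)
            stop("expected a diploid genotype for dikaryon sample ",
                 samples$name[j], " at ", fix[i, "CHROM"], ":", fix[i, "POS"],
                 ", got '", g, "'")
          a1[i, j] <- min(al); a2[i, j] <- max(al)
        }
      }
    }
  }
  GenotypeCalls(sites, samples, a1, a2, dp, gq)
}

#' Write genotype calls as VCF 4.2
#'
#' Emits one genotype column per sample. Monokaryons are written as haploid
#' single-allele genotypes by default (`dialect = "haploid"`), or as
#' homozygous diploid genotypes (`dialect = "diploid"`) for tools that do not
#' accept mixed ploidy. Dikaryons are written as unphased diploid genotypes
#' with alleles in ascending order. DP/GQ FORMAT fields are included only if
#' any call carries a value; `NA` values are written as `"."`. The output is
#' deterministic (no timestamps), so identical inputs give byte-identical
#' files, and `readGenotypeVcf(writeGenotypeVcf(x))` reproduces `x` exactly.
#'
#' @param x a [GenotypeCalls-class].
#' @param path output path (a `.gz` suffix writes gzip).
#' @param dialect monokaryon encoding, `"haploid"` or `"diploid"`.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(x, path, dialect = c("haploid", "diploid")) {
  dialect <- match.arg(dialect)
  d <- dim(x)
  sites <- x@sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dikaryoMap",
    paste0("##contig=<ID=", unique(as.character(GenomicRanges::seqnames(sites))), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  has_dp <- any(!is.na(x@depth)); has_gq <- any(!is.na(x@gq))
  if (has_dp) header <- c(header,
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (has_gq) header <- c(header,
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Phred-scaled genotype quality">')
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", x@samples$name),
                            collapse = "\t"))
  lines <- header
  if (d[1] > 0) {
    fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
    tok <- genotypeTokens(x, dialect)
    cell <- tok
    if (has_dp) {
      dpc <- ifelse(is.na(x@depth), ".", as.character(x@depth))
      cell <- matrix(paste(cell, dpc, sep = ":"), d[1], d[2])
    }
    if (has_gq) {
      gqc <- ifelse(is.na(x@gq), ".", as.character(x@gq))
      cell <- matrix(paste(cell, gqc, sep = ":"), d[1], d[2])
    }
    alt <- vapply(S4Vectors::mcols(sites)$alt, function(a)
      if (length(a)) paste(a, collapse = ",") else ".", character(1))
    body <- paste(
      as.character(GenomicRanges::seqnames(sites)),
      GenomicRanges::start(sites), ".",
      S4Vectors::mcols(sites)$ref, alt, ".", ".", ".", fmt,
      sep = "\t")
    body <- paste(body, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
    lines <- c(lines, body)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
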
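#' Classify a genotype call under the dominance model
#'
#' Maps an allele call onto the dominance genotype classes used in
#' mono-/dikaryotic trait mapping: `DOM` ("A": a monokaryon carrying the
#' dominant-associated allele, or a dikaryon with two copies), `HET`
#' ("A + a": a dikaryon with exactly one copy), `REC` ("a" / "a + a": no
#' copy), and `MISSING`.
#'
#' @param alleles integer vector of allele indices: length 1 for a
#'   monokaryon, length 2 for a dikaryon; `NA` for a missing call.
#' @param dominant_allele the allele index treated as dominant-associated.
#' @param karyotype `"monokaryon"` or `"dikaryon"`.
#' @return one of `"DOM"`, `"HET"`, `"REC"`, `"MISSING"`.
#' @examples
#' classifyGenotype(c(0, 1), 1, "dikaryon")   # "HET" ("A + a")
#' classifyGenotype(0, 1, "monokaryon")       # "REC"
#' @export
classifyGenotype <- function(alleles, dominant_allele, karyotype) {
  karyotype <- match.arg(karyotype, .KARYOTYPES)
  if (length(dominant_allele) != 1L || is.na(dominant_allele) || dominant_allele < 0)
    stop("dominant_allele must be a single non-negative allele index")
  if (all(is.na(alleles))) return("MISSING")
  if (anyNA(alleles)) stop("partially missing allele call")
  n_expected <- if (karyotype == "monokaryon") 1L else 2L
  if (length(alleles) != n_expected)
    stop("expected ", n_expected, " allele(s) for a ", karyotype, " call")
  ndom <- sum(alleles == dominant_allele)
  if (karyotype == "monokaryon") {
    if (ndom == 1L) "DOM" else "REC"
  } else {
    c("REC", "HET", "DOM")[ndom + 1L]
  }
}

# vectorized class matrix (sites x samples); dominant is a per-site vector
.classMatrix <- function(x, dominant) {
  d <- dim(x)
  cls <- matrix(NA_character_, d[1], d[2], dimnames = list(NULL, x@samples$name))
  mono <- x@samples$karyotype == "monokaryon"
  for (j in seq_len(d[2])) {
    a1 <- x@a1[, j]; a2 <- x@a2[, j]
    miss <- is.na(a1)
    if (mono[j]) {
      cj <- ifelse(a1 == dominant, "DOM", "REC")
    } else {
      ndom <- (a1 == dominant) + (a2 == dominant)
      cj <- c("REC", "HET", "DOM")[ndom + 1L]
    }
    cj[miss | is.na(dominant)] <- "MISSING"
    cls[, j] <- cj
  }
  cls
}

#' Render genotype classes in field notation
#'
#' `DOM` becomes `"A"`, `HET` becomes `"A+a"`, `REC` becomes `"a"` for a
#' monokaryon and `"a+a"` for a dikaryon, `MISSING` becomes `"."`.
#'
#' @param class character vector of classes (`DOM`/`HET`/`REC`/`MISSING`).
#' @param karyotype matching karyotype vector (recycled).
#' @return character vector in "A"/"a" notation.
#' @export
formatGenotypeClass <- function(class, karyotype) {
  karyotype <- rep_len(karyotype, length(class))
  out <- rep(".", length(class))
  out[class == "DOM"] <- "A"
  out[class == "HET"] <- "A+a"
  out[class == "REC"] <- ifelse(karyotype[class == "REC"] == "dikaryon", "a+a", "a")
  out
}

# compatibility of one genotype class with one phenotype under dominance
.compatible <- function(class, phenotype) {
  (phenotype == "AB" & class %in% c("DOM", "HET")) |
    (phenotype == "B" & class == "REC")
}

#' Genotype-phenotype co-segregation at one site
#'
#' A phenotyped sample is *compatible* with a site iff its dominance
#' genotype class matches its phenotype: abnormal-browning (AB) samples must
#' be `DOM` or `HET`, normal-browning (B) samples must be `REC`. The site
#' passes iff every sample is compatible and none is missing.
#'
#' @param classes character vector of genotype classes, one per sample.
#' @param phenotypes matching phenotype vector (`"B"`/`"AB"`; `"unknown"` is
#'   an error here — use [panelConcordance()] for scoring with unknowns).
#' @return list with `pass` (logical), `score` (fraction of phenotyped
#'   samples compatible; missing counts as incompatible), and `compatible`
#'   (per-sample logical).
#' @export
cosegregationPass <- function(classes, phenotypes) {
  if (length(classes) != length(phenotypes))
    stop("classes and phenotypes must have equal length")
  if (any(!phenotypes %in% c("B", "AB")))
    stop("every sample must have phenotype B or AB for co-segregation")
  comp <- .compatible(classes, phenotypes)
  score <- mean(comp)
  list(pass = all(comp) && !any(classes == "MISSING"),
       score = score, compatible = comp)
}

# per-site dominant allele indices under an orientation policy
.dominantAlleles <- function(x, orientation = c("founder", "alt"),
                             dominant_role = "P1") {
  orientation <- match.arg(orientation)
  ns <- dim(x)[1]
  if (orientation == "alt") {
    return(list(dominant = rep(1L, ns), skip = rep(NA_character_, ns)))
  }
  idx <- which(x@samples$role == dominant_role)
  if (length(idx) == 0L) {
    message("no sample with role '", dominant_role,
            "' genotyped; falling back to ALT-allele orientation")
    return(list(dominant = rep(1L, ns), skip = rep(NA_character_, ns)))
  }
  if (length(idx) > 1L)
    stop("multiple samples with role '", dominant_role, "'")
  if (x@samples$karyotype[idx] != "monokaryon")
    stop("dominant founder '", x@samples$name[idx], "' must be a monokaryon")
  dom <- x@a1[, idx]
  skip <- ifelse(is.na(dom), "dominant_founder_missing", NA_character_)
  list(dominant = dom, skip = skip)
}

#' Select variants co-segregating with the trait
#'
#' Applies [cosegregationPass()] to every site over the phenotyped samples
#' in `x`. The dominant-associated allele is oriented per site: under
#' `orientation = "founder"` (default) it is the allele carried by the
#' designated dominant founder monokaryon (role `dominant_role`); sites where
#' that founder's call is missing are skipped with a logged reason. Under
#' `orientation = "alt"` (the fallback used automatically when no founder is
#' genotyped) the first ALT allele is taken as dominant, appropriate when the
#' reference assembly is a recessive-phenotype strain.
#'
#' @param x a [GenotypeCalls-class]; all its samples take part, so subset to
#'   the discovery strains first.
#' @param orientation `"founder"` or `"alt"`.
#' @param dominant_role sample-sheet role of the dominant founder.
#' @return a data.frame, sorted by (scaffold, position), with one row per
#'   site: `scaffold`, `position`, `ref`, `alt`, `dominant_allele`,
#'   per-sample class columns (`class.<sample>` in "A"/"a" notation),
#'   `score`, `pass` (`NA` for skipped sites) and `skip` reason.
#'   Candidate sites are the rows with `pass == TRUE`.
#' @export
selectCosegregating <- function(x, orientation = c("founder", "alt"),
                                dominant_role = "P1") {
  orientation <- match.arg(orientation)
  ph <- x@samples$phenotype
  if (any(ph == "unknown"))
    stop("all samples must have phenotype B or AB; drop unknowns first")
  ori <- .dominantAlleles(x, orientation, dominant_role)
  cls <- .classMatrix(x, ori$dominant)
  comp <- matrix(FALSE, nrow(cls), ncol(cls))
  for (j in seq_len(ncol(cls)))
    comp[, j] <- .compatible(cls[, j], ph[j])
  score <- rowMeans(comp)
  pass <- score == 1 & rowSums(cls == "MISSING") == 0
  pass[!is.na(ori$skip)] <- NA
  score[!is.na(ori$skip)] <- NA
  sites <- x@sites
  notation <- cls
  for (j in seq_len(ncol(cls)))
    notation[, j] <- formatGenotypeClass(cls[, j], x@samples$karyotype[j])
  colnames(notation) <- paste0("class.", x@samples$name)
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(sites)),
    position = GenomicRanges::start(sites),
    ref = S4Vectors::mcols(sites)$ref,
    alt = vapply(S4Vectors::mcols(sites)$alt, paste, character(1), collapse = ","),
    dominant_allele = ori$dominant,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(notation, stringsAsFactors = FALSE))
  out$score <- score
  out$pass <- pass
  out$skip <- ori$skip
  out[order(out$scaffold, out$position), , drop = FALSE]
}

#' Score panel cultivars for concordance with the dominance model
#'
#' Scores every site over a validation panel of dikaryotic cultivars using
#' the same compatibility rule as [selectCosegregating()], but returns *all*
#' sites with their concordance scores so partial concordance is
#' inspectable. Missing genotype classes are excluded from the score
#' denominator. Sites reaching a perfect score are flagged trait-associated.
#'
#' @param x a [GenotypeCalls-class] of panel samples (dikaryons with
#'   phenotype `B` or `AB`).
#' @param dominant_alleles per-site dominant allele indices (e.g. carried
#'   over from the discovery orientation), or a single index recycled;
#'   default `1` (ALT allele).
#' @return data.frame ranked by score (descending), then scaffold, then
#'   position, with columns as in [selectCosegregating()] plus
#'   `n_scored`, `trait_associated`.
#' @export
panelConcordance <- function(x, dominant_alleles = 1L) {
  if (any(x@samples$karyotype != "dikaryon"))
    stop("panel samples must be dikaryons")
  ph <- x@samples$phenotype
  if (any(!ph %in% c("B", "AB")))
    stop("panel samples must have phenotype B or AB")
  ns <- dim(x)[1]
  dominant <- rep_len(as.integer(dominant_alleles), ns)
  cls <- .classMatrix(x, dominant)
  comp <- scored <- matrix(FALSE, nrow(cls), ncol(cls))
  for (j in seq_len(ncol(cls))) {
    scored[, j] <- cls[, j] != "MISSING"
    comp[, j] <- .compatible(cls[, j], ph[j])
  }
  n_scored <- rowSums(scored)
  score <- ifelse(n_scored > 0, rowSums(comp) / n_scored, NA_real_)
  sites <- x@sites
  notation <- cls
  for (j in seq_len(ncol(cls)))
    notation[, j] <- formatGenotypeClass(cls[, j], x@samples$karyotype[j])
  colnames(notation) <- paste0("class.", x@samples$name)
  out <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(sites)),
    position = GenomicRanges::start(sites),
    ref = S4Vectors::mcols(sites)$ref,
    alt = vapply(S4Vectors::mcols(sites)$alt, paste, character(1), collapse = ","),
    dominant_allele = dominant,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(notation, stringsAsFactors = FALSE))
  out$score <- score
  out$n_scored <- n_scored
  out$trait_associated <- !is.na(score) & score == 1
  out[order(-out$score, out$scaffold, out$position), , drop = FALSE]
}
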
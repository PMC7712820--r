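# Independent oracles and random fixture generators for the test suite.
# These deliberately avoid the package's own code paths: coordinate walks
# are explicit base-R loops and effect classification goes through full-CDS
# translation with Biostrings::translate.

# --- random gene models ------------------------------------------------------

random_codons <- function(n) {
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste, collapse = "")
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  c("ATG", sample(sense, n - 2, replace = TRUE), sample(c("TAA","TAG","TGA"), 1))
}

# a random (possibly multi-interval) gene model embedded in a random scaffold
random_gene_model <- function(n_codons = NULL, n_intervals = NULL,
                              strand = NULL) {
  if (is.null(n_codons)) n_codons <- sample(4:40, 1)
  if (is.null(n_intervals)) n_intervals <- sample(1:4, 1)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  cds <- paste(random_codons(n_codons), collapse = "")
  L <- nchar(cds)
  # split the CDS into n_intervals chunks
  if (n_intervals > 1) {
    cuts <- sort(sample(seq_len(L - 1), n_intervals - 1))
  } else cuts <- integer()
  lens <- diff(c(0, cuts, L))
  gaps <- sample(5:50, n_intervals)          # intergenic gaps before chunks
  scaffold_len <- sum(lens) + sum(gaps) + 20
  seq_chars <- sample(c("A","C","G","T"), scaffold_len, replace = TRUE)
  # genomic layout left-to-right; translation order depends on strand
  starts <- ends <- integer(n_intervals)
  pos <- 0
  chunk_order <- if (strand == "+") seq_len(n_intervals) else rev(seq_len(n_intervals))
  # chunk i (translation order) occupies the i-th genomic slot for "+",
  # the reverse for "-": first-translated chunk is right-most on "-" genes
  cds_chunks <- substring(cds, c(1, cumsum(lens)[-n_intervals] + 1), cumsum(lens))
  genomic_slot <- 0
  for (g in seq_len(n_intervals)) {
    tr_idx <- chunk_order[g]                 # which translation chunk is here
    chunk <- cds_chunks[tr_idx]
    if (strand == "-")
      chunk <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chunk)))
    pos <- pos + gaps[g]
    starts[tr_idx] <- pos + 1
    ends[tr_idx] <- pos + nchar(chunk)
    seq_chars[(pos + 1):(pos + nchar(chunk))] <- strsplit(chunk, "")[[1]]
    pos <- pos + nchar(chunk)
  }
  reference <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(reference) <- "scafX"
  gm <- GeneModel("gX", "scafX", strand,
                  IRanges::IRanges(starts, ends), codingSeq = cds)
  list(gene = gm, reference = reference, cds = cds,
       starts = starts, ends = ends, strand = strand)
}

# explicit coordinate walk: data.frame mapping every CDS position to its
# genomic position, from the raw interval layout (not the GeneModel)
oracle_cds_map <- function(rg) {
  ord <- order(rg$starts, decreasing = (rg$strand == "-"))
  genomic <- integer()
  for (k in ord) {
    g <- if (rg$strand == "+") seq(rg$starts[k], rg$ends[k])
         else seq(rg$ends[k], rg$starts[k])
    genomic <- c(genomic, g)
  }
  data.frame(cds = seq_along(genomic), genomic = genomic)
}

# full-CDS translation-diff classifier (standard genetic code)
oracle_classify <- function(cds, cds_pos, alt_coding) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_coding
  aa <- function(s) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE)), "")[[1]]
  p_ref <- aa(cds); p_alt <- aa(mut)
  codon <- (cds_pos - 1) %/% 3 + 1
  if (identical(p_ref, p_alt)) return("synonymous")
  if (codon == 1 && substr(mut, 1, 3) != "ATG") return("start_loss")
  if (p_alt[codon] == "*" && p_ref[codon] != "*") return("nonsense")
  if (p_ref[codon] == "*" && p_alt[codon] != "*") return("stop_loss")
  "missense"
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# --- random genotype tables --------------------------------------------------

random_samples <- function(n_mono = 2, n_dik = 2) {
  n <- n_mono + n_dik
  S4Vectors::DataFrame(
    name = sprintf("S%02d", seq_len(n)),
    karyotype = c(rep("monokaryon", n_mono), rep("dikaryon", n_dik)),
    phenotype = sample(c("B", "AB"), n, replace = TRUE),
    role = rep("strain", n))
}

# random GenotypeCalls: occasional multi-allelic sites, missing calls,
# NA depth/quality cells
random_calls <- function(n_sites = 6, n_mono = 2, n_dik = 2,
                         p_multi = 0.2, p_missing = 0.15,
                         with_dp = TRUE, with_gq = TRUE) {
  samples <- random_samples(n_mono, n_dik)
  nk <- nrow(samples)
  nalt <- ifelse(runif(n_sites) < p_multi, sample(2:3, n_sites, TRUE), 1L)
  ref <- sample(c("A", "C", "G", "T"), n_sites, TRUE)
  alt <- lapply(seq_len(n_sites), function(i)
    sample(setdiff(c("A", "C", "G", "T"), ref[i]), nalt[i]))
  sites <- GenomicRanges::GRanges("s1",
    IRanges::IRanges(sort(sample.int(10000, n_sites)), width = 1))
  S4Vectors::mcols(sites)$ref <- ref
  S4Vectors::mcols(sites)$alt <- IRanges::CharacterList(alt)
  a1 <- a2 <- matrix(NA_integer_, n_sites, nk)
  for (i in seq_len(n_sites)) for (j in seq_len(nk)) {
    if (runif(1) < p_missing) next
    if (samples$karyotype[j] == "monokaryon") {
      a1[i, j] <- sample.int(nalt[i] + 1L, 1L) - 1L
    } else {
      pair <- sort(sample.int(nalt[i] + 1L, 2L, replace = TRUE) - 1L)
      a1[i, j] <- pair[1]; a2[i, j] <- pair[2]
    }
  }
  dp <- if (with_dp) matrix(sample(c(NA, 0:80), n_sites * nk, TRUE), n_sites, nk)
  gq <- if (with_gq) matrix(sample(c(NA, 0:99), n_sites * nk, TRUE), n_sites, nk)
  GenotypeCalls(sites, samples, a1, a2, dp, gq)
}

# brute-force per-record filter re-check, first-failure reason in audit order
oracle_filter_reason <- function(x, criteria) {
  sites <- variantSites(x)
  al <- alleleCalls(x); dp <- readDepth(x); gq <- genoQual(x)
  ref <- S4Vectors::mcols(sites)$ref
  alt <- S4Vectors::mcols(sites)$alt
  vapply(seq_along(sites), function(i) {
    if (criteria$require_biallelic && length(alt[[i]]) != 1) return("not_biallelic")
    if (criteria$snps_only &&
        (nchar(ref[i]) != 1 || length(alt[[i]]) == 0 ||
         any(nchar(alt[[i]]) != 1))) return("not_snp")
    for (j in seq_len(ncol(al$a1))) {
      if (is.na(al$a1[i, j])) next
      if (criteria$min_depth > 0 &&
          (is.na(dp[i, j]) || dp[i, j] < criteria$min_depth)) return("low_depth")
    }
    for (j in seq_len(ncol(al$a1))) {
      if (is.na(al$a1[i, j])) next
      if (criteria$min_gq > 0 &&
          (is.na(gq[i, j]) || gq[i, j] < criteria$min_gq)) return("low_gq")
    }
    if (criteria$require_complete && any(is.na(al$a1[i, ]))) return("missing_call")
    NA_character_
  }, character(1))
}

# brute-force dominance compatibility of one sample
oracle_compatible <- function(class, phenotype) {
  if (phenotype == "AB") class %in% c("DOM", "HET") else class == "REC"
}

# small discovery design config used across tests (noiseless genotypes)
discovery_config <- function(seed, ...) {
  args <- list(seed = seed, n_scaffolds = 1, scaffold_length = 40000,
               gene_scaffold = 1, gene_start = 22001,
               background_snp_rate = 2e-3, n_f2_dikaryons = 0,
               n_panel_ab = 0, n_panel_b = 0, genotype_error_rate = 0)
  args[names(list(...))] <- list(...)
  do.call(pedigreeSimConfig, args)
}

discovery_roles <- c("P1", "F1", "F2", "F2self")
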
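#' Configuration for the pedigree simulator
#'
#' Describes the synthetic mapping experiment the simulator generates: a
#' random reference genome carrying one protein-coding gene, two founder
#' monokaryon haplotypes that differ at background SNPs plus planted causal
#' coding SNPs inside that gene, an F1 dikaryon, meiotic F2 spores and
#' selfed F2 dikaryons segregating the dominant trait 3:1, and a validation
#' panel of dikaryotic cultivars. Defaults mirror the discovery design this
#' pipeline targets: a 975-bp single-CDS gene carrying 5 missense + 3
#' synonymous dominant-allele SNPs, a selfed F2 cohort of 108, a 3 AB + 13 B
#' cultivar panel, and ~42x mean depth.
#'
#' All stochastic draws flow from the single `seed`; each simulation stage
#' derives its own stream from it, so identical config + seed gives
#' byte-identical outputs.
#'
#' @param n_scaffolds number of reference scaffolds.
#' @param scaffold_length length of each scaffold (bases).
#' @param background_snp_rate per-base probability that the two founders are
#'   polymorphic at a background position.
#' @param gene_scaffold scaffold (index) carrying the causal gene.
#' @param gene_start 1-based genomic start of the CDS.
#' @param gene_strand `"+"` or `"-"`.
#' @param cds_length CDS length in bases (multiple of 3).
#' @param n_causal_missense,n_causal_synonymous planted causal coding SNPs
#'   of each effect class, all carried by the dominant founder.
#' @param block_flank half-width (bases) of the causal linkage block around
#'   the gene; markers inside it co-inherit with the causal allele.
#' @param n_f2_dikaryons selfed F2 dikaryons in the segregation cohort.
#' @param n_panel_ab,n_panel_b validation-panel dikaryons with (heterozygous
#'   causal block) and without the dominant block.
#' @param mean_depth mean per-call read depth (negative-binomial).
#' @param depth_dispersion negative-binomial size parameter (smaller = more
#'   over-dispersed).
#' @param genotype_error_rate probability that an emitted genotype is
#'   flipped to a random wrong genotype class.
#' @param gq_per_read,gq_cap genotype-quality model: GQ =
#'   `min(gq_cap, round(gq_per_read * depth))` Phred.
#' @param haploid_dialect monokaryon VCF encoding, `"haploid"` or
#'   `"diploid"` (see [writeGenotypeVcf()]).
#' @param seed master seed (integer).
#' @return a validated `PedigreeSimConfig` list.
#' @export
pedigreeSimConfig <- function(n_scaffolds = 3, scaffold_length = 100000,
                              background_snp_rate = 1e-3,
                              gene_scaffold = 3, gene_start = 22001,
                              gene_strand = "+", cds_length = 975,
                              n_causal_missense = 5, n_causal_synonymous = 3,
                              block_flank = 500,
                              n_f2_dikaryons = 108,
                              n_panel_ab = 3, n_panel_b = 13,
                              mean_depth = 42, depth_dispersion = 8,
                              genotype_error_rate = 0.002,
                              gq_per_read = 3, gq_cap = 99,
                              haploid_dialect = "haploid",
                              seed = 1) {
  cfg <- list(n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length),
              background_snp_rate = background_snp_rate,
              gene_scaffold = as.integer(gene_scaffold),
              gene_start = as.integer(gene_start),
              gene_strand = gene_strand,
              cds_length = as.integer(cds_length),
              n_causal_missense = as.integer(n_causal_missense),
              n_causal_synonymous = as.integer(n_causal_synonymous),
              block_flank = as.integer(block_flank),
              n_f2_dikaryons = as.integer(n_f2_dikaryons),
              n_panel_ab = as.integer(n_panel_ab),
              n_panel_b = as.integer(n_panel_b),
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              genotype_error_rate = genotype_error_rate,
              gq_per_read = gq_per_read, gq_cap = gq_cap,
              haploid_dialect = match.arg(haploid_dialect,
                                          c("haploid", "diploid")),
              seed = as.integer(seed))
  counts <- c("n_scaffolds", "scaffold_length", "cds_length",
              "n_causal_missense", "n_causal_synonymous", "block_flank",
              "n_f2_dikaryons", "n_panel_ab", "n_panel_b")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("config field '", f, "' must be a non-negative count")
  if (cfg$n_scaffolds < 1L || cfg$scaffold_length < 3L)
    stop("need at least one scaffold of length >= 3")
  for (f in c("background_snp_rate", "genotype_error_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must lie in [0, 1]")
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  if (cfg$depth_dispersion <= 0) stop("depth_dispersion must be positive")
  if (cfg$cds_length %% 3L != 0L || cfg$cds_length < 9L)
    stop("cds_length must be a multiple of 3 and >= 9")
  if (!cfg$gene_strand %in% c("+", "-")) stop("gene_strand must be '+' or '-'")
  if (cfg$gene_scaffold < 1L || cfg$gene_scaffold > cfg$n_scaffolds)
    stop("gene_scaffold out of range")
  if (cfg$gene_start < 1L ||
      cfg$gene_start + cfg$cds_length - 1L > cfg$scaffold_length)
    stop("configured CDS does not fit on its scaffold")
  structure(cfg, class = "PedigreeSimConfig")
}

.with_stream <- function(seed, offset, code) {
  withr::with_seed(seed + offset, code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate the reference genome and causal gene model
#'
#' Generates `n_scaffolds` random nucleotide sequences and plants one gene
#' whose CDS begins with ATG, ends with a stop codon, contains no internal
#' stop, and has length `cds_length` (a multiple of 3) at the configured
#' scaffold/offset/strand.
#'
#' @param config a [pedigreeSimConfig()].
#' @return list with `reference` (named [Biostrings::DNAStringSet]) and
#'   `gene` (a [GeneModel-class]).
#' @export
simulateReference <- function(config) {
  stopifnot(inherits(config, "PedigreeSimConfig"))
  .with_stream(config$seed, 0L, {
    seqs <- vapply(seq_len(config$n_scaffolds), function(i)
      paste(sample(c("A", "C", "G", "T"), config$scaffold_length,
                   replace = TRUE), collapse = ""), character(1))
    n_codons <- config$cds_length %/% 3L
    all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                    c("A","C","G","T")), 1, paste, collapse = "")
    sense <- setdiff(all_codons, .STOP_CODONS)
    cds <- paste(c("ATG",
                   sample(sense, n_codons - 2L, replace = TRUE),
                   sample(.STOP_CODONS, 1L)), collapse = "")
    genomic <- if (config$gene_strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    k <- config$gene_scaffold
    substr(seqs[k], config$gene_start,
           config$gene_start + config$cds_length - 1L) <- genomic
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- paste0("scaffold_", seq_len(config$n_scaffolds))
    gene <- GeneModel(geneId = "gene_1",
                      scaffold = names(reference)[k],
                      strand = config$gene_strand,
                      cdsIntervals = IRanges::IRanges(
                        config$gene_start,
                        config$gene_start + config$cds_length - 1L),
                      reference = reference)
    list(reference = reference, gene = gene)
  })
}

# pick one causal SNP of the requested effect class inside the CDS
.placeCausal <- function(reference, gene, target, used_cds, max_tries = 500L) {
  L <- cdsLength(gene)
  cds <- as.character(codingSeq(gene))
  minus <- geneStrand(gene) == "-"
  for (t in seq_len(max_tries)) {
    p <- sample.int(L, 1L)
    if (p %in% used_cds) next
    gpos <- cdsToGenomic(gene, p)
    ref_g <- as.character(Biostrings::subseq(reference[[geneScaffold(gene)]],
                                             gpos, gpos))
    alt_c <- sample(setdiff(c("A", "C", "G", "T"), substr(cds, p, p)), 1L)
    alt_g <- if (minus) .revcomp1(alt_c) else alt_c
    eff <- classifyEffect(gene, geneScaffold(gene), gpos, ref_g, alt_g)
    if (eff$effect == target)
      return(list(cds_pos = p, position = gpos, ref = ref_g, alt = alt_g,
                  effect = eff$effect, label = eff$label))
  }
  stop("could not place a ", target, " SNP in the CDS after ",
       max_tries, " tries (generation error)")
}

#' Simulate founder haplotypes with planted causal variants
#'
#' The recessive founder equals the reference everywhere (the reference
#' assembly plays the recessive, normal-browning background). The dominant
#' founder carries `n_causal_missense + n_causal_synonymous` alternate
#' alleles inside the gene CDS — each placement verified with
#' [classifyEffect()] — plus Bernoulli(`background_snp_rate`) background
#' differences genome-wide (the CDS itself is excluded so the planted coding
#' SNP counts stay exact).
#'
#' @param ref output of [simulateReference()].
#' @param config the same [pedigreeSimConfig()].
#' @return list of class `FounderHaplotypes`: `sites` (a
#'   [GenomicRanges::GRanges], mcols `ref`, `alt`, `causal`, `cds_pos`,
#'   `effect`; the dominant founder carries the `alt` allele at every site),
#'   `causal` (the causal subset), plus `reference` and `gene`.
#' @export
simulateFounders <- function(ref, config) {
  stopifnot(inherits(config, "PedigreeSimConfig"))
  reference <- ref$reference; gene <- ref$gene
  .with_stream(config$seed, 1L, {
    used <- integer()
    causal <- list()
    for (target in c(rep("missense", config$n_causal_missense),
                     rep("synonymous", config$n_causal_synonymous))) {
      v <- .placeCausal(reference, gene, target, used)
      used <- c(used, v$cds_pos)
      causal[[length(causal) + 1L]] <- v
    }
    cdf <- if (length(causal)) do.call(rbind, lapply(causal, as.data.frame)) else
      data.frame(cds_pos = integer(), position = integer(), ref = character(),
                 alt = character(), effect = character(), label = character())
    gene_span <- c(min(IRanges::start(cdsIntervals(gene))),
                   max(IRanges::end(cdsIntervals(gene))))
    rows <- list()
    for (k in seq_len(config$n_scaffolds)) {
      scaf <- names(reference)[k]
      hit <- which(stats::runif(config$scaffold_length) < config$background_snp_rate)
      if (scaf == geneScaffold(gene))
        hit <- hit[hit < gene_span[1] | hit > gene_span[2]]
      if (!length(hit)) next
      refb <- strsplit(as.character(reference[[k]]), "")[[1]][hit]
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = scaf, position = hit, ref = refb, alt = altb,
        causal = FALSE, cds_pos = NA_integer_, effect = NA_character_,
        stringsAsFactors = FALSE)
    }
    bg <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scaffold = character(), position = integer(),
                 ref = character(), alt = character(), causal = logical(),
                 cds_pos = integer(), effect = character())
    ca <- data.frame(scaffold = rep(geneScaffold(gene), nrow(cdf)),
                     position = cdf$position, ref = cdf$ref, alt = cdf$alt,
                     causal = rep(TRUE, nrow(cdf)), cds_pos = cdf$cds_pos,
                     effect = cdf$effect, stringsAsFactors = FALSE)
    all <- rbind(bg, ca)
    all <- all[order(all$scaffold, all$position), , drop = FALSE]
    sites <- GenomicRanges::GRanges(
      seqnames = all$scaffold,
      ranges = IRanges::IRanges(all$position, width = 1))
    S4Vectors::mcols(sites)$ref <- all$ref
    S4Vectors::mcols(sites)$alt <- IRanges::CharacterList(as.list(all$alt))
    S4Vectors::mcols(sites)$causal <- all$causal
    S4Vectors::mcols(sites)$cds_pos <- all$cds_pos
    S4Vectors::mcols(sites)$effect <- all$effect
    structure(list(sites = sites, causal = sites[all$causal],
                   reference = reference, gene = gene),
              class = "FounderHaplotypes")
  })
}

# one meiotic spore: per-block founder choice, causal block co-inherited.
# block_of: integer block index per site; causal_block: index of the causal
# block (NA if no causal sites). Returns alleles (0 = recessive/reference
# founder, 1 = dominant founder) and the causal-block indicator.
.drawSpore <- function(block_of, n_blocks, causal_block) {
  pick <- stats::rbinom(n_blocks, 1L, 0.5)
  list(alleles = pick[block_of],
       causal = if (is.na(causal_block)) 0L else pick[causal_block])
}

#' Simulate the mapping pedigree
#'
#' Emits, with genotypes at every founder-polymorphic site:
#' founder monokaryons (roles `P1` dominant/AB and `P2` recessive/B), the F1
#' dikaryon holding both founder haplotypes (AB, "A + a" at causal sites),
#' two recessive F2 spore monokaryons (role `F2`) and the dikaryon mated
#' from them (role `F2self`) — the classic 5-strain discovery design
#' together with P1 and F1 —, a selfed F2 dikaryon cohort (role `F2cohort`,
#' two independent spores each, phenotype AB iff at least one spore carries
#' the dominant causal block), and a validation panel (role `panel`) of
#' dikaryons heterozygous for the causal block (AB) or without it (B).
#'
#' Each spore inherits one founder allele per locus independently with
#' probability 1/2 (unlinked markers), except that all sites inside the
#' configured causal linkage block co-inherit as one unit. Every phenotype
#' is a deterministic function of causal-block carriage (dominance).
#'
#' @param founders output of [simulateFounders()].
#' @param config the same [pedigreeSimConfig()].
#' @return an object of class `PedigreeSim`: list with `sites`, `samples`
#'   (DataFrame), allele matrices `a1`/`a2`, `in_block` (per-site logical),
#'   `gene`, `reference`, `config`.
#' @export
simulatePedigree <- function(founders, config) {
  stopifnot(inherits(config, "PedigreeSimConfig"))
  sites <- founders$sites
  gene <- founders$gene
  ns <- length(sites)
  gene_span <- c(min(IRanges::start(cdsIntervals(gene))) - config$block_flank,
                 max(IRanges::end(cdsIntervals(gene))) + config$block_flank)
  in_block <- as.character(GenomicRanges::seqnames(sites)) == geneScaffold(gene) &
    GenomicRanges::start(sites) >= gene_span[1] &
    GenomicRanges::start(sites) <= gene_span[2]
  block_of <- integer(ns)
  block_of[in_block] <- 1L
  if (any(!in_block)) block_of[!in_block] <- 1L + seq_len(sum(!in_block))
  n_blocks <- max(block_of, 1L)
  causal_block <- if (any(in_block & S4Vectors::mcols(sites)$causal)) 1L else NA_integer_

  .with_stream(config$seed, 2L, {
    name <- karyo <- pheno <- role <- character()
    cols_a1 <- cols_a2 <- list()
    addSample <- function(nm, ka, ro, h1, h2 = NULL, dom_blocks) {
      name <<- c(name, nm); karyo <<- c(karyo, ka); role <<- c(role, ro)
      pheno <<- c(pheno, if (dom_blocks >= 1L) "AB" else "B")
      cols_a1[[length(cols_a1) + 1L]] <<- h1
      cols_a2[[length(cols_a2) + 1L]] <<- if (is.null(h2)) rep(NA_integer_, ns) else h2
    }
    dom_hap <- rep(1L, ns); rec_hap <- rep(0L, ns)
    has_causal <- !is.na(causal_block)
    addSample("P1", "monokaryon", "P1", dom_hap, dom_blocks = as.integer(has_causal))
    addSample("P2", "monokaryon", "P2", rec_hap, dom_blocks = 0L)
    addSample("F1", "dikaryon", "F1", rec_hap, dom_hap, dom_blocks = as.integer(has_causal))
    # two recessive F2 spores + their mated dikaryon (discovery strains)
    recSpore <- function() {
      for (t in 1:64) {
        s <- .drawSpore(block_of, n_blocks, causal_block)
        if (s$causal == 0L) return(s)
      }
      stop("failed to draw a recessive spore")
    }
    s1 <- recSpore(); s2 <- recSpore()
    addSample("F2-1", "monokaryon", "F2", s1$alleles, dom_blocks = 0L)
    addSample("F2-2", "monokaryon", "F2", s2$alleles, dom_blocks = 0L)
    addSample("F2self", "dikaryon", "F2self",
              pmin(s1$alleles, s2$alleles), pmax(s1$alleles, s2$alleles),
              dom_blocks = 0L)
    if (config$n_f2_dikaryons > 0) {
      for (i in seq_len(config$n_f2_dikaryons)) {
        sa <- .drawSpore(block_of, n_blocks, causal_block)
        sb <- .drawSpore(block_of, n_blocks, causal_block)
        addSample(sprintf("F2d-%04d", i), "dikaryon", "F2cohort",
                  pmin(sa$alleles, sb$alleles), pmax(sa$alleles, sb$alleles),
                  dom_blocks = sa$causal + sb$causal)
      }
    }
    panelHap <- function(force_causal) {
      s <- .drawSpore(block_of, n_blocks, causal_block)
      a <- s$alleles
      a[in_block] <- force_causal
      a
    }
    for (i in seq_len(config$n_panel_ab)) {
      h1 <- panelHap(1L); h2 <- panelHap(0L)
      addSample(sprintf("PanelAB-%02d", i), "dikaryon", "panel",
                pmin(h1, h2), pmax(h1, h2), dom_blocks = as.integer(has_causal))
    }
    for (i in seq_len(config$n_panel_b)) {
      h1 <- panelHap(0L); h2 <- panelHap(0L)
      addSample(sprintf("PanelB-%02d", i), "dikaryon", "panel",
                pmin(h1, h2), pmax(h1, h2), dom_blocks = 0L)
    }
    a1 <- do.call(cbind, cols_a1); a2 <- do.call(cbind, cols_a2)
    if (ns == 0L) { a1 <- matrix(NA_integer_, 0, length(name)); a2 <- a1 }
    colnames(a1) <- colnames(a2) <- name
    samples <- S4Vectors::DataFrame(name = name, karyotype = karyo,
                                    phenotype = pheno, role = role)
    structure(list(sites = sites, samples = samples, a1 = a1, a2 = a2,
                   in_block = in_block, gene = gene,
                   reference = founders$reference, config = config),
              class = "PedigreeSim")
  })
}

#' Noiseless genotype calls of a simulated pedigree
#'
#' The true simulated genotypes as a [GenotypeCalls-class], without depth or
#' quality noise (DP/GQ absent).
#'
#' @param sim a `PedigreeSim` from [simulatePedigree()].
#' @return a [GenotypeCalls-class].
#' @export
pedigreeGenotypeCalls <- function(sim) {
  GenotypeCalls(sim$sites, sim$samples, sim$a1, sim$a2)
}

#' Apply depth / quality / genotype-error noise to simulated genotypes
#'
#' Per-call read depth is drawn from a negative binomial with mean
#' `mean_depth` and size `depth_dispersion`; a depth of zero makes the call
#' missing. With probability `genotype_error_rate` a call is flipped to a
#' uniformly chosen *wrong* genotype class (monokaryon: the other allele;
#' dikaryon: one of the two other unordered biallelic genotypes). GQ is
#' `min(gq_cap, round(gq_per_read * depth))`.
#'
#' @param sim a `PedigreeSim`.
#' @return a noisy [GenotypeCalls-class] with DP and GQ set.
#' @export
noisyGenotypeCalls <- function(sim) {
  config <- sim$config
  ns <- length(sim$sites); nk <- nrow(sim$samples)
  .with_stream(config$seed, 3L, {
    a1 <- sim$a1; a2 <- sim$a2
    depth <- matrix(stats::rnbinom(ns * nk, mu = config$mean_depth,
                                   size = config$depth_dispersion), ns, nk)
    gq <- pmin(config$gq_cap, round(config$gq_per_read * depth))
    err <- matrix(stats::runif(ns * nk) < config$genotype_error_rate, ns, nk)
    mono <- matrix(rep(sim$samples$karyotype == "monokaryon", each = ns), ns, nk)
    # flip erroneous monokaryon calls to the other allele
    flip <- err & mono
    a1[flip] <- 1L - a1[flip]
    # flip erroneous dikaryon calls to one of the two other genotypes
    dflip <- which(err & !mono)
    if (length(dflip)) {
      cur <- a1[dflip] + a2[dflip]           # 0, 1, 2 copies of alt
      pick <- vapply(cur, function(g) sample(setdiff(0:2, g), 1L), integer(1))
      a1[dflip] <- ifelse(pick == 2L, 1L, 0L)
      a2[dflip] <- ifelse(pick >= 1L, 1L, 0L)
    }
    missing <- depth == 0L
    a1[missing] <- NA_integer_; a2[missing] <- NA_integer_
    colnames(a1) <- colnames(a2) <- sim$samples$name
    GenotypeCalls(sim$sites, sim$samples, a1, a2, depth, gq)
  })
}

#' Write a simulated pedigree experiment to disk
#'
#' Emits the reference FASTA, gene model GFF3, (noisy) VCF 4.2 with GT/DP/GQ
#' fields, and the TSV sample sheet. With the same config + seed the VCF is
#' byte-identical across runs.
#'
#' @param sim a `PedigreeSim`.
#' @param dir output directory (created if needed).
#' @return named list of file paths, with the emitted noisy
#'   [GenotypeCalls-class] attached as attribute `"calls"`.
#' @export
writePedigreeData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "reference.fasta"),
                gff3 = file.path(dir, "genes.gff3"),
                vcf = file.path(dir, "genotypes.vcf"),
                sheet = file.path(dir, "samples.tsv"))
  Biostrings::writeXStringSet(sim$reference, paths$fasta)
  writeGeneModelGFF3(sim$gene, paths$gff3)
  calls <- noisyGenotypeCalls(sim)
  writeGenotypeVcf(calls, paths$vcf, dialect = sim$config$haploid_dialect)
  writeSampleSheet(sim$samples, paths$sheet)
  attr(paths, "calls") <- calls
  paths
}

#' Phenotype counts from selfing a heterozygous dominant dikaryon
#'
#' Draws `n` selfed F2 dikaryons using the simulator's meiotic model (two
#' independent spores, each inheriting the dominant causal block with
#' probability 1/2; dominance makes the dikaryon AB iff either spore carries
#' it) and returns the AB/B phenotype counts. This is the marginal phenotype
#' law of the full pedigree simulator, exposed for segregation-ratio
#' calibration at scale.
#'
#' @param n number of F2 dikaryons.
#' @param seed integer seed.
#' @return named integer vector `c(AB = ..., B = ...)`.
#' @export
simulateF2PhenotypeCounts <- function(n, seed = 1) {
  .with_stream(as.integer(seed), 2L, {
    sp1 <- stats::rbinom(n, 1L, 0.5)
    sp2 <- stats::rbinom(n, 1L, 0.5)
    ab <- sum(sp1 + sp2 >= 1L)
    c(AB = ab, B = n - ab)
  })
}
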
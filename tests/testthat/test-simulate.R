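test_that("config invariants are enforced", {
  expect_error(pedigreeSimConfig(background_snp_rate = 1.5), "\\[0, 1\\]")
  expect_error(pedigreeSimConfig(mean_depth = 0), "mean_depth")
  expect_error(pedigreeSimConfig(n_panel_ab = -1), "non-negative")
  expect_error(pedigreeSimConfig(cds_length = 974), "multiple of 3")
  expect_error(pedigreeSimConfig(scaffold_length = 10000, gene_start = 9500,
                                 cds_length = 975), "does not fit")
})

test_that("the simulated gene is a clean single-ORF CDS of the configured length", {
  cfg <- discovery_config(seed = 5)
  ref <- simulateReference(cfg)
  cds <- as.character(codingSeq(ref$gene))
  expect_equal(nchar(cds), 975)
  expect_equal(cdsLength(ref$gene), 975)
  expect_equal(substr(cds, 1, 3), "ATG")
  codons <- substring(cds, seq(1, 973, 3), seq(3, 975, 3))
  expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
  expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  # the gene really sits in the reference at the configured offset
  expect_equal(as.character(Biostrings::subseq(ref$reference[["scaffold_1"]],
                                               22001, 22001 + 974)), cds)
})

test_that("identical config + seed gives byte-identical outputs", {
  cfg <- discovery_config(seed = 42, n_panel_ab = 2, n_panel_b = 2,
                          n_f2_dikaryons = 4)
  run <- function() {
    sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
    d <- withr::local_tempdir()
    p <- writePedigreeData(sim, d)
    lapply(p[c("fasta", "vcf", "sheet")], readLines)
  }
  expect_identical(run(), run())
  # a different seed changes the genome
  cfg2 <- discovery_config(seed = 43)
  expect_false(identical(
    as.character(simulateReference(cfg)$reference[[1]]),
    as.character(simulateReference(cfg2)$reference[[1]])))
})

test_that("founders carry the planted coding SNPs and nothing else when rates are zero", {
  cfg <- discovery_config(seed = 9, background_snp_rate = 0)
  ref <- simulateReference(cfg)
  f <- simulateFounders(ref, cfg)
  expect_equal(length(f$sites), 8)
  expect_true(all(S4Vectors::mcols(f$sites)$causal))
  eff <- S4Vectors::mcols(f$causal)$effect
  expect_equal(sum(eff == "missense"), 5)
  expect_equal(sum(eff == "synonymous"), 3)
  # classification of each planted variant agrees with translation diffing
  cds <- as.character(codingSeq(ref$gene))
  for (i in seq_along(f$causal)) {
    v <- f$causal[i]
    p <- S4Vectors::mcols(v)$cds_pos
    alt_g <- as.character(S4Vectors::mcols(v)$alt[[1]])
    alt_c <- if (geneStrand(ref$gene) == "-") comp_base(alt_g) else alt_g
    expect_equal(S4Vectors::mcols(v)$effect, oracle_classify(cds, p, alt_c))
  }
  # fully degenerate config: founders identical to the reference
  cfg0 <- discovery_config(seed = 9, background_snp_rate = 0,
                           n_causal_missense = 0, n_causal_synonymous = 0)
  f0 <- simulateFounders(simulateReference(cfg0), cfg0)
  expect_equal(length(f0$sites), 0)
})

test_that("minus-strand genes place causal SNPs that classify correctly", {
  cfg <- discovery_config(seed = 21, background_snp_rate = 0,
                          gene_strand = "-")
  ref <- simulateReference(cfg)
  f <- simulateFounders(ref, cfg)
  eff <- S4Vectors::mcols(f$causal)$effect
  expect_equal(sum(eff == "missense"), 5)
  expect_equal(sum(eff == "synonymous"), 3)
  ann <- annotateEffects(ref$gene, f$causal)
  expect_equal(ann$effect, eff)
})

test_that("the pedigree reproduces the discovery genotype pattern at causal sites", {
  cfg <- discovery_config(seed = 33)
  sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
  causal <- which(S4Vectors::mcols(sim$sites)$causal)
  sm <- as.data.frame(sim$samples)
  idx <- function(r) which(sm$role == r)
  # (P1, spore1, spore2, F1, F2self) = (A, a, a, A+a, a+a)
  expect_true(all(sim$a1[causal, idx("P1")] == 1))
  expect_true(all(sim$a1[causal, idx("F2")] == 0))
  expect_true(all(sim$a1[causal, idx("F1")] == 0 & sim$a2[causal, idx("F1")] == 1))
  expect_true(all(sim$a1[causal, idx("F2self")] == 0 &
                  sim$a2[causal, idx("F2self")] == 0))
  # phenotype is a pure function of causal-block carriage
  carries <- vapply(seq_len(nrow(sm)), function(j) {
    h1 <- all(sim$a1[causal, j] == 1)
    h2 <- !is.na(sim$a2[causal[1], j]) && all(sim$a2[causal, j] == 1)
    h1 || h2
  }, logical(1))
  expect_equal(sm$phenotype, ifelse(carries, "AB", "B"))
})

test_that("selfed F2 cohorts segregate 3:1 and empty cohorts are allowed", {
  counts <- simulateF2PhenotypeCounts(10000, seed = 11)
  frac <- counts["AB"] / sum(counts)
  ci <- 0.75 + c(-1, 1) * qnorm(0.995) * sqrt(0.75 * 0.25 / 10000)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  cfg <- discovery_config(seed = 3, n_f2_dikaryons = 0)
  sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
  expect_false("F2cohort" %in% sim$samples$role)
  expect_equal(sort(unique(sim$samples$role)),
               sort(c("P1", "P2", "F1", "F2", "F2self")))
})

test_that("unlinked background loci segregate independently in spore pairs", {
  # P(both discovery spores carry the reference allele) = 1/4 exactly
  hits <- 0; n <- 0
  for (s in 1:150) {
    cfg <- discovery_config(seed = 1000 + s, background_snp_rate = 1e-3)
    sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
    bg <- which(!sim$in_block)
    if (!length(bg)) next
    sp <- which(sim$samples$role == "F2")
    both_ref <- sim$a1[bg, sp[1]] == 0 & sim$a1[bg, sp[2]] == 0
    hits <- hits + sum(both_ref); n <- n + length(both_ref)
  }
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(hits / n - 0.25), 3 * se)
})

test_that("depth noise matches the configured negative binomial", {
  cfg <- pedigreeSimConfig(seed = 8, n_scaffolds = 1, scaffold_length = 40000,
                           gene_scaffold = 1, background_snp_rate = 2e-3,
                           n_f2_dikaryons = 100, mean_depth = 42,
                           depth_dispersion = 8, genotype_error_rate = 0)
  sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
  calls <- noisyGenotypeCalls(sim)
  dp <- readDepth(calls)
  expect_gt(length(dp), 1e4)
  expect_lt(abs(mean(dp) - 42) / 42, 0.02)
  # over-dispersion beyond Poisson: var = mu + mu^2/size
  expect_gt(var(as.vector(dp)), 1.5 * 42)
  # GQ model: min(cap, per_read * depth)
  expect_true(all(genoQual(calls) == pmin(99, round(3 * dp))))
})

test_that("noiseless emission reproduces the true genotype classes (round trip)", {
  cfg <- discovery_config(seed = 14, n_panel_ab = 3, n_panel_b = 3,
                          mean_depth = 60, depth_dispersion = 50)
  sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
  d <- withr::local_tempdir()
  p <- writePedigreeData(sim, d)
  back <- readGenotypeVcf(p$vcf, readSampleSheet(p$sheet))
  truth <- pedigreeGenotypeCalls(sim)
  al_b <- alleleCalls(back); al_t <- alleleCalls(truth)
  # error rate is zero, so any discrepancy can only be a dropped (depth-0) call
  seen <- !is.na(al_b$a1)
  expect_true(all(al_b$a1[seen] == al_t$a1[seen]))
  expect_true(all(is.na(al_b$a2[seen]) == is.na(al_t$a2[seen])))
  expect_true(all(al_b$a2[seen & !is.na(al_t$a2)] ==
                  al_t$a2[seen & !is.na(al_t$a2)]))
  expect_gt(mean(seen), 0.99)
})

test_that("genotype errors hit roughly the configured rate and wrong classes only", {
  cfg <- pedigreeSimConfig(seed = 77, n_scaffolds = 1, scaffold_length = 40000,
                           gene_scaffold = 1, background_snp_rate = 2e-3,
                           n_f2_dikaryons = 100, genotype_error_rate = 0.05,
                           mean_depth = 60, depth_dispersion = 100)
  sim <- simulatePedigree(simulateFounders(simulateReference(cfg), cfg), cfg)
  calls <- noisyGenotypeCalls(sim)
  truth <- pedigreeGenotypeCalls(sim)
  tb <- alleleCalls(truth); nb <- alleleCalls(calls)
  seen <- !is.na(nb$a1)
  differ <- seen & (nb$a1 != tb$a1 |
                    (!is.na(tb$a2) & nb$a2 != tb$a2))
  rate <- sum(differ) / sum(seen)
  se <- sqrt(0.05 * 0.95 / sum(seen))
  expect_lt(abs(rate - 0.05), 4 * se)
})
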
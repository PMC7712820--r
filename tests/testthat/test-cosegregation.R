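test_that("genotype classes cover the full karyotype x allele-set table", {
  # hand-enumerated truth table, dominant allele = 1
  expect_equal(classifyGenotype(1, 1, "monokaryon"), "DOM")
  expect_equal(classifyGenotype(0, 1, "monokaryon"), "REC")
  expect_equal(classifyGenotype(NA, 1, "monokaryon"), "MISSING")
  expect_equal(classifyGenotype(c(1, 1), 1, "dikaryon"), "DOM")
  expect_equal(classifyGenotype(c(0, 1), 1, "dikaryon"), "HET")
  expect_equal(classifyGenotype(c(1, 0), 1, "dikaryon"), "HET") # unordered
  expect_equal(classifyGenotype(c(0, 0), 1, "dikaryon"), "REC")
  expect_equal(classifyGenotype(c(NA, NA), 1, "dikaryon"), "MISSING")
  # dominant allele may be the reference allele
  expect_equal(classifyGenotype(0, 0, "monokaryon"), "DOM")
  expect_error(classifyGenotype(c(0, 1), 1, "monokaryon"), "expected 1 allele")
  expect_error(classifyGenotype(1, NA, "monokaryon"), "dominant_allele")
})

test_that("field notation renders A / A+a / a / a+a", {
  expect_equal(formatGenotypeClass(c("DOM", "HET", "REC", "MISSING"),
                                   c("monokaryon", "dikaryon", "monokaryon",
                                     "dikaryon")),
               c("A", "A+a", "a", "."))
  expect_equal(formatGenotypeClass("REC", "dikaryon"), "a+a")
})

test_that("the five-strain discovery pattern passes and degenerate ones fail", {
  # (P1 "A" AB) (N27 "a" B) (N32 "a" B) (F1 "A+a" AB) (SJ713 "a+a" B)
  classes <- c("DOM", "REC", "REC", "HET", "REC")
  phen <- c("AB", "B", "B", "AB", "B")
  res <- cosegregationPass(classes, phen)
  expect_true(res$pass)
  expect_equal(res$score, 1)
  # all-recessive: the AB strains are incompatible
  res2 <- cosegregationPass(rep("REC", 5), phen)
  expect_false(res2$pass)
  expect_equal(res2$score, 3 / 5)
  # a missing class blocks the pass even if the rest fit
  res3 <- cosegregationPass(c("DOM", "REC", "REC", "HET", "MISSING"), phen)
  expect_false(res3$pass)
  expect_error(cosegregationPass(classes, c(phen[-5], "unknown")), "B or AB")
})

test_that("pass flags equal brute-force truth-table evaluation", {
  withr::with_seed(3, {
    for (rep in 1:2000) {
      n <- sample(3:8, 1)
      classes <- sample(c("DOM", "HET", "REC", "MISSING"), n, TRUE)
      phen <- sample(c("B", "AB"), n, TRUE)
      res <- cosegregationPass(classes, phen)
      ok <- vapply(seq_len(n), function(i)
        oracle_compatible(classes[i], phen[i]), logical(1))
      expect_equal(res$pass, all(ok) && !any(classes == "MISSING"))
      expect_equal(res$score, mean(ok))
    }
  })
})

# construct GenotypeCalls for a discovery design from class letters
calls_from_pattern <- function(pattern_by_site, samples) {
  ns <- length(pattern_by_site)
  sites <- GenomicRanges::GRanges("s1", IRanges::IRanges(seq_len(ns) * 10, width = 1))
  S4Vectors::mcols(sites)$ref <- rep("A", ns)
  S4Vectors::mcols(sites)$alt <- IRanges::CharacterList(as.list(rep("T", ns)))
  nk <- nrow(samples)
  a1 <- a2 <- matrix(NA_integer_, ns, nk)
  for (i in seq_len(ns)) for (j in seq_len(nk)) {
    g <- pattern_by_site[[i]][j]
    if (samples$karyotype[j] == "monokaryon") {
      a1[i, j] <- switch(g, A = 1L, a = 0L, NA_integer_)
    } else {
      al <- switch(g, AA = c(1L, 1L), Aa = c(0L, 1L), aa = c(0L, 0L), c(NA, NA))
      a1[i, j] <- al[1]; a2[i, j] <- al[2]
    }
  }
  GenotypeCalls(sites, samples, a1, a2)
}

disc_samples <- S4Vectors::DataFrame(
  name = c("P37-5", "N27", "N32", "CAR", "SJ713"),
  karyotype = c("monokaryon", "monokaryon", "monokaryon", "dikaryon", "dikaryon"),
  phenotype = c("AB", "B", "B", "AB", "B"),
  role = c("P1", "F2", "F2", "F1", "F2self"))

test_that("site selection orients on the dominant founder and sorts output", {
  x <- calls_from_pattern(list(
    c("A", "a", "a", "Aa", "aa"),   # discovery pattern -> pass
    c("A", "A", "a", "Aa", "aa"),   # N27 carries the dominant allele -> fail
    c("a", "a", "a", "aa", "aa")),  # monomorphic -> cannot satisfy AB strains
    disc_samples)
  res <- selectCosegregating(x)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE))
  # the founder's own allele defines "A", so P37-5 is always class A, and at
  # the monomorphic site every strain shares that allele (B strains then
  # carry the "dominant" class, which is exactly why the site fails)
  expect_equal(res$`class.P37-5`, c("A", "A", "A"))
  expect_equal(res$`class.SJ713`, c("a+a", "a+a", "A"))
  expect_equal(res$dominant_allele, c(1L, 1L, 0L))
  expect_false(is.unsorted(res$position))
  # founder-missing sites are skipped with a logged reason
  y <- calls_from_pattern(list(c(NA, "a", "a", "Aa", "aa")), disc_samples)
  ry <- selectCosegregating(y)
  expect_true(is.na(ry$pass))
  expect_equal(ry$skip, "dominant_founder_missing")
})

test_that("sample order never changes co-segregation results", {
  withr::with_seed(13, {
    x <- calls_from_pattern(list(
      c("A", "a", "a", "Aa", "aa"),
      c("a", "a", "A", "aa", "Aa"),
      c("A", "A", "a", "AA", "aa")), disc_samples)
    res <- selectCosegregating(x)
    perm <- sample(5)
    res_p <- selectCosegregating(x[, perm])
    expect_equal(res_p$pass, res$pass)
    expect_equal(res_p$score, res$score)
    expect_equal(res_p$`class.N32`, res$`class.N32`)
  })
})

test_that("panel concordance ranks sites and flags perfect scores", {
  # 16-cultivar layout: 3 AB + 13 B dikaryons; three trait sites are HET in
  # every AB cultivar and REC in every B cultivar; two decoys are HET in
  # only 1 or 2 AB cultivars
  panel <- S4Vectors::DataFrame(
    name = sprintf("CV%02d", 1:16),
    karyotype = rep("dikaryon", 16),
    phenotype = c(rep("AB", 3), rep("B", 13)),
    role = rep("panel", 16))
  site_pattern <- function(n_het_ab) {
    c(ifelse(seq_len(3) <= n_het_ab, "Aa", "aa"), rep("aa", 13))
  }
  x <- calls_from_pattern(list(
    site_pattern(3), site_pattern(3), site_pattern(3),
    site_pattern(2), site_pattern(1)), panel)
  res <- panelConcordance(x)
  expect_equal(sum(res$trait_associated), 3)
  expect_equal(res$position[res$trait_associated], c(10, 20, 30))
  expect_true(all(diff(res$score) <= 0))
  expect_equal(res$score[res$position == 40], 15 / 16)
  expect_equal(res$score[res$position == 50], 14 / 16)
  # all-REC matrix: AB cultivars incompatible everywhere, nothing flagged
  y <- calls_from_pattern(list(site_pattern(0)), panel)
  expect_equal(sum(panelConcordance(y)$trait_associated), 0)
})

test_that("panel scores equal independent per-sample recounts, missing excluded", {
  panel <- S4Vectors::DataFrame(
    name = sprintf("CV%02d", 1:8),
    karyotype = rep("dikaryon", 8),
    phenotype = sample(c(rep("AB", 3), rep("B", 5))),
    role = rep("panel", 8))
  withr::with_seed(29, {
    for (rep in 1:100) {
      pattern <- lapply(1:4, function(i)
        sample(c("AA", "Aa", "aa", "miss"), 8, TRUE))
      x <- calls_from_pattern(pattern, panel)
      res <- panelConcordance(x)
      res <- res[order(res$position), ]
      for (i in 1:4) {
        cls <- vapply(seq_len(8), function(j)
          switch(pattern[[i]][j], AA = "DOM", Aa = "HET", aa = "REC", "MISSING"),
          character(1))
        scored <- cls != "MISSING"
        comp <- vapply(seq_len(8), function(j)
          oracle_compatible(cls[j], panel$phenotype[j]), logical(1))
        want <- if (any(scored)) sum(comp[scored]) / sum(scored) else NA_real_
        expect_equal(res$score[i], want)
        expect_equal(res$n_scored[i], sum(scored))
      }
    }
  })
})

test_that("adding an incompatible sample strictly lowers a panel score", {
  base <- S4Vectors::DataFrame(
    name = c("a1", "a2", "b1", "b2"),
    karyotype = rep("dikaryon", 4),
    phenotype = c("AB", "AB", "B", "B"),
    role = rep("panel", 4))
  x <- calls_from_pattern(list(c("Aa", "Aa", "aa", "aa")), base)
  s0 <- panelConcordance(x)$score
  extra <- rbind(as.data.frame(base),
                 data.frame(name = "bad", karyotype = "dikaryon",
                            phenotype = "B", role = "panel"))
  y <- calls_from_pattern(list(c("Aa", "Aa", "aa", "aa", "Aa")),
                          S4Vectors::DataFrame(extra))
  expect_lt(panelConcordance(y)$score, s0)
  # adding a compatible one leaves a perfect score perfect
  z <- calls_from_pattern(list(c("Aa", "Aa", "aa", "aa", "aa")),
                          S4Vectors::DataFrame(extra))
  expect_equal(panelConcordance(z)$score, 1)
})
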
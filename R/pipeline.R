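#' Run the full co-segregation mapping pipeline
#'
#' Orchestrates simulate (or ingest) -> record-level filter -> dominance
#' co-segregation over the discovery strains -> coding-effect annotation ->
#' validation-panel concordance -> Mendelian segregation test, and returns a
#' machine-readable report. Deterministic given the same config and seed.
#'
#' @param config either a [pedigreeSimConfig()] (simulation mode) or a list
#'   `list(vcf =, sample_sheet =, gff3 =, fasta =)` of input paths
#'   (ingest mode; the segregation stage then needs `observed` counts in
#'   `...`).
#' @param outdir optional output directory; when given, the filtered VCF,
#'   candidate/panel TSVs and the JSON report are written there (simulation
#'   mode also writes the simulated FASTA/GFF3/VCF/sample sheet).
#' @param criteria record-level [filterCriteria()].
#' @param orientation dominant-allele orientation for
#'   [selectCosegregating()].
#' @param discovery_roles sample-sheet roles forming the discovery set.
#' @param panel_role sample-sheet role of the validation panel.
#' @param ratio expected Mendelian phenotype ratio (AB:B) for the
#'   segregation test.
#' @param observed optional named phenotype counts `c(AB=, B=)` for the
#'   segregation test; in simulation mode the default is the simulated
#'   selfed-F2 cohort's phenotype counts.
#' @return a `PipelineReport` list: `provenance` (seed, config hash, paths),
#'   `counts` (sites at each stage; non-increasing along filter ->
#'   co-segregation), `segregation`, `candidates` (per-candidate effect +
#'   concordance), `panel`, and `timestamp` (kept in its own field so the
#'   rest of the report is reproducible byte for byte).
#' @export
runPipeline <- function(config, outdir = NULL,
                        criteria = filterCriteria(),
                        orientation = c("founder", "alt"),
                        discovery_roles = c("P1", "F1", "F2", "F2self"),
                        panel_role = "panel",
                        ratio = c(AB = 3, B = 1),
                        observed = NULL) {
  orientation <- match.arg(orientation)
  stage <- "input"
  report <- tryCatch({
    if (inherits(config, "PedigreeSimConfig")) {
      ref <- simulateReference(config)
      founders <- simulateFounders(ref, config)
      sim <- simulatePedigree(founders, config)
      gene <- sim$gene
      if (!is.null(outdir)) {
        paths <- writePedigreeData(sim, outdir)
        calls <- attr(paths, "calls")
      } else {
        calls <- noisyGenotypeCalls(sim)
        paths <- list()
      }
      if (is.null(observed)) {
        cohort <- sim$samples$role == "F2cohort"
        observed <- c(AB = sum(sim$samples$phenotype[cohort] == "AB"),
                      B = sum(sim$samples$phenotype[cohort] == "B"))
      }
      provenance <- list(mode = "simulation", seed = config$seed,
                         config_hash = rlang::hash(unclass(config)),
                         paths = paths)
    } else {
      for (f in c("vcf", "sample_sheet")) {
        if (is.null(config[[f]])) stop("ingest config needs '", f, "'")
      }
      samples <- readSampleSheet(config$sample_sheet)
      calls <- readGenotypeVcf(config$vcf, samples)
      gene <- if (!is.null(config$gff3) && !is.null(config$fasta))
        readGeneModelGFF3(config$gff3, config$fasta, gene = config$gene)
      else NULL
      provenance <- list(mode = "ingest",
                         config_hash = rlang::hash(config),
                         paths = config[c("vcf", "sample_sheet", "gff3", "fasta")])
    }

    stage <- "filter"
    disc <- calls[, calls@samples$role %in% discovery_roles]
    if (dim(disc)[2] == 0L) stop("no discovery samples with roles ",
                                 paste(discovery_roles, collapse = ", "))
    filt <- applyFilters(disc, criteria)

    stage <- "cosegregation"
    coseg <- selectCosegregating(filt$passed, orientation = orientation)
    cand <- coseg[!is.na(coseg$pass) & coseg$pass, , drop = FALSE]

    stage <- "annotation"
    if (!is.null(gene) && nrow(cand) > 0) {
      eff <- annotateEffects(gene, data.frame(
        scaffold = cand$scaffold, position = cand$position,
        ref = cand$ref, alt = cand$alt))
      cand$cds_position <- eff$cds_position
      cand$effect <- eff$effect
      cand$label <- eff$label
    } else {
      cand$cds_position <- rep(NA_integer_, nrow(cand))
      cand$effect <- rep(NA_character_, nrow(cand))
      cand$label <- rep(NA_character_, nrow(cand))
    }

    stage <- "panel"
    pan_idx <- calls@samples$role == panel_role &
      calls@samples$phenotype %in% c("B", "AB")
    panel <- NULL
    trait_associated <- 0L
    if (any(pan_idx) && nrow(cand) > 0) {
      key <- paste(as.character(GenomicRanges::seqnames(calls@sites)),
                   GenomicRanges::start(calls@sites))
      keep <- key %in% paste(cand$scaffold, cand$position)
      pan_calls <- calls[keep, pan_idx]
      dom <- cand$dominant_allele[match(
        paste(as.character(GenomicRanges::seqnames(pan_calls@sites)),
              GenomicRanges::start(pan_calls@sites)),
        paste(cand$scaffold, cand$position))]
      panel <- panelConcordance(pan_calls, dom)
      trait_associated <- sum(panel$trait_associated)
    }

    stage <- "segregation"
    seg <- NULL
    if (!is.null(observed) && sum(observed) > 0) {
      seg <- chiSquareSegregation(observed, ratio)
    }

    effects_tab <- table(factor(cand$effect,
                                levels = c("synonymous", "missense",
                                           "nonsense", "stop_loss",
                                           "start_loss", "noncoding")))
    counts <- list(
      sites_in = dim(disc)[1],
      sites_after_filter = dim(filt$passed)[1],
      cosegregating = nrow(cand),
      coding = if (nrow(cand)) sum(!is.na(cand$cds_position)) else 0L,
      by_effect = as.list(effects_tab),
      trait_associated = trait_associated)

    list(provenance = provenance,
         counts = counts,
         filter = list(criteria = unclass(criteria),
                       rejected = filt$rejected),
         orientation = orientation,
         candidates = cand,
         panel = panel,
         segregation = if (is.null(seg)) NULL else
           list(observed = as.list(observed),
                ratio = as.list(ratio),
                chi2 = seg@chi2, df = seg@df, p = seg@p),
         timestamp = format(Sys.time(), tz = "UTC"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$candidates,
                       file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$panel))
      utils::write.table(report$panel, file.path(outdir, "panel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report
    json$candidates <- NULL; json$panel <- NULL
    json$schema_version <- "1.0"
    jsonlite::write_json(json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    report$provenance$paths$report <- file.path(outdir, "report.json")
  }
  report
}
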
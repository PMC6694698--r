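# End-to-end pipeline driver over a cohort directory (as produced by
# generateCohort(), or any bundle following the same file layout).

.pipelineDefaults <- function() {
  list(tumorSample = "TUMOR", germlineSample = "NORMAL",
       vcfGatk = "gatk.vcf", vcfMutect = "mutect.vcf",
       vcfVarscan = "varscan.vcf",
       gff = "annotation.gff3", genome = "genome.fa", seqType = "genome",
       expression = "expression.tsv", ligands = "ligands.tsv",
       pwmDir = "pwm", hla = "hla.tsv", drivers = "drivers.tsv",
       identifiedPeptides = "identified_peptides.tsv",
       tissue = "pancreas", tpmThreshold = 1, rankCutoff = 5,
       strictCutoff = TRUE, hypermutatedK = 3, underrepThreshold = 0,
       topN = 10, includeIndels = FALSE, decoyN = 100000L,
       decoySeed = 20240001L, verbose = FALSE)
}

#' Run the full prioritization pipeline on a cohort directory
#'
#' Executes every stage in order: caller VCF parsing, consensus merging and
#' majority-rule conflict resolution, somatic/germline classification,
#' phased linked-SNP attachment, high-confidence selection, effect
#' annotation, mutant context construction, candidate enumeration for both
#' HLA classes, PWM scoring with decoy calibration, wild-type identity
#' filtering, binder calls against the percentile-rank cutoff and the
#' ligand database, expression / hypermutated-gene / representation
#' filters, hotspot-overlap classification, long peptide design, ranking
#' and top-N reporting. The customized proteome and (when an
#' identified-peptides file is present) observed-peptide flags are produced
#' alongside.
#'
#' @param dir input directory; a `config.yaml` inside it overrides the
#'   defaults, and the `config` argument overrides both.
#' @param config named list of overrides (see the pipeline defaults in the
#'   source for the full set: cutoffs, thresholds, file names, decoy
#'   calibration settings).
#' @param outDir optional output directory for `variants.tsv`,
#'   `proteome.fa`, `report.tsv`.
#' @return list with elements `consensus`, `highConfidence`, `effects`,
#'   `contexts`, `candidates`, `scores`, `binders`, `mutations` (the
#'   filtered mutation table), `designs`, `report`, `proteome`,
#'   `observedPeptides`, `config`.
#' @export
runPipeline <- function(dir, config = list(), outDir = NULL) {
  cfg <- .pipelineDefaults()
  yamlPath <- file.path(dir, "config.yaml")
  if (file.exists(yamlPath)) cfg[names(read_yaml(yamlPath))] <- read_yaml(yamlPath)
  cfg[names(config)] <- config
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  p <- function(f) file.path(dir, f)

  callsets <- list(
    readCallerVcf(p(cfg$vcfGatk), "gatk", cfg$tumorSample, cfg$germlineSample),
    readCallerVcf(p(cfg$vcfMutect), "mutect", cfg$tumorSample, cfg$germlineSample),
    readCallerVcf(p(cfg$vcfVarscan), "varscan", cfg$tumorSample, cfg$germlineSample))
  cons <- mergeCallSets(callsets)
  say("consensus variants: ", length(cons))
  cons <- suppressWarnings(classifyOrigin(cons))
  cons <- linkPhasedSnps(cons)
  hc <- selectHighConfidence(cons)
  say("high-confidence variants: ", length(hc))

  txset <- loadTranscripts(p(cfg$gff), p(cfg$genome), seqType = cfg$seqType)
  effects <- suppressWarnings(annotateEffects(hc, txset))
  contexts <- suppressWarnings(
    buildContexts(effects, txset, hc, includeIndels = cfg$includeIndels))
  say("mutant contexts: ", nrow(contexts))

  candidates <- rbind(
    suppressWarnings(enumerateCandidates(contexts, "I")),
    suppressWarnings(enumerateCandidates(contexts, "II")))
  hla <- read.delim(p(cfg$hla), stringsAsFactors = FALSE)
  models <- readPwmModels(p(cfg$pwmDir), hla, seed = cfg$decoySeed,
                          decoyN = cfg$decoyN)
  scores <- scoreCandidates(candidates, models)

  refProteome <- buildCustomProteome(txset, NULL)
  kept <- filterWtIdentity(candidates, refProteome)
  ligandDb <- readLigandDb(p(cfg$ligands))
  binders <- callBinders(kept, scores, ligandDb, cutoff = cfg$rankCutoff,
                         strict = cfg$strictCutoff)
  say("predicted binders: ", sum(binders$is_binder))

  mutations <- contexts
  somNonSyn <- effects[effects$origin == "somatic" &
                       effects$consequence != "synonymous", , drop = FALSE]
  geneCounts <- table(somNonSyn$gene)
  expression <- readExpressionTable(p(cfg$expression))
  mutations <- filterExpression(mutations, expression, cfg$tissue,
                                cfg$tpmThreshold)
  mutations <- filterHypermutated(mutations, k = cfg$hypermutatedK,
                                  geneCounts = geneCounts)
  mutations <- filterUnderrepresented(mutations, ligandDb, refProteome,
                                      cfg$underrepThreshold)
  say("mutations after filters: ", nrow(mutations))

  ip <- lapply(seq_len(nrow(mutations)), function(i)
    classifyIpmsdbOverlap(mutations[i, , drop = FALSE], candidates,
                          ligandDb, refProteome))
  mutations$ipmsdb_I <- vapply(ip, `[[`, character(1), "I")
  mutations$ipmsdb_II <- vapply(ip, `[[`, character(1), "II")

  designs <- designLongPeptides(mutations, binders)
  if (!is.null(designs)) {
    hit <- match(designs$mutation_id, mutations$mutation_id)
    designs$p90_tpm <- mutations$p90_tpm[hit]
    designs$ipmsdb_I <- mutations$ipmsdb_I[hit]
    designs$ipmsdb_II <- mutations$ipmsdb_II[hit]
    designs <- rankDesigns(designs)
  }
  top <- suppressWarnings(selectTop(designs, cfg$topN))
  drivers <- if (file.exists(p(cfg$drivers)))
    read.delim(p(cfg$drivers), stringsAsFactors = FALSE) else NULL
  report <- buildReport(top, drivers)

  proteome <- buildCustomProteome(txset, effects)
  observed <- NULL
  idPath <- p(cfg$identifiedPeptides)
  if (file.exists(idPath)) {
    peps <- read.delim(idPath, stringsAsFactors = FALSE)$peptide
    observed <- flagObservedMutantPeptides(peps, proteome, effects)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeVariantTable(cons, file.path(outDir, "variants.tsv"))
    writeProteomeFasta(proteome, file.path(outDir, "proteome.fa"))
    writeReport(report, file.path(outDir, "report.tsv"))
  }
  list(consensus = cons, highConfidence = hc, effects = effects,
       contexts = contexts, candidates = candidates, scores = scores,
       binders = binders, mutations = mutations, designs = designs,
       report = report, proteome = proteome, observedPeptides = observed,
       config = cfg)
}
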
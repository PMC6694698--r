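#' TranscriptSet: protein-coding transcript models
#'
#' Holds, per transcript, the ordered CDS genomic intervals, the spliced
#' (strand-corrected) coding sequence and its translation. Minus-strand CDS
#' are reverse-complemented before translation. Transcripts whose CDS length
#' is not a multiple of three are flagged incomplete and excluded from
#' effect annotation and context building.
#'
#' @slot cds a [GenomicRanges::GRangesList], one element per transcript, CDS
#'   intervals ordered in transcription direction.
#' @slot cdsSeq a [Biostrings::DNAStringSet] of spliced coding sequences.
#' @slot protein an [Biostrings::AAStringSet] of translations (no trailing
#'   stop symbol).
#' @slot geneSymbol named character, transcript id -> gene symbol.
#' @slot incomplete named logical, `TRUE` when the CDS length is not
#'   divisible by three.
#'
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  slots = c(cds = "GRangesList", cdsSeq = "DNAStringSet",
            protein = "AAStringSet", geneSymbol = "character",
            incomplete = "logical"))

setValidity("TranscriptSet", function(object) {
  ids <- names(object@cds)
  msg <- character()
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "transcript names must be unique and non-NULL")
  for (slotnm in c("cdsSeq", "protein")) {
    if (!identical(names(slot(object, slotnm)), ids))
      msg <- c(msg, sprintf("names of '%s' disagree with 'cds'", slotnm))
  }
  if (!identical(names(object@geneSymbol), ids) ||
      !identical(names(object@incomplete), ids))
    msg <- c(msg, "geneSymbol/incomplete must be named by transcript")
  ok <- !object@incomplete
  if (any(ok)) {
    tr <- vapply(as.character(object@cdsSeq[ok]), .translateCds, character(1))
    if (!identical(unname(tr), unname(as.character(object@protein[ok]))))
      msg <- c(msg, "translated cdsSeq does not equal protein")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TranscriptSet transcript identifiers
#' @param x,object a `TranscriptSet`.
#' @export
txIds <- function(x) names(x@cds)

#' @describeIn TranscriptSet protein sequences (no stop symbol)
#' @export
proteinSeqs <- function(x) x@protein

#' @describeIn TranscriptSet spliced coding sequences
#' @export
cdsSeqs <- function(x) x@cdsSeq

#' @describeIn TranscriptSet gene symbol per transcript
#' @export
geneSymbols <- function(x) x@geneSymbol

#' @describeIn TranscriptSet incomplete-CDS flags
#' @export
isIncomplete <- function(x) x@incomplete

setMethod("show", "TranscriptSet", function(object) {
  cat(sprintf("TranscriptSet with %d transcripts (%d genes, %d incomplete)\n",
              length(object@cds), length(unique(object@geneSymbol)),
              sum(object@incomplete)))
  if (length(object@cds)) {
    n <- min(5L, length(object@cds))
    for (i in seq_len(n)) {
      cat(sprintf("  %s (%s): %d aa%s\n", txIds(object)[i],
                  object@geneSymbol[i], width(object@protein)[i],
                  if (object@incomplete[i]) " [incomplete]" else ""))
    }
    if (length(object@cds) > n) cat("  ...\n")
  }
})

#' PwmModel: per-allele position weight matrix scorer with decoy calibration
#'
#' A simplified, self-contained stand-in for published HLA ligand predictors.
#' Class I models carry one matrix per supported peptide length (rows =
#' positions, columns = the twenty amino acids); class II models carry a
#' single 9-position binding-core matrix and score a peptide by the best
#' core sub-window. Percentile ranks come from a decoy distribution of
#' `decoyN` random peptides per length, generated from a fixed seed.
#'
#' @slot allele allele name, e.g. `"A0101"`.
#' @slot hlaClass `"I"` or `"II"`.
#' @slot matrices named list of numeric matrices; class I names are peptide
#'   lengths, class II has the single element `"core"`.
#' @slot decoys named list (by peptide length) of sorted decoy score vectors.
#' @slot decoyN number of decoys per length.
#' @slot seed RNG seed used for decoy generation.
#' @slot background length-20 amino-acid sampling weights for decoys.
#'
#' @exportClass PwmModel
setClass("PwmModel",
  slots = c(allele = "character", hlaClass = "character",
            matrices = "list", decoys = "list", decoyN = "integer",
            seed = "integer", background = "numeric"))

setValidity("PwmModel", function(object) {
  msg <- character()
  if (!object@hlaClass %in% c("I", "II"))
    msg <- c(msg, "hlaClass must be 'I' or 'II'")
  for (nm in names(object@matrices)) {
    m <- object@matrices[[nm]]
    if (!is.matrix(m) || ncol(m) != 20L ||
        !identical(colnames(m), AA_STANDARD))
      msg <- c(msg, sprintf("matrix '%s' must have the 20 standard residues as columns", nm))
    else if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, sprintf("matrix '%s' must hold finite non-negative weights", nm))
    else if (identical(object@hlaClass, "II") && nrow(m) != 9L)
      msg <- c(msg, "class II core matrix must have 9 positions")
    else if (identical(object@hlaClass, "I") && nrow(m) != as.integer(nm))
      msg <- c(msg, sprintf("class I matrix '%s' must have %s positions", nm, nm))
  }
  if (length(object@background) != 20L || any(object@background < 0))
    msg <- c(msg, "background must be 20 non-negative weights")
  bad <- vapply(object@decoys, function(d) length(d) != object@decoyN ||
                  is.unsorted(d), logical(1))
  if (any(bad))
    msg <- c(msg, "each decoy distribution must be sorted and of size decoyN")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PwmModel", function(object) {
  cat(sprintf("PwmModel %s (HLA class %s): lengths %s, %d decoys/length, seed %d\n",
              object@allele, object@hlaClass,
              paste(names(object@decoys), collapse = ","),
              object@decoyN, object@seed))
})

#' FixtureSpec: parameters of a synthetic cohort
#'
#' Describes the toy inputs planted by [generateCohort()]: a single-chromosome
#' genome of one-exon genes, three caller VCFs with planted concordance,
#' discordance and phasing, an expression table, a ligand database, PWM motif
#' files and a ground-truth table of expected pipeline outcomes.
#'
#' @slot seed integer RNG seed; identical seeds give identical bundles.
#' @slot nGenes number of genes (>= 9; genes beyond the planted roles carry
#'   background mutations).
#' @slot proteinLengthRange length-2 integer range of protein lengths (aa).
#' @slot nSomatic number of planted non-synonymous somatic mutations.
#' @slot fractionPhasedLinked fraction of background mutations that receive a
#'   phase-linked germline SNP; 0 disables all linked-SNP planting.
#' @slot nDbLigands number of background ligand-database entries.
#' @slot decoyN decoys per peptide length for percentile-rank calibration.
#' @slot nExprSamples expression samples per gene in the TPM table.
#' @slot tissue tissue label used in the expression table.
#'
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  slots = c(seed = "integer", nGenes = "integer",
            proteinLengthRange = "integer", nSomatic = "integer",
            fractionPhasedLinked = "numeric", nDbLigands = "integer",
            decoyN = "integer", nExprSamples = "integer",
            tissue = "character"))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@nGenes < 9L)
    msg <- c(msg, "nGenes must be >= 9 (8 planted roles plus a host gene)")
  if (length(object@proteinLengthRange) != 2L ||
      object@proteinLengthRange[1] < 80L)
    msg <- c(msg, "proteinLengthRange must be two integers >= 80")
  cap <- 11L + 3L * max(0L, object@nGenes - 9L)
  if (object@nSomatic < 11L || object@nSomatic > cap)
    msg <- c(msg, sprintf("nSomatic must be in [11, %d] for nGenes = %d (more somatic SNVs than planted codon slots)", cap, object@nGenes))
  if (object@fractionPhasedLinked < 0 || object@fractionPhasedLinked > 1)
    msg <- c(msg, "fractionPhasedLinked must be in [0, 1]")
  if (any(c(object@nDbLigands, object@decoyN, object@nExprSamples) < 1L))
    msg <- c(msg, "counts must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a FixtureSpec
#'
#' @param seed integer seed.
#' @param nGenes,proteinLengthRange,nSomatic,fractionPhasedLinked,nDbLigands
#'   see the class slots.
#' @param decoyN,nExprSamples,tissue see the class slots.
#' @return A validated [FixtureSpec-class] object.
#' @examples
#' fixtureSpec(seed = 1)
#' @export
fixtureSpec <- function(seed = 1L, nGenes = 14L,
                        proteinLengthRange = c(120L, 260L),
                        nSomatic = 23L, fractionPhasedLinked = 0.1,
                        nDbLigands = 40L, decoyN = 100000L,
                        nExprSamples = 10L, tissue = "pancreas") {
  new("FixtureSpec", seed = as.integer(seed), nGenes = as.integer(nGenes),
      proteinLengthRange = as.integer(proteinLengthRange),
      nSomatic = as.integer(nSomatic),
      fractionPhasedLinked = as.numeric(fractionPhasedLinked),
      nDbLigands = as.integer(nDbLigands), decoyN = as.integer(decoyN),
      nExprSamples = as.integer(nExprSamples), tissue = tissue)
}

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: seed %d, %d genes, %d somatic SNVs, %.0f%% linked, %d decoys\n",
              object@seed, object@nGenes, object@nSomatic,
              100 * object@fractionPhasedLinked, object@decoyN))
})
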
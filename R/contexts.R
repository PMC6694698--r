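# Mutant peptide contexts: the <= 31-residue window centred on the altered
# residue (15 residues each side, truncated at the protein termini), with
# phase-linked non-synonymous SNP edits applied, and the optional
# frameshift open-reading-frame context.

.contextRow <- function(mutation_id, variant_id, tx, gene, chrom, pos,
                        aa_pos, hgvs, mutant_seq, wt_seq, mutated_index,
                        linked_edits, kind = "snv", flagged = FALSE) {
  data.frame(mutation_id = mutation_id, variant_id = variant_id,
             transcript_id = tx, gene = gene, chrom = chrom, pos = pos,
             aa_pos = aa_pos, hgvs = hgvs, mutant_seq = mutant_seq,
             wt_seq = wt_seq, mutated_index = mutated_index,
             linked_edits = linked_edits, kind = kind, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Build the mutant context for one missense SNV
#'
#' Places the novel residue at the centre of a 31-mer (15 reference residues
#' each side; truncated, never padded, at the termini) and applies every
#' non-synonymous linked-SNP edit whose protein position falls inside the
#' window. The wild-type sequence keeps the reference residues at all edited
#' positions.
#'
#' @param effect one row of [annotateEffects()] output with
#'   `consequence == "missense"`.
#' @param txset a [TranscriptSet-class].
#' @param linked data.frame of effects of linked germline SNPs on the same
#'   transcript (may be empty / NULL).
#' @param flank residues kept on each side of the mutation (default 15).
#' @return one-row data.frame (see [buildContexts()] for the columns), or
#'   `NULL` with a warning when the mutant residue is a stop.
#' @export
buildSnvContext <- function(effect, txset, linked = NULL, flank = 15L) {
  stopifnot(nrow(effect) == 1L)
  if (!identical(effect$consequence, "missense"))
    stop("buildSnvContext requires a missense effect")
  if (identical(effect$mut_aa, "*")) {
    warning("mutated residue is a stop for ", effect$variant_id, "; rejected")
    return(NULL)
  }
  tx <- effect$transcript_id
  prot <- as.character(proteinSeqs(txset)[[tx]])
  aa <- effect$aa_pos
  ws <- max(1L, aa - flank)
  we <- min(nchar(prot), aa + flank)
  wt <- substr(prot, ws, we)
  mutIdx <- aa - ws + 1L
  mut <- wt
  substr(mut, mutIdx, mutIdx) <- effect$mut_aa
  edits <- character(0)
  hgvs <- effect$hgvs
  if (!is.null(linked) && nrow(linked)) {
    linked <- linked[linked$transcript_id == tx &
                     linked$consequence == "missense" &
                     linked$aa_pos >= ws & linked$aa_pos <= we &
                     linked$aa_pos != aa, , drop = FALSE]
    if (nrow(linked)) {
      linked <- linked[order(linked$aa_pos), , drop = FALSE]
      for (k in seq_len(nrow(linked))) {
        idx <- linked$aa_pos[k] - ws + 1L
        substr(mut, idx, idx) <- linked$mut_aa[k]
        edits <- c(edits, paste0(idx, ":", linked$wt_aa[k], ">",
                                 linked$mut_aa[k]))
      }
      hgvs <- paste(c(effect$hgvs, linked$hgvs), collapse = "+")
    }
  }
  .contextRow(paste0(tx, ":", hgvs), effect$variant_id, tx, effect$gene,
              effect$chrom, effect$pos, aa, hgvs, mut, wt, mutIdx,
              paste(edits, collapse = ";"))
}

#' Build the open-reading-frame context for a frameshift indel
#'
#' Emits the 24 reference residues immediately upstream of the first altered
#' residue (fewer near the N terminus) followed by the novel open-reading
#' frame translation up to, and not including, the first stop. When the
#' frameshift stops immediately, the context holds the upstream residues
#' only and is flagged.
#'
#' @param effect one frameshift row of [annotateEffects()] output.
#' @param txset a [TranscriptSet-class].
#' @param upstream number of unaltered residues to keep (default 24).
#' @return one-row context data.frame, or `NULL` when the edited CDS never
#'   diverges from the reference protein.
#' @export
buildIndelContext <- function(effect, txset, upstream = 24L) {
  stopifnot(nrow(effect) == 1L)
  if (!identical(effect$consequence, "frameshift"))
    stop("buildIndelContext requires a frameshift effect")
  tx <- effect$transcript_id
  cdsNt <- as.character(cdsSeqs(txset)[[tx]])
  prot <- as.character(proteinSeqs(txset)[[tx]])
  minus <- identical(as.character(BiocGenerics::strand(txset@cds[[tx]]))[1], "-")
  ref <- if (minus) .revcomp(effect$ref) else effect$ref
  alt <- if (minus) .revcomp(effect$alt) else effect$alt
  cdsPos <- effect$cds_pos
  if (minus) cdsPos <- cdsPos - nchar(ref) + 1L  # position of left-most ref base
  mutNt <- paste0(substr(cdsNt, 1L, cdsPos - 1L), alt,
                  substr(cdsNt, cdsPos + nchar(ref), nchar(cdsNt)))
  mutAll <- {
    ncod <- nchar(mutNt) %/% 3L
    codons <- substring(mutNt, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    paste(unname(GENETIC_CODE[codons]), collapse = "")
  }
  # first altered residue = first divergence between mutant and reference
  nmin <- min(nchar(mutAll), nchar(prot))
  d <- NA_integer_
  for (i in seq_len(nmin)) {
    if (substr(mutAll, i, i) != substr(prot, i, i)) { d <- i; break }
  }
  if (is.na(d)) {
    if (nchar(mutAll) > nchar(prot)) d <- nchar(prot) + 1L else return(NULL)
  }
  us <- max(1L, d - upstream)
  up <- substr(prot, us, d - 1L)
  novelAll <- substr(mutAll, d, nchar(mutAll))
  novel <- sub("\\*.*", "", novelAll)
  flagged <- !nzchar(novel)
  if (flagged)
    warning("immediate stop after frameshift for ", effect$variant_id,
            "; context holds upstream residues only")
  ctx <- paste0(up, novel)
  wt <- substr(prot, us, min(nchar(prot), us + nchar(ctx) - 1L))
  .contextRow(paste0(tx, ":", effect$hgvs), effect$variant_id, tx,
              effect$gene, effect$chrom, effect$pos, d, effect$hgvs,
              ctx, wt, nchar(up) + 1L, "", kind = "indel", flagged = flagged)
}

#' Build mutant contexts for all retained somatic effects
#'
#' Missense somatic variants get a centred (<= 31-mer) context via
#' [buildSnvContext()], including linked-SNP edits taken from the
#' `linked_snps` column of the consensus set. Synonymous and stop-gained
#' effects are excluded. Frameshift contexts are produced only when
#' `includeIndels = TRUE` (the default matches the disabled setting).
#'
#' @param effects [annotateEffects()] output for the high-confidence set
#'   (somatic and linked germline rows).
#' @param txset a [TranscriptSet-class].
#' @param variants the consensus GRanges carrying `linked_snps` (optional;
#'   without it no linked edits are applied).
#' @param includeIndels logical; emit frameshift ORF contexts (default
#'   `FALSE`).
#' @param flank,upstream window geometry, see the single-context builders.
#' @return data.frame of contexts: `mutation_id`, `variant_id`,
#'   `transcript_id`, `gene`, `chrom`, `pos`, `aa_pos`, `hgvs`,
#'   `mutant_seq`, `wt_seq`, `mutated_index`, `linked_edits`, `kind`,
#'   `flagged`.
#' @export
buildContexts <- function(effects, txset, variants = NULL,
                          includeIndels = FALSE, flank = 15L,
                          upstream = 24L) {
  linkMap <- list()
  if (!is.null(variants) && length(variants) &&
      !is.null(mcols(variants)$linked_snps)) {
    m <- mcols(variants)
    linkMap <- setNames(as.list(m$linked_snps), m$variant_id)
  }
  som <- effects[!is.na(effects$origin) & effects$origin == "somatic", ,
                 drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(som))) {
    e <- som[i, , drop = FALSE]
    if (e$consequence == "missense") {
      lids <- linkMap[[e$variant_id]]
      linked <- if (length(lids))
        effects[effects$variant_id %in% lids, , drop = FALSE] else NULL
      ctx <- buildSnvContext(e, txset, linked, flank = flank)
      if (!is.null(ctx)) out[[length(out) + 1L]] <- ctx
    } else if (e$consequence == "frameshift" && includeIndels) {
      ctx <- buildIndelContext(e, txset, upstream = upstream)
      if (!is.null(ctx)) out[[length(out) + 1L]] <- ctx
    }
  }
  if (!length(out)) {
    return(.contextRow(character(0), character(0), character(0),
                       character(0), character(0), integer(0), integer(0),
                       character(0), character(0), character(0), integer(0),
                       character(0), character(0), logical(0)))
  }
  do.call(rbind, out)
}
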
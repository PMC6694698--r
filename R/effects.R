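# Protein-level effect annotation of consensus variants (minimal consequence
# set: missense / synonymous / stop_gained / frameshift / inframe_indel).

.effectRow <- function(variant_id, origin, chrom, pos, ref, alt, tx, gene,
                       cds_pos, aa_pos, wt_aa, mut_aa, consequence, hgvs) {
  data.frame(variant_id = variant_id, origin = origin, chrom = chrom,
             pos = pos, ref = ref, alt = alt, transcript_id = tx,
             gene = gene, cds_pos = cds_pos, aa_pos = aa_pos,
             wt_aa = wt_aa, mut_aa = mut_aa, consequence = consequence,
             hgvs = hgvs, stringsAsFactors = FALSE)
}

#' Annotate protein-level effects of consensus variants
#'
#' Maps each variant onto the canonical transcript of its gene (longest CDS;
#' ties broken by transcript id) and calls the codon-level consequence. SNVs
#' become missense / synonymous / stop_gained; length-changing alleles become
#' frameshift or inframe_indel. Variants outside any CDS are ignored.
#'
#' @param gr consensus variants (e.g. from [selectHighConfidence()]); any
#'   GRanges with `variant_id`, `ref`, `alt` and optional `origin` columns.
#' @param txset a [TranscriptSet-class].
#' @return data.frame with one row per variant landing in a canonical CDS:
#'   `variant_id`, `origin`, `chrom`, `pos`, `ref`, `alt`, `transcript_id`,
#'   `gene`, `cds_pos`, `aa_pos`, `wt_aa`, `mut_aa`, `consequence`, `hgvs`.
#' @export
annotateEffects <- function(gr, txset) {
  canon <- .canonicalTx(txset)
  out <- list()
  if (length(gr)) {
    m <- mcols(gr)
    origin <- if (!is.null(m$origin)) m$origin else rep(NA_character_, length(gr))
    chroms <- as.character(seqnames(gr))
    for (i in seq_along(gr)) {
      chrom <- chroms[i]; pos <- start(gr)[i]
      ref <- m$ref[i]; alt <- m$alt[i]
      hitTx <- NULL
      for (tx in canon) {
        cp <- .cdsPosition(txset, tx, chrom, pos)
        if (!is.na(cp)) { hitTx <- tx; cdsPos <- cp; break }
      }
      if (is.null(hitTx)) next
      tx <- hitTx
      gene <- geneSymbols(txset)[[tx]]
      cdsNt <- as.character(cdsSeqs(txset)[[tx]])
      prot <- as.character(proteinSeqs(txset)[[tx]])
      minus <- identical(as.character(BiocGenerics::strand(txset@cds[[tx]]))[1], "-")
      if (nchar(ref) == 1L && nchar(alt) == 1L) {
        cRef <- if (minus) .complement(ref) else ref
        cAlt <- if (minus) .complement(alt) else alt
        if (substr(cdsNt, cdsPos, cdsPos) != cRef) {
          warning("reference allele mismatch for ", m$variant_id[i],
                  " on ", tx, "; variant skipped")
          next
        }
        codonIdx <- (cdsPos - 1L) %/% 3L + 1L
        within <- (cdsPos - 1L) %% 3L + 1L
        codon <- substr(cdsNt, 3L * codonIdx - 2L, 3L * codonIdx)
        mutCodon <- codon
        substr(mutCodon, within, within) <- cAlt
        wt <- .translateCodon(codon); mut <- .translateCodon(mutCodon)
        consequence <- if (wt == mut) "synonymous"
          else if (mut == "*") "stop_gained" else "missense"
        out[[length(out) + 1L]] <- .effectRow(
          m$variant_id[i], origin[i], chrom, pos, ref, alt, tx, gene,
          cdsPos, codonIdx, wt, mut, consequence,
          hgvsP(wt, codonIdx, mut))
      } else {
        delta <- nchar(alt) - nchar(ref)
        consequence <- if (delta %% 3L == 0L) "inframe_indel" else "frameshift"
        codonIdx <- (cdsPos - 1L) %/% 3L + 1L
        wt <- if (codonIdx <= nchar(prot)) substr(prot, codonIdx, codonIdx)
              else "*"
        out[[length(out) + 1L]] <- .effectRow(
          m$variant_id[i], origin[i], chrom, pos, ref, alt, tx, gene,
          cdsPos, codonIdx, wt, NA_character_, consequence,
          if (consequence == "frameshift") .hgvsFs(wt, codonIdx)
          else paste0("p.", .AA3[wt], codonIdx, "delins"))
      }
    }
  }
  if (!length(out)) {
    return(.effectRow(character(0), character(0), character(0), integer(0),
                      character(0), character(0), character(0), character(0),
                      integer(0), integer(0), character(0), character(0),
                      character(0), character(0)))
  }
  do.call(rbind, out)
}
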
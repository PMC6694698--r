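# Transcript models from GFF3 + FASTA.

.attrFirst <- function(x) {
  vapply(x, function(v) if (length(v)) v[[1]] else NA_character_, character(1))
}

#' Load protein-coding transcript models
#'
#' Reads a GFF3 annotation (GENCODE dialect: `mRNA`/`exon`/`CDS` features
#' with `Parent` attributes) together with sequences, splices and
#' strand-corrects each CDS and translates it. `seqType = "genome"` expects a
#' genome FASTA and extracts CDS intervals from it; `seqType = "cds"` expects
#' a FASTA of spliced coding sequences named by transcript id.
#'
#' Transcripts whose CDS length is not divisible by three are kept but
#' flagged incomplete and skipped by effect annotation.
#'
#' @param gff3 GFF3 file path.
#' @param fasta FASTA file path (genome or spliced CDS, per `seqType`).
#' @param seqType `"genome"` (default) or `"cds"`.
#' @return A [TranscriptSet-class].
#' @export
loadTranscripts <- function(gff3, fasta, seqType = c("genome", "cds")) {
  seqType <- match.arg(seqType)
  ann <- rtracklayer::import(gff3)
  type <- as.character(ann$type)
  cdsFeat <- ann[type == "CDS"]
  if (length(cdsFeat) == 0L) stop("no CDS features in ", gff3)
  parent <- .attrFirst(cdsFeat$Parent)
  if (anyNA(parent)) stop("CDS features without Parent attribute in ", gff3)
  mrna <- ann[type %in% c("mRNA", "transcript")]
  gene <- setNames(rep(NA_character_, length(mrna)), .attrFirst(mrna$ID))
  gn <- if (!is.null(mrna$gene_name)) as.character(mrna$gene_name) else NULL
  if (!is.null(gn)) gene[] <- gn
  cdsByTx <- split(cdsFeat, parent)
  ids <- names(cdsByTx)
  # order intervals in transcription direction
  cdsByTx <- GRangesList(lapply(cdsByTx, function(g) {
    st <- as.character(BiocGenerics::strand(g))[1]
    g[order(start(g), decreasing = identical(st, "-"))]
  }))
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  cdsSeq <- setNames(character(length(ids)), ids)
  for (tx in ids) {
    g <- cdsByTx[[tx]]
    st <- as.character(BiocGenerics::strand(g))[1]
    if (seqType == "cds") {
      if (!tx %in% names(seqs))
        stop("CDS/FASTA mismatch: no sequence for transcript ", tx)
      cdsSeq[tx] <- as.character(seqs[[tx]])
    } else {
      chr <- as.character(seqnames(g))[1]
      if (!chr %in% names(seqs))
        stop("CDS/FASTA mismatch: no sequence for chromosome '", chr,
             "' needed by transcript ", tx)
      if (max(end(g)) > length(seqs[[chr]]))
        stop("CDS/FASTA mismatch: transcript ", tx,
             " extends past the end of '", chr, "'")
      pieces <- vapply(seq_along(g), function(i) {
        as.character(subseq(seqs[[chr]], start(g)[i], end(g)[i]))
      }, character(1))
      if (identical(st, "-")) pieces <- vapply(pieces, .revcomp, character(1))
      cdsSeq[tx] <- paste(pieces, collapse = "")
    }
  }
  incomplete <- nchar(cdsSeq) %% 3L != 0L
  protein <- vapply(cdsSeq, .translateCds, character(1))
  geneSymbol <- gene[ids]
  geneSymbol[is.na(geneSymbol)] <- ids[is.na(geneSymbol)]
  names(geneSymbol) <- ids
  new("TranscriptSet",
      cds = cdsByTx,
      cdsSeq = DNAStringSet(cdsSeq),
      protein = AAStringSet(protein),
      geneSymbol = geneSymbol,
      incomplete = setNames(incomplete, ids))
}

# canonical transcript per gene: longest CDS, ties broken lexicographically
.canonicalTx <- function(txset) {
  ids <- txIds(txset)
  ids <- ids[!isIncomplete(txset)[ids]]
  if (!length(ids)) return(character(0))
  len <- width(cdsSeqs(txset))[match(ids, txIds(txset))]
  ord <- order(geneSymbols(txset)[ids], -len, ids)
  ids <- ids[ord]
  ids[!duplicated(geneSymbols(txset)[ids])]
}

# genomic position -> 1-based CDS position within a transcript, NA if outside
.cdsPosition <- function(txset, tx, chrom, gpos) {
  g <- txset@cds[[tx]]
  if (is.null(g) || !chrom %in% as.character(seqnames(g))) return(NA_integer_)
  st <- as.character(BiocGenerics::strand(g))[1]
  offset <- 0L
  for (i in seq_along(g)) {
    s <- start(g)[i]; e <- end(g)[i]
    if (gpos >= s && gpos <= e) {
      return(offset + if (identical(st, "-")) (e - gpos + 1L) else (gpos - s + 1L))
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}
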
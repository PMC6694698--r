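# Proteogenomics: the sample-customized protein database and flagging of
# MS-identified mutant peptides.

#' Build the customized protein database
#'
#' Emits every reference protein once (headers `transcript|gene`), plus one
#' mutant entry per affected transcript carrying the full mutant sequence
#' with all retained non-synonymous substitutions applied and a header
#' suffix listing the edits (`transcript|gene|p.Xxx#Yyy;...`, ordered by
#' protein position). With zero variants the output equals the reference
#' proteome. Ordering is deterministic (by transcript id).
#'
#' @param txset a [TranscriptSet-class].
#' @param effects [annotateEffects()] output; only missense rows are
#'   applied (the frameshift option of the context builder does not
#'   contribute database entries).
#' @return An [Biostrings::AAStringSet]: reference entries then mutant
#'   entries.
#' @export
buildCustomProteome <- function(txset, effects = NULL) {
  ids <- sort(txIds(txset))
  ids <- ids[!isIncomplete(txset)[ids]]
  ref <- proteinSeqs(txset)[ids]
  names(ref) <- paste0(ids, "|", geneSymbols(txset)[ids])
  if (is.null(effects) || nrow(effects) == 0L) return(ref)
  eff <- effects[effects$consequence == "missense" &
                 effects$transcript_id %in% ids, , drop = FALSE]
  if (nrow(eff) == 0L) return(ref)
  mutant <- list()
  for (tx in sort(unique(eff$transcript_id))) {
    e <- eff[eff$transcript_id == tx, , drop = FALSE]
    e <- e[!duplicated(e$aa_pos), , drop = FALSE]
    e <- e[order(e$aa_pos), , drop = FALSE]
    seqc <- as.character(proteinSeqs(txset)[[tx]])
    for (k in seq_len(nrow(e))) substr(seqc, e$aa_pos[k], e$aa_pos[k]) <- e$mut_aa[k]
    nm <- paste0(tx, "|", geneSymbols(txset)[[tx]], "|",
                 paste(e$hgvs, collapse = ";"))
    mutant[[nm]] <- seqc
  }
  c(ref, AAStringSet(unlist(mutant)))
}

#' Write a protein FASTA
#'
#' @param proteome an [Biostrings::AAStringSet].
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteome, path, width = 60L) {
  writeXStringSet(proteome, path, width = width)
  invisible(path)
}

#' Flag MS-identified peptides as mutant, wild type or unmapped
#'
#' A peptide is flagged `mutant` when it occurs in a mutant database entry,
#' spans an edited residue and does not occur anywhere in the reference
#' proteome; `wt` when it occurs in the reference proteome; `unmapped`
#' otherwise (including peptides with non-standard residues).
#'
#' @param peptides character vector of identified peptide sequences.
#' @param proteome customized database from [buildCustomProteome()] (mutant
#'   entries are recognized by their edit-carrying headers).
#' @param effects the [annotateEffects()] output used to build the database
#'   (provides edited positions per transcript).
#' @return data.frame with columns `peptide`, `status`, `entry` (first
#'   matching database entry or `NA`).
#' @export
flagObservedMutantPeptides <- function(peptides, proteome, effects) {
  nm <- names(proteome)
  isMut <- grepl("\\|p\\.", nm)
  refSeqs <- as.character(proteome[!isMut])
  mutSeqs <- as.character(proteome[isMut])
  mutTx <- sub("\\|.*", "", names(mutSeqs))
  editPos <- split(effects$aa_pos[effects$consequence == "missense"],
                   effects$transcript_id[effects$consequence == "missense"])
  status <- character(length(peptides))
  entry <- rep(NA_character_, length(peptides))
  refBlob <- paste(refSeqs, collapse = "#")
  for (i in seq_along(peptides)) {
    p <- peptides[i]
    if (!.isStandardPeptide(p)) { status[i] <- "unmapped"; next }
    if (grepl(p, refBlob, fixed = TRUE)) {
      status[i] <- "wt"
      hit <- which(vapply(refSeqs, grepl, logical(1), pattern = p,
                          fixed = TRUE))[1]
      entry[i] <- names(refSeqs)[hit]
      next
    }
    found <- FALSE
    for (j in seq_along(mutSeqs)) {
      at <- regexpr(p, mutSeqs[[j]], fixed = TRUE)
      if (at > 0L) {
        span <- c(at, at + nchar(p) - 1L)
        ep <- editPos[[mutTx[j]]]
        if (length(ep) && any(ep >= span[1] & ep <= span[2])) {
          status[i] <- "mutant"; entry[i] <- names(mutSeqs)[j]
          found <- TRUE
          break
        }
      }
    }
    if (!found && !nzchar(status[i])) status[i] <- "unmapped"
  }
  data.frame(peptide = peptides, status = status, entry = entry,
             stringsAsFactors = FALSE)
}
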
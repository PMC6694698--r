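# Long peptide design: the shortest contiguous sub-window of the mutant
# context covering the maximum number of fully contained predicted binders;
# ranking and Table-style reporting.

#' Design the optimal long peptide for one mutation
#'
#' Over all contiguous windows of the context, chooses the window maximizing
#' the number of fully contained predicted binders (a binder counts only if
#' its entire span lies inside the window); among maxima the shortest, among
#' those the leftmost.
#'
#' @param context one context row ([buildContexts()]).
#' @param binders binder candidates of this mutation ([callBinders()]
#'   output restricted to `is_binder`).
#' @param maxLength optional cap on the window length (residues). By
#'   default there is no cap beyond the context itself; a cap matters only
#'   for long open-reading-frame contexts, where two distant binder
#'   clusters may not fit one window and the larger cluster wins.
#' @return one-row data.frame: `mutation_id`, `start`, `end` (context
#'   coordinates), `sequence`, `n_binders_I`, `n_binders_II`,
#'   `n_alleles_I`, `n_alleles_II`, `min_pval_I`, `min_pval_II`,
#'   `n_peptides` (unique binder sequences contained); or `NULL` when the
#'   mutation has no binder.
#' @export
designLongPeptide <- function(context, binders, maxLength = NULL) {
  binders <- binders[binders$mutation_id == context$mutation_id &
                     binders$is_binder, , drop = FALSE]
  if (nrow(binders) == 0L) return(NULL)
  L <- nchar(context$mutant_seq)
  if (is.null(maxLength)) maxLength <- L
  bs <- binders$context_start
  be <- bs + binders$length - 1L
  # enumerate all O(L^2) windows; count fully contained binder spans
  best <- c(count = -1L, len = .Machine$integer.max, a = 0L, b = 0L)
  for (a in seq_len(L)) {
    for (b in a:min(L, a + maxLength - 1L)) {
      cnt <- sum(bs >= a & be <= b)
      wlen <- b - a + 1L
      if (cnt > best["count"] ||
          (cnt == best["count"] && wlen < best["len"])) {
        best <- c(count = cnt, len = wlen, a = a, b = b)
      }
    }
  }
  a <- best[["a"]]; b <- best[["b"]]
  inside <- bs >= a & be <= b
  contained <- binders[inside, , drop = FALSE]
  alleles <- function(cl) {
    al <- unlist(strsplit(contained$binder_alleles[contained$hla_class == cl],
                          ","))
    length(unique(al[nzchar(al)]))
  }
  minp <- function(cl) {
    p <- contained$p_value[contained$hla_class == cl]
    if (!length(p) || all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
  }
  data.frame(mutation_id = context$mutation_id, start = a, end = b,
             sequence = substr(context$mutant_seq, a, b),
             n_binders_I = sum(contained$hla_class == "I"),
             n_binders_II = sum(contained$hla_class == "II"),
             n_alleles_I = alleles("I"), n_alleles_II = alleles("II"),
             min_pval_I = minp("I"), min_pval_II = minp("II"),
             n_peptides = length(unique(contained$sequence)),
             stringsAsFactors = FALSE)
}

#' Design long peptides for every mutation with at least one binder
#'
#' @param contexts context data.frame.
#' @param binders [callBinders()] output.
#' @return data.frame of designs joined with the context annotation columns
#'   (`gene`, `chrom`, `pos`, `hgvs`, ...). Mutations without binders carry
#'   no design and are excluded from ranking.
#' @export
designLongPeptides <- function(contexts, binders) {
  out <- list()
  for (i in seq_len(nrow(contexts))) {
    d <- designLongPeptide(contexts[i, , drop = FALSE], binders)
    if (is.null(d)) next
    d$gene <- contexts$gene[i]
    d$transcript_id <- contexts$transcript_id[i]
    d$chrom <- contexts$chrom[i]
    d$pos <- contexts$pos[i]
    d$hgvs <- contexts$hgvs[i]
    d$mutated_index <- contexts$mutated_index[i]
    out[[length(out) + 1L]] <- d
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Rank long peptide designs
#'
#' Sort keys in order: minimum class-I binder p-value ascending (designs
#' without class-I binders last); total binder count descending; distinct
#' class I + class II alleles descending; EXACT immunopeptidome match
#' first; genomic coordinate ascending as the final deterministic
#' tie-break.
#'
#' @param designs [designLongPeptides()] output, optionally with
#'   `ipmsdb_I` / `ipmsdb_II` columns for the EXACT tie-break.
#' @return `designs` ordered with a `rank` column set.
#' @export
rankDesigns <- function(designs) {
  if (is.null(designs) || nrow(designs) == 0L) return(designs)
  p1 <- designs$min_pval_I
  p1[is.na(p1)] <- 1.01  # below any real p-value's precedence
  totBind <- designs$n_binders_I + designs$n_binders_II
  totAll <- designs$n_alleles_I + designs$n_alleles_II
  exact <- rep(FALSE, nrow(designs))
  if (!is.null(designs$ipmsdb_I))
    exact <- designs$ipmsdb_I == "EXACT" | designs$ipmsdb_II == "EXACT"
  chromKey <- suppressWarnings(as.numeric(sub("^chr", "", designs$chrom)))
  chromKey[is.na(chromKey)] <- 1e6
  ord <- order(p1, -totBind, -totAll, -exact, chromKey, designs$chrom,
               designs$pos, designs$hgvs)
  designs <- designs[ord, , drop = FALSE]
  designs$rank <- seq_len(nrow(designs))
  rownames(designs) <- NULL
  designs
}

#' Select the top designs
#'
#' @param designs ranked designs.
#' @param n number to keep (default 10).
#' @return the first `min(n, available)` designs; warns when fewer than `n`
#'   are available.
#' @export
selectTop <- function(designs, n = 10L) {
  if (is.null(designs)) return(NULL)
  if (nrow(designs) < n)
    warning("only ", nrow(designs), " design(s) available for top-", n,
            " selection")
  head(designs, n)
}

#' Build the final report table
#'
#' One row per selected design with the fourteen report columns: rank,
#' chromosome position, gene, 90th-percentile tissue TPM, protein mutation,
#' driver status, long peptide sequence, immunopeptidome overlap categories
#' per class, lowest class I and class II binder p-values, and binder /
#' allele counts. `NONE` overlap categories print as empty strings, as do
#' missing driver annotations.
#'
#' @param designs ranked (and selected) designs carrying `p90_tpm`,
#'   `ipmsdb_I`, `ipmsdb_II` columns.
#' @param drivers optional data.frame with columns `gene`, `status`.
#' @return data.frame with the report columns.
#' @export
buildReport <- function(designs, drivers = NULL) {
  if (is.null(designs) || nrow(designs) == 0L) designs <- designs[0, , drop = FALSE]
  blankNone <- function(x) ifelse(is.na(x) | x == "NONE", "", x)
  drv <- rep("", nrow(designs))
  if (!is.null(drivers) && nrow(drivers)) {
    hit <- match(designs$gene, drivers$gene)
    drv <- ifelse(is.na(hit), "", drivers$status[hit])
  }
  fmtP <- function(p) ifelse(is.na(p), "", format(p, trim = TRUE,
                                                  scientific = FALSE))
  out <- data.frame(
    Rank = designs$rank,
    Chromosome_position = paste0(sub("^chr", "", designs$chrom), "_",
                                 designs$pos),
    Gene = designs$gene,
    Expression_TPM_p90 = designs$p90_tpm,
    Mutation = designs$hgvs,
    Driver_status = drv,
    Long_peptide_sequence = designs$sequence,
    `ipMSDB_HLA-I` = blankNone(designs$ipmsdb_I),
    `ipMSDB_HLA-II` = blankNone(designs$ipmsdb_II),
    `Lowest_HLA-I_pval` = fmtP(designs$min_pval_I),
    `Lowest_HLA-II_pval` = fmtP(designs$min_pval_II),
    N_predicted_peptides = designs$n_peptides,
    `N_HLA-I_alleles` = designs$n_alleles_I,
    `N_HLA-II_alleles` = designs$n_alleles_II,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(designs) == 0L) out <- out[0, , drop = FALSE]
  out
}

#' Write the report as TSV
#'
#' @param report [buildReport()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
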
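# Exclusion filters (expression, wild-type identity, hypermutated genes,
# ligand-database representation) and immunopeptidome hotspot-overlap
# classification.

#' Read a per-gene tissue expression table
#'
#' TSV with columns `gene`, `tissue` and either per-sample TPM columns
#' (named `s1`, `s2`, ... or anything else numeric) or a precomputed `p90`
#' column.
#'
#' @param path TSV path.
#' @return data.frame with at least `gene`, `tissue` and `p90` (computed
#'   from the sample columns when absent).
#' @export
readExpressionTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "tissue") %in% names(tab)))
  if (!"p90" %in% names(tab)) {
    sampleCols <- setdiff(names(tab), c("gene", "tissue"))
    sampleCols <- sampleCols[vapply(tab[sampleCols], is.numeric, logical(1))]
    if (!length(sampleCols))
      stop("expression table needs a p90 column or numeric sample columns")
    tab$p90 <- apply(tab[sampleCols], 1L, expressionP90)
  }
  tab
}

#' 90th percentile of expression samples
#'
#' Linear interpolation between order statistics (the default quantile
#' convention, type 7); e.g. samples 1..10 give 9.1.
#'
#' @param tpms non-negative numeric vector.
#' @return the 90th percentile TPM.
#' @export
expressionP90 <- function(tpms) {
  unname(quantile(tpms, probs = 0.9, type = 7, na.rm = TRUE))
}

#' Filter mutations on wild-type gene expression
#'
#' Drops mutations whose gene has 90th-percentile TPM below the threshold
#' in the given tissue (default `TPM < 1`, strict, so exactly 1 is
#' retained). Genes absent from the table are retained with a
#' missing-expression flag rather than silently dropped.
#'
#' @param mutations data.frame with a `gene` column (one row per mutation).
#' @param expression table from [readExpressionTable()].
#' @param tissue tissue to look up.
#' @param threshold TPM threshold (default 1).
#' @return `mutations` restricted to retained rows, with added `p90_tpm`
#'   and `expression_missing` columns.
#' @export
filterExpression <- function(mutations, expression, tissue = "pancreas",
                             threshold = 1) {
  sub <- expression[expression$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0L) stop("tissue '", tissue, "' absent from expression table")
  hit <- match(mutations$gene, sub$gene)
  mutations$p90_tpm <- sub$p90[hit]
  mutations$expression_missing <- is.na(hit)
  keep <- mutations$expression_missing | mutations$p90_tpm >= threshold
  mutations[keep, , drop = FALSE]
}

#' Filter candidate peptides occurring in a reference proteome
#'
#' Drops a mutant peptide when its exact sequence occurs anywhere in any of
#' the reference proteomes (the wild-type counterpart being present does not
#' matter; only mutant identity does).
#'
#' @param candidates candidate data.frame with a `sequence` column.
#' @param proteomes an [Biostrings::AAStringSet] or a list of them.
#' @return `candidates` restricted to peptides absent from all references.
#' @export
filterWtIdentity <- function(candidates, proteomes) {
  if (!is.list(proteomes)) proteomes <- list(proteomes)
  if (nrow(candidates) == 0L) return(candidates)
  blobs <- vapply(proteomes, function(p) paste(as.character(p), collapse = "#"),
                  character(1))
  seqs <- unique(candidates$sequence)
  inRef <- vapply(seqs, function(s)
    any(vapply(blobs, grepl, logical(1), pattern = s, fixed = TRUE)),
    logical(1))
  candidates[!candidates$sequence %in% seqs[inRef], , drop = FALSE]
}

#' Filter mutations in hypermutated genes
#'
#' Drops every mutation of a gene carrying more than `k` somatic mutations
#' (such genes are likely false-positive havens). `k = Inf` disables the
#' filter.
#'
#' @param mutations data.frame with a `gene` column.
#' @param k maximum somatic mutations per gene (default 3).
#' @param geneCounts optional named vector of per-gene somatic mutation
#'   counts; defaults to counting rows of `mutations` per gene.
#' @return the retained rows.
#' @export
filterHypermutated <- function(mutations, k = 3, geneCounts = NULL) {
  if (is.infinite(k)) return(mutations)
  if (is.null(geneCounts)) geneCounts <- table(mutations$gene)
  bad <- names(geneCounts)[geneCounts > k]
  mutations[!mutations$gene %in% bad, , drop = FALSE]
}

#' Read a ligand database table
#'
#' TSV of observed HLA ligands: columns `peptide`, `hla_class`,
#' `source_protein`, `n_observations`.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readLigandDb <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "hla_class", "source_protein",
                  "n_observations") %in% names(tab)))
  if (any(nchar(tab$peptide) < 8L)) stop("ligand peptides must be >= 8 residues")
  if (any(tab$n_observations < 1L)) stop("n_observations must be >= 1")
  tab
}

#' Fraction of a protein covered by database ligands
#'
#' @param protein name of the proteome entry.
#' @param ligandDb table from [readLigandDb()].
#' @param proteome reference [Biostrings::AAStringSet] holding `protein`.
#' @return fraction of residues covered by at least one ligand mapped to
#'   that protein.
#' @export
proteinCoverage <- function(protein, ligandDb, proteome) {
  if (!protein %in% names(proteome)) return(0)
  seqc <- proteome[[protein]]
  peps <- unique(ligandDb$peptide[ligandDb$source_protein == protein])
  if (!length(peps)) return(0)
  hits <- list()
  for (p in peps) {
    m <- matchPattern(p, seqc)
    if (length(m)) hits[[length(hits) + 1L]] <- IRanges(start(m), end(m))
  }
  if (!length(hits)) return(0)
  cov <- reduce(do.call(c, hits))
  sum(width(cov)) / length(seqc)
}

#' Classify the immunopeptidome hotspot overlap of a mutation
#'
#' Over the wild-type forms of the mutation's candidate peptides, per HLA
#' class: `EXACT` when any wild-type form equals a database ligand;
#' otherwise `INCLUDED` when any wild-type form is a proper substring of a
#' ligand or properly contains one; otherwise `PARTIAL` when any wild-type
#' form overlaps, by at least `minOverlap` residues, a ligand mapped to the
#' same source protein; otherwise `NONE`. The best applicable category is
#' reported (EXACT > INCLUDED > PARTIAL > NONE).
#'
#' @param context one context row ([buildContexts()]).
#' @param candidates candidates of that mutation (both classes).
#' @param ligandDb table from [readLigandDb()].
#' @param proteome reference [Biostrings::AAStringSet] (entry names match
#'   `ligandDb$source_protein`).
#' @param minOverlap minimum same-protein overlap for `PARTIAL` (default 5).
#' @return list with elements `I`, `II` (categories) and `coverage` (the
#'   source protein's ligand coverage fraction).
#' @export
classifyIpmsdbOverlap <- function(context, candidates, ligandDb, proteome,
                                  minOverlap = 5L) {
  protName <- names(proteome)[startsWith(names(proteome),
                                         paste0(context$transcript_id, "|"))]
  protName <- protName[1]
  offset <- context$aa_pos - context$mutated_index  # context idx -> protein pos - offset
  res <- list(I = "NONE", II = "NONE",
              coverage = if (!is.na(protName))
                proteinCoverage(protName, ligandDb, proteome) else 0)
  for (cl in c("I", "II")) {
    cand <- candidates[candidates$hla_class == cl &
                       candidates$mutation_id == context$mutation_id, ,
                       drop = FALSE]
    if (!nrow(cand)) next
    wt <- unique(cand[, c("wt_sequence", "context_start", "length")])
    db <- ligandDb[ligandDb$hla_class == cl, , drop = FALSE]
    if (!nrow(db)) next
    if (any(wt$wt_sequence %in% db$peptide)) { res[[cl]] <- "EXACT"; next }
    included <- FALSE
    for (w in unique(wt$wt_sequence)) {
      if (any(vapply(db$peptide, function(p)
        (nchar(p) > nchar(w) && grepl(w, p, fixed = TRUE)) ||
        (nchar(p) < nchar(w) && grepl(p, w, fixed = TRUE)),
        logical(1)))) { included <- TRUE; break }
    }
    if (included) { res[[cl]] <- "INCLUDED"; next }
    if (is.na(protName)) next
    same <- db[db$source_protein == protName, , drop = FALSE]
    if (!nrow(same)) next
    partial <- FALSE
    for (p in unique(same$peptide)) {
      m <- matchPattern(p, proteome[[protName]])
      if (!length(m)) next
      for (k in seq_along(m)) {
        ls <- start(m)[k]; le <- end(m)[k]
        ws <- wt$context_start + offset
        we <- ws + wt$length - 1L
        ov <- pmin(we, le) - pmax(ws, ls) + 1L
        if (any(ov >= minOverlap)) { partial <- TRUE; break }
      }
      if (partial) break
    }
    if (partial) res[[cl]] <- "PARTIAL"
  }
  res
}

#' Filter mutations underrepresented in the ligand database
#'
#' Drops a mutation when its source protein's ligand coverage fraction is
#' below the threshold. The default threshold of 0 leaves the filter inert.
#'
#' @param mutations data.frame with a `transcript_id` column.
#' @param ligandDb table from [readLigandDb()].
#' @param proteome reference [Biostrings::AAStringSet].
#' @param threshold minimum coverage fraction (default 0).
#' @return the retained rows, with an added `db_coverage` column.
#' @export
filterUnderrepresented <- function(mutations, ligandDb, proteome,
                                   threshold = 0) {
  if (nrow(mutations) == 0L) { mutations$db_coverage <- numeric(0); return(mutations) }
  cov <- vapply(seq_len(nrow(mutations)), function(i) {
    nm <- names(proteome)[startsWith(names(proteome),
                                     paste0(mutations$transcript_id[i], "|"))]
    if (!length(nm)) return(0)
    proteinCoverage(nm[1], ligandDb, proteome)
  }, numeric(1))
  mutations$db_coverage <- cov
  mutations[cov >= threshold, , drop = FALSE]
}
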
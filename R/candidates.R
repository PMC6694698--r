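# Candidate epitope enumeration, scoring (built-in PWM or external tables)
# and binder calls.

.candidateCols <- function() {
  data.frame(mutation_id = character(0), hla_class = character(0),
             context_start = integer(0), length = integer(0),
             sequence = character(0), wt_sequence = character(0),
             covers_mutation = logical(0))
}

#' Enumerate mutation-spanning candidate peptides from contexts
#'
#' All windows of the class's allowed lengths (class I: 9-12, class II:
#' 12-19) whose span includes the mutated residue. The wild-type form of
#' each window is carried along for ligand-database matching and the
#' wild-type identity filter.
#'
#' @param contexts context data.frame from [buildContexts()].
#' @param hlaClass `"I"` or `"II"`.
#' @param lengths window lengths; defaults to the class bounds.
#' @return data.frame: `mutation_id`, `hla_class`, `context_start`
#'   (1-based in the context), `length`, `sequence`, `wt_sequence`,
#'   `covers_mutation` (always `TRUE` for retained candidates).
#' @export
enumerateCandidates <- function(contexts, hlaClass = c("I", "II"),
                                lengths = NULL) {
  hlaClass <- match.arg(hlaClass)
  if (is.null(lengths)) lengths <- if (hlaClass == "I") 9:12 else 12:19
  out <- list()
  for (i in seq_len(nrow(contexts))) {
    ctx <- contexts$mutant_seq[i]
    wt <- contexts$wt_seq[i]
    mi <- contexts$mutated_index[i]
    Lctx <- nchar(ctx)
    if (Lctx < min(lengths)) {
      warning("context ", contexts$mutation_id[i], " shorter than ",
              min(lengths), " residues; no class ", hlaClass, " candidates")
      next
    }
    for (L in lengths) {
      if (L > Lctx) next
      starts <- max(1L, mi - L + 1L):min(mi, Lctx - L + 1L)
      starts <- starts[starts >= 1L]
      if (!length(starts)) next
      out[[length(out) + 1L]] <- data.frame(
        mutation_id = contexts$mutation_id[i], hla_class = hlaClass,
        context_start = starts, length = L,
        sequence = substring(ctx, starts, starts + L - 1L),
        wt_sequence = substring(wt, starts,
                                pmin(starts + L - 1L, nchar(wt))),
        covers_mutation = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.candidateCols())
  do.call(rbind, out)
}

#' Score candidates against a set of PWM models
#'
#' Each model of matching HLA class scores every candidate of that class;
#' percentile ranks and p-values come from the model's decoy calibration.
#'
#' @param candidates [enumerateCandidates()] output (classes may be mixed).
#' @param models named list of [PwmModel-class] objects.
#' @return long data.frame: candidate columns plus `allele`, `score`,
#'   `percent_rank`, `p_value`.
#' @export
scoreCandidates <- function(candidates, models) {
  out <- list()
  for (model in models) {
    sel <- candidates$hla_class == model@hlaClass
    if (!any(sel)) next
    cc <- candidates[sel, , drop = FALSE]
    sc <- suppressWarnings(scorePwm(cc$sequence, model))
    cal <- calibratePercentRank(sc, model, nchar(cc$sequence))
    cc$allele <- model@allele
    cc$score <- sc
    cc$percent_rank <- cal$percent_rank
    cc$p_value <- cal$p_value
    out[[length(out) + 1L]] <- cc
  }
  if (!length(out)) {
    cc <- .candidateCols()
    cc$allele <- character(0); cc$score <- numeric(0)
    cc$percent_rank <- numeric(0); cc$p_value <- numeric(0)
    return(cc)
  }
  do.call(rbind, out)
}

#' Attach externally computed predictor scores
#'
#' Adapter for published predictor outputs: a TSV with columns `peptide`,
#' `allele`, `score`, `percent_rank` and optionally `p_value` (defaulted to
#' `percent_rank / 100`). Candidates with no table row for any allele are
#' flagged unscored and excluded from binder calls.
#'
#' @param path score table path.
#' @param candidates [enumerateCandidates()] output.
#' @return long data.frame as in [scoreCandidates()]; unscored candidates
#'   are listed in `attr(result, "unscored")`.
#' @export
loadExternalScores <- function(path, candidates) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "score", "percent_rank")
  if (!all(need %in% names(tab)))
    stop("external score table must have columns: ",
         paste(need, collapse = ", "))
  if (!"p_value" %in% names(tab)) tab$p_value <- tab$percent_rank / 100
  key <- paste(tab$peptide, tab$allele)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflicting <- vapply(unique(dup), function(k) {
      g <- tab[key == k, c("score", "percent_rank", "p_value")]
      nrow(unique(g)) > 1L
    }, logical(1))
    if (any(conflicting))
      stop("conflicting duplicate (peptide, allele) rows in ", path, ": ",
           paste(names(conflicting)[conflicting], collapse = "; "))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  out <- list()
  scoredAny <- rep(FALSE, nrow(candidates))
  for (al in unique(tab$allele)) {
    sub <- tab[tab$allele == al, , drop = FALSE]
    hit <- match(candidates$sequence, sub$peptide)
    sel <- !is.na(hit)
    if (!any(sel)) next
    scoredAny <- scoredAny | sel
    cc <- candidates[sel, , drop = FALSE]
    cc$allele <- al
    cc$score <- sub$score[hit[sel]]
    cc$percent_rank <- sub$percent_rank[hit[sel]]
    cc$p_value <- sub$p_value[hit[sel]]
    out[[length(out) + 1L]] <- cc
  }
  res <- if (length(out)) do.call(rbind, out) else {
    cc <- .candidateCols()
    cc$allele <- character(0); cc$score <- numeric(0)
    cc$percent_rank <- numeric(0); cc$p_value <- numeric(0)
    cc
  }
  unscored <- unique(candidates$sequence[!scoredAny])
  if (length(unscored))
    warning(length(unscored),
            " candidate peptide(s) missing from the score table; ",
            "flagged unscored and excluded from binder calls")
  attr(res, "unscored") <- unscored
  res
}

#' Call predicted binders
#'
#' A candidate is a predicted binder when its percentile rank is below the
#' cutoff (default 5, strict `<`; `strict = FALSE` switches to `<=`) for at
#' least one allele, or when the wild-type form of the peptide is an exact
#' ligand-database match of the same HLA class.
#'
#' @param candidates [enumerateCandidates()] output.
#' @param scores long score table from [scoreCandidates()] or
#'   [loadExternalScores()].
#' @param ligandDb optional ligand database from [readLigandDb()].
#' @param cutoff percentile-rank cutoff (default 5).
#' @param strict logical, strict inequality (default `TRUE`).
#' @return `candidates` with added columns `best_rank`, `p_value` (minimum
#'   across alleles), `binder_alleles` (comma-separated alleles passing the
#'   rank rule), `db_match` and `is_binder`.
#' @export
callBinders <- function(candidates, scores, ligandDb = NULL, cutoff = 5,
                        strict = TRUE) {
  n <- nrow(candidates)
  key <- paste(candidates$mutation_id, candidates$hla_class,
               candidates$context_start, candidates$length)
  skey <- paste(scores$mutation_id, scores$hla_class,
                scores$context_start, scores$length)
  best_rank <- rep(NA_real_, n)
  p_value <- rep(NA_real_, n)
  binder_alleles <- character(n)
  pass <- if (strict) function(r) r < cutoff else function(r) r <= cutoff
  idx <- split(seq_len(nrow(scores)), skey)
  for (i in seq_len(n)) {
    j <- idx[[key[i]]]
    if (is.null(j)) next
    r <- scores$percent_rank[j]
    if (all(is.na(r))) next
    best_rank[i] <- min(r, na.rm = TRUE)
    p_value[i] <- min(scores$p_value[j], na.rm = TRUE)
    ok <- !is.na(r) & pass(r)
    binder_alleles[i] <- paste(sort(unique(scores$allele[j][ok])),
                               collapse = ",")
  }
  db_match <- rep(FALSE, n)
  if (!is.null(ligandDb) && nrow(ligandDb)) {
    for (cl in unique(candidates$hla_class)) {
      peps <- ligandDb$peptide[ligandDb$hla_class == cl]
      sel <- candidates$hla_class == cl
      db_match[sel] <- candidates$wt_sequence[sel] %in% peps
    }
  }
  # candidates without any score (dropped peptides, rows missing from an
  # external table) are excluded from binder calls entirely
  scored <- !is.na(best_rank)
  unscored <- attr(scores, "unscored")
  if (!is.null(unscored)) scored <- scored & !(candidates$sequence %in% unscored)
  candidates$best_rank <- best_rank
  candidates$p_value <- p_value
  candidates$binder_alleles <- binder_alleles
  candidates$db_match <- db_match
  isb <- scored & (pass(best_rank) | db_match)
  isb[is.na(isb)] <- FALSE
  candidates$is_binder <- isb
  candidates
}
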
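# Built-in PWM scorer with decoy calibration, plus PWM matrix file I/O.

.aaIndexMatrix <- function(peptides) {
  # peptides of equal length -> integer matrix of residue indices (n x L)
  L <- nchar(peptides[1])
  m <- matrix(match(unlist(strsplit(peptides, "")), AA_STANDARD),
              ncol = L, byrow = TRUE)
  m
}

.scoreClassI <- function(idx, M) {
  # idx: n x L residue-index matrix; M: L x 20 weight matrix
  s <- numeric(nrow(idx))
  for (j in seq_len(ncol(idx))) s <- s + M[j, idx[, j]]
  s
}

.scoreClassII <- function(idx, M) {
  # best 9-mer core under the 9 x 20 core matrix
  L <- ncol(idx)
  if (L < 9L) stop("class II scoring requires peptides of length >= 9")
  best <- rep(-Inf, nrow(idx))
  for (o in 0:(L - 9L)) {
    s <- numeric(nrow(idx))
    for (j in 1:9) s <- s + M[j, idx[, j + o]]
    best <- pmax(best, s)
  }
  best
}

#' Construct a PwmModel with decoy calibration
#'
#' Builds the per-allele scorer and its decoy score distributions. Decoys
#' are `decoyN` peptides per length drawn i.i.d. from the background
#' amino-acid frequencies under a fixed seed, so percentile ranks are
#' reproducible.
#'
#' @param allele allele name.
#' @param hlaClass `"I"` or `"II"`.
#' @param matrices class I: named list of length-L-by-20 matrices, names =
#'   peptide lengths; class II: list(core = 9-by-20 matrix). Columns must be
#'   [AA_STANDARD].
#' @param seed decoy RNG seed.
#' @param decoyN decoys per length (default 100000).
#' @param decoyLengths peptide lengths to calibrate; defaults to the matrix
#'   lengths (class I) or 12:19 (class II).
#' @param background length-20 sampling weights (default uniform).
#' @return A [PwmModel-class].
#' @export
pwmModel <- function(allele, hlaClass = c("I", "II"), matrices,
                     seed = 20240001L, decoyN = 100000L,
                     decoyLengths = NULL,
                     background = rep(1 / 20, 20)) {
  hlaClass <- match.arg(hlaClass)
  if (is.null(decoyLengths))
    decoyLengths <- if (hlaClass == "I") as.integer(names(matrices)) else 12:19
  decoys <- .withSeed(seed, {
    out <- list()
    for (L in sort(as.integer(decoyLengths))) {
      idx <- matrix(sample.int(20L, decoyN * L, replace = TRUE,
                               prob = background), ncol = L)
      s <- if (hlaClass == "I") .scoreClassI(idx, matrices[[as.character(L)]])
           else .scoreClassII(idx, matrices[["core"]])
      out[[as.character(L)]] <- sort(s)
    }
    out
  })
  new("PwmModel", allele = allele, hlaClass = hlaClass,
      matrices = matrices, decoys = decoys, decoyN = as.integer(decoyN),
      seed = as.integer(seed), background = background)
}

#' Score peptides with a PWM model
#'
#' Class I peptides are scored as the sum of position weights under the
#' matrix of their length; class II peptides as the maximum 9-mer core score.
#' Peptides containing non-standard residues, or class I peptides of a
#' length without a matrix, score `NA` with a warning (they are dropped from
#' binder calls downstream).
#'
#' @param peptides character vector.
#' @param model a [PwmModel-class].
#' @return numeric score vector aligned with `peptides`.
#' @export
scorePwm <- function(peptides, model) {
  scores <- rep(NA_real_, length(peptides))
  ok <- .isStandardPeptide(peptides)
  if (any(!ok) && length(peptides))
    warning(sum(!ok), " peptide(s) with non-standard residues dropped")
  lens <- nchar(peptides)
  for (L in unique(lens[ok])) {
    sel <- ok & lens == L
    if (model@hlaClass == "I") {
      M <- model@matrices[[as.character(L)]]
      if (is.null(M)) {
        warning("no class I matrix for length ", L, "; peptides dropped")
        next
      }
      scores[sel] <- .scoreClassI(.aaIndexMatrix(peptides[sel]), M)
    } else {
      if (L < 9L) {
        warning("class II peptides must be >= 9 residues; dropped")
        next
      }
      scores[sel] <- .scoreClassII(.aaIndexMatrix(peptides[sel]),
                                   model@matrices[["core"]])
    }
  }
  scores
}

#' Percentile rank and p-value of scores against the decoy distribution
#'
#' `percent_rank` is 100 times the fraction of decoys scoring at least the
#' query score; `p_value = percent_rank / 100`. Deterministic given the
#' model's decoy seed.
#'
#' @param scores numeric scores.
#' @param model a [PwmModel-class].
#' @param lengths peptide length per score (scalar or vector).
#' @return data.frame with `percent_rank` and `p_value`.
#' @export
calibratePercentRank <- function(scores, model, lengths) {
  lengths <- rep_len(lengths, length(scores))
  pr <- rep(NA_real_, length(scores))
  for (L in unique(lengths)) {
    d <- model@decoys[[as.character(L)]]
    if (is.null(d) || !length(d))
      stop("no decoy distribution for allele ", model@allele,
           ", length ", L, " (configuration error)")
    sel <- which(lengths == L & !is.na(scores))
    if (!length(sel)) next
    nBelow <- findInterval(scores[sel], d, left.open = TRUE)
    pr[sel] <- 100 * (length(d) - nBelow) / length(d)
  }
  data.frame(percent_rank = pr, p_value = pr / 100)
}

#' Write / read a PWM matrix TSV
#'
#' Plain TSV: first column `pos`, then one column per residue in
#' [AA_STANDARD] order.
#'
#' @param M numeric matrix (positions x 20).
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
writePwmMatrix <- function(M, path) {
  df <- data.frame(pos = seq_len(nrow(M)), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePwmMatrix
#' @export
readPwmMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  M <- as.matrix(df[, AA_STANDARD, drop = FALSE])
  rownames(M) <- NULL
  M
}

#' Read the PWM models of a fixture/pipeline bundle
#'
#' Expects `<dir>/<allele>_L<len>.tsv` matrices for class I alleles and
#' `<dir>/<allele>_core.tsv` for class II alleles.
#'
#' @param dir PWM directory.
#' @param hla data.frame with columns `allele`, `hla_class`.
#' @param seed,decoyN decoy calibration parameters.
#' @return named list of [PwmModel-class] objects.
#' @export
readPwmModels <- function(dir, hla, seed = 20240001L, decoyN = 100000L) {
  models <- list()
  for (i in seq_len(nrow(hla))) {
    al <- hla$allele[i]; cl <- hla$hla_class[i]
    if (cl == "I") {
      files <- Sys.glob(file.path(dir, paste0(al, "_L*.tsv")))
      if (!length(files)) stop("no PWM files for allele ", al, " in ", dir)
      lens <- as.integer(sub(".*_L(\\d+)\\.tsv$", "\\1", files))
      mats <- setNames(lapply(files, readPwmMatrix), as.character(lens))
      mats <- mats[order(as.integer(names(mats)))]
    } else {
      f <- file.path(dir, paste0(al, "_core.tsv"))
      if (!file.exists(f)) stop("no core PWM file for allele ", al)
      mats <- list(core = readPwmMatrix(f))
    }
    models[[al]] <- pwmModel(al, cl, mats, seed = seed + i, decoyN = decoyN)
  }
  models
}
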
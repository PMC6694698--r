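# Shared small helpers: amino-acid tables, HGVS formatting, allele
# normalization. Coordinates are 1-based inclusive everywhere at the R level;
# VCF/GFF3 I/O is 1-based by convention.

#' The twenty standard amino acids
#'
#' One-letter codes, alphabetical.
#' @export
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          "*" = "Ter")

#' Protein-level HGVS label for a substitution
#'
#' @param wt,mut one-letter amino acid codes.
#' @param pos 1-based protein position.
#' @return Character such as `"p.Tyr749Asp"`.
#' @export
hgvsP <- function(wt, pos, mut) {
  paste0("p.", .AA3[wt], pos, .AA3[mut])
}

.hgvsFs <- function(wt, pos) paste0("p.", .AA3[wt], pos, "fs")

.translateCodon <- function(codon) {
  unname(GENETIC_CODE[toupper(codon)])
}

.translateCds <- function(nt) {
  # translate full codons only; returns one-letter string without a trailing
  # stop; premature internal stops are preserved as '*'
  nt <- toupper(nt)
  ncod <- nchar(nt) %/% 3L
  if (ncod == 0L) return("")
  codons <- substring(nt, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- unname(GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa <- paste(aa, collapse = "")
  sub("\\*$", "", aa)
}

.revcomp <- function(nt) {
  as.character(reverseComplement(DNAString(nt)))
}

.complement <- function(nt) {
  chartr("ACGTacgt", "TGCAtgca", nt)
}

# Left-normalize an allele pair: strip shared suffix then shared prefix while
# keeping at least one base on each side; `pos` moves right past the stripped
# prefix. Makes equality across callers well defined.
.normalizeAllele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

.variantId <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.substrReplace <- function(x, at, value) {
  # replace length(value) characters of x starting at `at`
  paste0(substr(x, 1L, at - 1L), value,
         substr(x, at + nchar(value), nchar(x)))
}

.isStandardPeptide <- function(x) {
  !is.na(x) & nzchar(x) & !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), x)
}

# run code under a temporary RNG state derived from `seed`, restoring the
# caller's RNG afterwards so library calls stay referentially transparent
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
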
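# Reading per-caller VCFs into caller call sets.

.CALLERS <- c("gatk", "mutect", "varscan")

.parseGt <- function(gt) {
  # returns list(alleles = integer vector, phased = logical)
  if (is.na(gt) || gt %in% c(".", "./.", ".|.", ""))
    return(list(alleles = integer(0), phased = FALSE))
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  suppressWarnings(al <- as.integer(parts))
  list(alleles = al[!is.na(al)], phased = phased)
}

#' Build a caller call set from a data frame
#'
#' Programmatic constructor used by tests and simulations; [readCallerVcf()]
#' produces the same representation from a VCF file. One row per ALT allele.
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt`, and
#'   optionally `in_tumor`, `in_germline` (default `TRUE`/`FALSE`), `phased`,
#'   `hap` (1 or 2, haplotype side carrying the ALT), `phase_set`.
#' @param caller one of `"gatk"`, `"mutect"`, `"varscan"`.
#' @return A [GenomicRanges::GRanges] with the caller-variant metadata
#'   columns, alleles left-normalized.
#' @export
callerCallSet <- function(df, caller = c("gatk", "mutect", "varscan")) {
  caller <- match.arg(caller)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  n <- nrow(df)
  fill <- function(col, default) if (col %in% names(df)) df[[col]] else rep(default, n)
  pos <- as.integer(df$pos)
  ref <- toupper(as.character(df$ref)); alt <- toupper(as.character(df$alt))
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (any(!nzchar(ref)) || any(!nzchar(alt)) || any(ref == alt))
    stop("ref and alt must be nonempty and different")
  norm <- Map(.normalizeAllele, pos, ref, alt)
  pos <- vapply(norm, `[[`, integer(1), "pos")
  ref <- vapply(norm, `[[`, character(1), "ref")
  alt <- vapply(norm, `[[`, character(1), "alt")
  gr <- GRanges(df$chrom, IRanges(pos, width = nchar(ref)))
  mcols(gr) <- DataFrame(
    caller = rep(caller, n), ref = ref, alt = alt,
    in_tumor = as.logical(fill("in_tumor", TRUE)),
    in_germline = as.logical(fill("in_germline", FALSE)),
    phased = as.logical(fill("phased", FALSE)),
    hap = as.integer(fill("hap", NA_integer_)),
    phase_set = as.character(fill("phase_set", NA_character_)))
  gr
}

#' Read one caller's VCF into a caller call set
#'
#' Parses a VCF 4.x file with tumor and germline sample columns into one
#' record per ALT allele (multi-allelic records are split). Presence in
#' tumor/germline is taken from the genotypes; phased genotypes (`|`
#' separator) with a `PS` tag contribute phase-set and haplotype-side
#' annotations used later for linked-SNP attachment.
#'
#' @param path VCF file path.
#' @param caller caller identity of the file.
#' @param tumor,germline sample column names.
#' @return A [GenomicRanges::GRanges] as in [callerCallSet()], containing the
#'   variants present in at least one of the two samples.
#' @examples
#' \dontrun{readCallerVcf("mutect.vcf", "mutect", "TUMOR", "NORMAL")}
#' @export
readCallerVcf <- function(path, caller = c("gatk", "mutect", "varscan"),
                          tumor = "TUMOR", germline = "NORMAL") {
  caller <- match.arg(caller)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(suppressWarnings(readVcf(path, genome = "toy")),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  smp <- colnames(vcf)
  missing <- setdiff(c(tumor, germline), smp)
  if (length(missing))
    stop("VCF '", path, "' lacks sample column(s): ",
         paste(missing, collapse = ", "),
         " (configured tumor/germline sample names must match the header)")
  rr <- rowRanges(vcf)
  gt <- geno(vcf)$GT
  ps <- if ("PS" %in% names(geno(vcf))) geno(vcf)$PS else NULL
  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    ref <- as.character(rr$REF[i])
    alts <- as.character(rr$ALT[[i]])
    alts <- alts[nzchar(alts) & alts != "."]
    if (!length(alts)) next
    tgt <- .parseGt(gt[i, tumor]); ggt <- .parseGt(gt[i, germline])
    pset <- if (!is.null(ps)) ps[i, tumor] else NA
    pset <- if (is.na(pset)) NA_character_ else as.character(pset)
    rows <- lapply(seq_along(alts), function(a) {
      in_t <- a %in% tgt$alleles
      in_g <- a %in% ggt$alleles
      if (!in_t && !in_g) return(NULL)
      hap <- NA_integer_
      phased <- tgt$phased && !is.na(pset)
      if (phased && in_t && length(tgt$alleles) == 2L) {
        sides <- which(tgt$alleles == a)
        if (length(sides) == 1L) hap <- sides else phased <- FALSE
      }
      data.frame(chrom = as.character(seqnames(rr)[i]),
                 pos = start(rr)[i], ref = ref, alt = alts[a],
                 in_tumor = in_t, in_germline = in_g,
                 phased = phased, hap = hap,
                 phase_set = if (phased) pset else NA_character_)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(caller = character(0), ref = character(0),
                           alt = character(0), in_tumor = logical(0),
                           in_germline = logical(0), phased = logical(0),
                           hap = integer(0), phase_set = character(0))
    return(gr)
  }
  callerCallSet(out, caller)
}
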
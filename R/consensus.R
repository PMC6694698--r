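# Non-redundant consensus call set: union of three callers, majority-rule
# conflict resolution at shared coordinates, somatic/germline classification,
# high-confidence selection and phased linked-SNP attachment.

.callsetToDf <- function(gr) {
  if (length(gr) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      caller = character(0), in_tumor = logical(0),
                      in_germline = logical(0), phased = logical(0),
                      hap = integer(0), phase_set = character(0)))
  }
  data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
             ref = mcols(gr)$ref, alt = mcols(gr)$alt,
             caller = mcols(gr)$caller, in_tumor = mcols(gr)$in_tumor,
             in_germline = mcols(gr)$in_germline, phased = mcols(gr)$phased,
             hap = mcols(gr)$hap, phase_set = mcols(gr)$phase_set)
}

#' Merge three caller call sets into a consensus set
#'
#' Builds the union of the variants of all callers, keyed on
#' (chrom, pos, ref, alt). Identical calls accumulate supporters. At a
#' genomic coordinate where callers report different (ref, alt) alleles, a
#' variant is kept only when its supporters form a strict majority of the
#' callers reporting anything at that coordinate; coordinates with no such
#' majority are rejected entirely (recorded in
#' `metadata(result)$rejected`). Insertions/deletions at the same position
#' count as conflicting calls, and alleles are left-normalized beforehand so
#' that equality is well defined.
#'
#' @param callsets list of caller call sets from [readCallerVcf()] or
#'   [callerCallSet()] (typically three, one per caller).
#' @return A [GenomicRanges::GRanges] of consensus variants with columns
#'   `variant_id`, `ref`, `alt`, `supporters` (a CharacterList),
#'   `in_tumor`, `in_germline`, `phased`, `hap`, `phase_set`.
#' @export
mergeCallSets <- function(callsets) {
  df <- do.call(rbind, lapply(callsets, .callsetToDf))
  if (nrow(df) == 0L) {
    gr <- GRanges()
    metadata(gr)$rejected <- data.frame(chrom = character(0), pos = integer(0))
    return(gr)
  }
  df$vkey <- .variantId(df$chrom, df$pos, df$ref, df$alt)
  # per (caller, variant): collapse duplicate records
  dd <- !duplicated(paste(df$caller, df$vkey))
  per <- df[dd, , drop = FALSE]
  # per variant: supporters and pooled presence/phase
  agg <- split(per, per$vkey)
  vs <- lapply(agg, function(g) {
    ph <- g[g$phased & !is.na(g$phase_set), , drop = FALSE]
    # prefer gatk phasing when several callers phased the site
    if (nrow(ph) > 1L) ph <- ph[order(match(ph$caller, .CALLERS)), , drop = FALSE]
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1],
               supporters = paste(sort(unique(g$caller)), collapse = ","),
               in_tumor = any(g$in_tumor), in_germline = any(g$in_germline),
               phased = nrow(ph) > 0L,
               hap = if (nrow(ph)) ph$hap[1] else NA_integer_,
               phase_set = if (nrow(ph)) ph$phase_set[1] else NA_character_)
  })
  vs <- do.call(rbind, vs)
  vs$nsupp <- lengths(strsplit(vs$supporters, ","))
  # conflict resolution per coordinate
  ckey <- paste(vs$chrom, vs$pos)
  keep <- rep(TRUE, nrow(vs))
  rejected <- list()
  for (co in unique(ckey[duplicated(ckey)])) {
    idx <- which(ckey == co)
    if (length(unique(vs$ref[idx])) > 1L)
      warning("inconsistent REF alleles at ", co,
              "; treated as conflicting calls")
    reporting <- length(unique(unlist(strsplit(vs$supporters[idx], ","))))
    maj <- vs$nsupp[idx] > reporting / 2
    if (!any(maj)) {
      keep[idx] <- FALSE
      rejected[[co]] <- data.frame(chrom = vs$chrom[idx[1]],
                                   pos = vs$pos[idx[1]])
      message("no majority at coordinate ", co, "; call rejected")
    } else {
      keep[idx[!maj]] <- FALSE
    }
  }
  vs <- vs[keep, , drop = FALSE]
  vs <- vs[order(vs$chrom, vs$pos, vs$ref, vs$alt), , drop = FALSE]
  gr <- GRanges(vs$chrom, IRanges(vs$pos, width = nchar(vs$ref)))
  mcols(gr) <- DataFrame(
    variant_id = .variantId(vs$chrom, vs$pos, vs$ref, vs$alt),
    ref = vs$ref, alt = vs$alt,
    supporters = CharacterList(strsplit(vs$supporters, ",")),
    in_tumor = vs$in_tumor, in_germline = vs$in_germline,
    phased = vs$phased, hap = vs$hap, phase_set = vs$phase_set)
  metadata(gr)$rejected <-
    if (length(rejected)) do.call(rbind, unname(rejected))
    else data.frame(chrom = character(0), pos = integer(0))
  gr
}

#' Classify consensus variants as somatic or germline SNP
#'
#' A variant present only in tumor is somatic; a variant present in both
#' tumor and germline is a germline SNP. Presence disagreements across
#' callers are resolved conservatively: germline evidence from any caller
#' makes the variant a germline SNP. Variants seen only in the germline
#' sample are excluded with a warning (they are neither vaccine targets nor
#' linked-SNP candidates).
#'
#' @param gr consensus variants from [mergeCallSets()].
#' @return `gr` with an added `origin` column, germline-only rows removed.
#' @export
classifyOrigin <- function(gr) {
  if (length(gr) == 0L) {
    mcols(gr)$origin <- character(0)
    return(gr)
  }
  germOnly <- !mcols(gr)$in_tumor & mcols(gr)$in_germline
  if (any(germOnly))
    warning(sum(germOnly), " germline-only variant(s) excluded: ",
            paste(mcols(gr)$variant_id[germOnly], collapse = ", "))
  gr <- gr[!germOnly]
  mcols(gr)$origin <- ifelse(mcols(gr)$in_germline, "germline_snp", "somatic")
  gr
}

#' Attach phase-linked germline SNPs to somatic variants
#'
#' A germline SNP is linked to a somatic variant when both are phased, share
#' a phase set and lie on the same haplotype side (same allele). Variants
#' without phase information are never linked.
#'
#' @param gr classified consensus variants (see [classifyOrigin()]).
#' @return `gr` with a `linked_snps` CharacterList column (variant ids of
#'   linked germline SNPs; empty for non-somatic rows).
#' @export
linkPhasedSnps <- function(gr) {
  n <- length(gr)
  linked <- vector("list", n)
  if (n) {
    m <- mcols(gr)
    chrom <- as.character(seqnames(gr))
    for (i in which(m$origin == "somatic" & m$phased)) {
      j <- which(m$origin == "germline_snp" & m$phased &
                 chrom == chrom[i] &
                 m$phase_set == m$phase_set[i] &
                 m$hap == m$hap[i])
      linked[[i]] <- m$variant_id[j]
    }
  }
  linked[vapply(linked, is.null, logical(1))] <- list(character(0))
  mcols(gr)$linked_snps <- CharacterList(linked)
  gr
}

#' Select high-confidence variants for neoantigen prediction
#'
#' Keeps somatic variants detected by MuTect alone or by at least two of the
#' three callers, plus the germline SNPs phase-linked to a retained somatic
#' variant. Linked SNPs inherit retention from their somatic partner; the
#' caller-support rule is not applied to them independently.
#'
#' @param gr consensus variants after [classifyOrigin()] and
#'   [linkPhasedSnps()].
#' @return The retained subset, with a `high_confidence` logical column set
#'   to `TRUE`.
#' @export
selectHighConfidence <- function(gr) {
  if (length(gr) == 0L) {
    mcols(gr)$high_confidence <- logical(0)
    return(gr)
  }
  m <- mcols(gr)
  if (is.null(m$linked_snps)) gr <- linkPhasedSnps(gr)
  m <- mcols(gr)
  hcSom <- m$origin == "somatic" &
    (vapply(m$supporters, function(s) "mutect" %in% s, logical(1)) |
       lengths(m$supporters) >= 2L)
  linkedIds <- unique(unlist(m$linked_snps[hcSom]))
  keep <- hcSom | (m$origin == "germline_snp" & m$variant_id %in% linkedIds)
  out <- gr[keep]
  mcols(out)$high_confidence <- rep(TRUE, length(out))
  out
}

#' Write the merged annotated variant table
#'
#' @param gr consensus variants (any stage after [mergeCallSets()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(gr, path) {
  m <- mcols(gr)
  df <- data.frame(
    chrom = as.character(seqnames(gr)), pos = start(gr),
    ref = m$ref, alt = m$alt,
    supporters = vapply(m$supporters, paste, character(1), collapse = ","),
    origin = if (!is.null(m$origin)) m$origin else NA_character_,
    high_confidence = if (!is.null(m$high_confidence)) m$high_confidence else NA,
    phase_set = m$phase_set,
    check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
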
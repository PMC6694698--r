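# Independent brute-force oracles and toy-input builders used across tests.

# --- majority-rule oracle: explicit loops over the written rule ----------
oracleMajority <- function(calls) {
  out <- list()
  coords <- unique(paste(calls$chrom, calls$pos))
  for (co in coords) {
    sub <- calls[paste(calls$chrom, calls$pos) == co, , drop = FALSE]
    variants <- unique(sub[, c("chrom", "pos", "ref", "alt")])
    reporting <- length(unique(sub$caller))
    for (i in seq_len(nrow(variants))) {
      supp <- sort(unique(sub$caller[sub$ref == variants$ref[i] &
                                     sub$alt == variants$alt[i]]))
      keep <- if (nrow(variants) == 1L) TRUE else length(supp) > reporting / 2
      if (keep) {
        v <- variants[i, , drop = FALSE]
        v$supporters <- paste(supp, collapse = ",")
        out[[length(out) + 1L]] <- v
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      supporters = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos, res$ref, res$alt), , drop = FALSE]
}

randomCallerInstance <- function(nPos = 8L) {
  # random 3-caller SNV call sets over a handful of coordinates
  pos <- sort(sample(1:30, nPos))
  alts <- c("T", "G", "C")
  rows <- list()
  for (p in pos) {
    for (cl in c("gatk", "mutect", "varscan")) {
      if (runif(1) < 0.6) {
        rows[[length(rows) + 1L]] <- data.frame(
          caller = cl, chrom = "1", pos = p, ref = "A",
          alt = sample(alts, 1L), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# --- long-peptide optimizer oracle: explicit triple loop -----------------
oracleDesign <- function(L, spans) {
  best <- NULL
  for (a in seq_len(L)) {
    for (b in a:L) {
      cnt <- 0L
      for (k in seq_len(nrow(spans))) {
        if (spans$start[k] >= a && spans$end[k] <= b) cnt <- cnt + 1L
      }
      if (is.null(best) || cnt > best$cnt ||
          (cnt == best$cnt && (b - a) < (best$b - best$a))) {
        best <- list(a = a, b = b, cnt = cnt)
      }
    }
  }
  best
}

# minimal binder table for designLongPeptide()
makeBinderTable <- function(mutation_id, starts, lengths,
                            hla_class = "I", p = 0.01, alleles = "A0101") {
  data.frame(mutation_id = mutation_id, hla_class = hla_class,
             context_start = starts, length = lengths,
             sequence = vapply(seq_along(starts), function(i)
               paste(sample(AA_STANDARD, lengths[i], replace = TRUE),
                     collapse = ""), character(1)),
             wt_sequence = "", covers_mutation = TRUE,
             best_rank = p * 100, p_value = p,
             binder_alleles = alleles, db_match = FALSE, is_binder = TRUE,
             stringsAsFactors = FALSE)
}

makeContextRow <- function(mutation_id = "TX:p.Ala16Val", seq = NULL,
                           mutated_index = 16L, gene = "G", chrom = "1",
                           pos = 100L) {
  if (is.null(seq))
    seq <- paste(sample(AA_STANDARD, 31, replace = TRUE), collapse = "")
  data.frame(mutation_id = mutation_id, variant_id = mutation_id,
             transcript_id = "TX", gene = gene, chrom = chrom, pos = pos,
             aa_pos = mutated_index, hgvs = "p.Ala16Val",
             mutant_seq = seq, wt_seq = seq, mutated_index = mutated_index,
             linked_edits = "", kind = "snv", flagged = FALSE,
             stringsAsFactors = FALSE)
}

# --- toy transcript files ------------------------------------------------
toyTxFiles <- function(cdsList, strand = NULL, genes = NULL,
                       dir = tempfile("toytx")) {
  dir.create(dir, showWarnings = FALSE)
  if (is.null(strand)) strand <- rep("+", length(cdsList))
  if (is.null(genes)) genes <- paste0("G", seq_along(cdsList))
  ids <- names(cdsList)
  if (is.null(ids)) ids <- paste0("TX", seq_along(cdsList))
  genome <- ""
  gff <- "##gff-version 3"
  starts <- integer(length(cdsList))
  for (i in seq_along(cdsList)) {
    genome <- paste0(genome, strrep("C", 10))
    s <- nchar(genome) + 1L
    seg <- cdsList[[i]]
    if (strand[i] == "-")
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    genome <- paste0(genome, seg)
    e <- nchar(genome)
    starts[i] <- s
    gff <- c(gff,
      sprintf("chr1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
              s, e, strand[i], genes[i], genes[i]),
      sprintf("chr1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;gene_name=%s",
              s, e, strand[i], ids[i], genes[i], genes[i]),
      sprintf("chr1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=CDS:%s;Parent=%s",
              s, e, strand[i], ids[i], ids[i]))
  }
  genome <- paste0(genome, strrep("C", 10))
  fa <- file.path(dir, "genome.fa")
  gset <- Biostrings::DNAStringSet(genome); names(gset) <- "chr1"
  Biostrings::writeXStringSet(gset, fa)
  gffPath <- file.path(dir, "ann.gff3")
  writeLines(gff, gffPath)
  list(gff = gffPath, fasta = fa, start = starts, dir = dir)
}

# --- tiny VCF writer -----------------------------------------------------
writeTestVcf <- function(path, rows, samples = c("TUMOR", "NORMAL")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=100000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    ps <- if (is.null(rows$ps) || is.na(rows$ps[i])) "." else rows$ps[i]
    paste(c("1", rows$pos[i], ".", rows$ref[i], rows$alt[i], ".", "PASS",
            ".", "GT:PS", paste0(rows$gt_t[i], ":", ps),
            paste0(rows$gt_n[i], ":.")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

# a random-protein transcript plus one planted missense SNV
randomMissenseCase <- function(protLen = 120L, aaPos = NULL) {
  aa <- sample(setdiff(AA_STANDARD, "M"), protLen - 1L, replace = TRUE)
  prot <- c("M", aa)
  codons <- unname(neovax:::.FX_CODON[prot])
  if (is.null(aaPos)) aaPos <- sample(2:protLen, 1L)
  # mutate codon GCT -> GTT when possible; otherwise force the site to Ala
  prot[aaPos] <- "A"; codons[aaPos] <- "GCT"
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  f <- toyTxFiles(list(TX1 = cds))
  tx <- loadTranscripts(f$gff, f$fasta)
  pos <- f$start[1] + 3L * (aaPos - 1L) + 1L  # codon offset 2
  v <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos))
  S4Vectors::mcols(v) <- S4Vectors::DataFrame(
    variant_id = paste0("chr1:", pos, ":C:T"), ref = "C", alt = "T",
    origin = "somatic")
  list(tx = tx, v = v, aaPos = aaPos, cds = cds, f = f)
}

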
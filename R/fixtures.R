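# Seeded synthetic cohorts with planted ground truth.
#
# The toy genome is a single plus-strand chromosome of one-exon genes. The
# background proteome is drawn from the 18 residues excluding W and M (start
# codons aside), and the fixture PWMs are anchor-indicator matrices on W
# (class I) and M (class II). Planted mutations therefore fall into clean
# score tiers -- 0 anchors (never a binder), 2 anchors (binder, %Rank well
# below the cutoff) and 3 anchors (the engineered best mutation, strictly
# the lowest %Rank) -- and the expected pipeline outcome is known by
# construction for any seed.

.FX_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
               M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACA", V = "GTT", W = "TGG", Y = "TAT")
.FX_BG <- setdiff(AA_STANDARD, c("W", "M"))
.FX_ANCHOR_W <- 6  # anchor weight; dominates the zero base weights

.fxGeneName <- function(i) sprintf("GENE%02d", i)
.fxTxName <- function(i) sprintf("TX%02d", i)

# one planted somatic/germline variant; type: LW (Leu TTG -> Trp TGG),
# AV (Ala GCT -> Val GTT), AG (Ala GCT -> Gly GGT), syn (GCT -> GCC)
.fxVariantNt <- function(type) {
  switch(type,
         LW = list(refCodon = "TTG", offset = 2L, ref = "T", alt = "G",
                   refAa = "L", mutAa = "W"),
         AV = list(refCodon = "GCT", offset = 2L, ref = "C", alt = "T",
                   refAa = "A", mutAa = "V"),
         AG = list(refCodon = "GCT", offset = 2L, ref = "C", alt = "G",
                   refAa = "A", mutAa = "G"),
         syn = list(refCodon = "GCT", offset = 3L, ref = "T", alt = "C",
                    refAa = "A", mutAa = "A"),
         stop("unknown planted variant type ", type))
}

.fxWriteVcf <- function(path, rows, caller, contigLen) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=1,length=%d>", contigLen),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  sel <- vapply(rows$callers, function(x) caller %in% strsplit(x, ",")[[1]],
                logical(1))
  if (caller == "mutect") sel <- sel & rows$class == "somatic"
  rr <- rows[sel, , drop = FALSE]
  rr <- rr[order(rr$pos), , drop = FALSE]
  lines <- character(nrow(rr))
  for (i in seq_len(nrow(rr))) {
    gt_t <- rr$gt_t[i]; gt_n <- rr$gt_n[i]; ps <- rr$ps[i]
    if (caller == "mutect") {  # somatic-only caller, no phasing emitted
      gt_t <- gsub("|", "/", gt_t, fixed = TRUE)
      ps <- NA
    }
    psStr <- if (is.na(ps)) "." else as.character(ps)
    lines[i] <- paste("1", rr$pos[i], ".", rr$ref[i], rr$alt[i], ".",
                      "PASS", ".", "GT:PS",
                      paste0(gt_t, ":", psStr), paste0(gt_n, ":."),
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Writes a self-consistent input bundle to `dir`: genome FASTA and GFF3
#' annotation, three per-caller VCFs (with planted concordance profiles, a
#' no-majority conflict, a multi-allelic site, phased linked SNPs and a
#' germline-only call), a tissue expression table, a ligand database, PWM
#' motif files, an HLA allotype list, a driver-gene list, an
#' identified-peptides list, a pipeline `config.yaml` and a `truth.json`
#' recording the expected pipeline outcome of every planted variant.
#' Identical seeds give identical bundles.
#'
#' Planted roles (one gene each): the engineered best mutation (three
#' class I anchors plus a class II core, exact ligand-database matches for
#' both classes), a driver-gene binder detected by MuTect alone, a binder in
#' a gene below the expression threshold, a hypermutated gene (5 somatic
#' mutations, one of them a would-be binder), a binder whose strongest
#' 9-mer is duplicated elsewhere in the reference proteome (wild-type
#' identity trap), a binder whose second anchor is contributed by a phased
#' linked germline SNP (with an opposite-haplotype decoy SNP), and a
#' non-binder rescued only by an exact wild-type ligand-database match.
#' Remaining mutations are background passengers.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `dir` and the `truth` list.
#' @export
generateCohort <- function(spec, dir) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pwm"), showWarnings = FALSE)
  .withSeed(spec@seed, .fxGenerate(spec, dir))
}

.fxGenerate <- function(spec, dir) {
  nG <- spec@nGenes
  host <- nG
  linkedOn <- spec@fractionPhasedLinked > 0
  lenR <- spec@proteinLengthRange
  L <- sample(lenR[1]:lenR[2], nG, replace = TRUE)
  prot <- lapply(seq_len(nG), function(g)
    c("M", sample(.FX_BG, L[g] - 1L, replace = TRUE)))
  codon <- lapply(seq_len(nG), function(g) unname(.FX_CODON[prot[[g]]]))

  setRes <- function(g, pos, aa, cod = .FX_CODON[[aa]]) {
    prot[[g]][pos] <<- aa
    codon[[g]][pos] <<- cod
  }

  # --- somatic mutation plan -------------------------------------------
  roleGene <- c(best = 1L, tier2 = 2L, exprTrap = 3L, hyper = 4L,
                wtTrap = 5L, linked = 6L, dbExact = 7L)
  mPos <- integer(nG)
  for (g in roleGene) mPos[g] <- sample(30:(L[g] - 30L), 1L)
  hyperPos <- round(seq(30, L[roleGene["hyper"]] - 30L, length.out = 5L))

  som <- list()
  addSom <- function(gene, aa, type, role, tier, supporters) {
    gene <- as.integer(gene); aa <- as.integer(aa)
    som[[length(som) + 1L]] <<- list(gene = gene, aa = aa, type = type,
                                     role = role, tier = tier,
                                     supporters = supporters)
  }
  all3 <- "gatk,mutect,varscan"
  addSom(roleGene["best"], mPos[roleGene["best"]], "LW", "best", 3L, all3)
  addSom(roleGene["tier2"], mPos[roleGene["tier2"]], "LW", "tier2", 2L,
         "mutect")
  addSom(roleGene["exprTrap"], mPos[roleGene["exprTrap"]], "LW", "exprTrap",
         2L, "gatk,varscan")
  hyperSupp <- c("gatk,mutect", "mutect,varscan", "gatk,varscan", "mutect",
                 all3)
  addSom(roleGene["hyper"], hyperPos[1], "LW", "hyper", 2L, hyperSupp[1])
  for (k in 2:5)
    addSom(roleGene["hyper"], hyperPos[k], "AV", "hyper", 0L, hyperSupp[k])
  addSom(roleGene["wtTrap"], mPos[roleGene["wtTrap"]], "LW", "wtTrap", 2L,
         all3)
  addSom(roleGene["linked"], mPos[roleGene["linked"]], "LW", "linked",
         if (linkedOn) 2L else 0L, "gatk,mutect")
  addSom(roleGene["dbExact"], mPos[roleGene["dbExact"]], "AV", "dbExact",
         0L, "mutect,varscan")

  nRandom <- spec@nSomatic - 11L
  randGenes <- setdiff(8:(nG - 1L), integer(0))
  randSupp <- c(all3, "gatk,mutect", "mutect,varscan", "gatk,varscan",
                "mutect")
  slots <- rep(randGenes, 3L)[seq_len(nRandom)]
  perGene <- table(slots)
  randPos <- list()
  for (g in as.integer(names(perGene)))
    randPos[[as.character(g)]] <- round(seq(30, L[g] - 30L,
                                            length.out = perGene[[as.character(g)]] + 1L))[-1L]
  taken <- integer(length(randGenes)); names(taken) <- randGenes
  for (r in seq_len(nRandom)) {
    g <- slots[r]
    taken[as.character(g)] <- taken[as.character(g)] + 1L
    aa <- if (r == 1L) 5L else randPos[[as.character(g)]][taken[as.character(g)]]
    supp <- if (nRandom >= 2L && r == nRandom) "varscan"
            else if (nRandom >= 2L && r == nRandom - 1L) "gatk"
            else randSupp[(r - 1L) %% length(randSupp) + 1L]
    addSom(g, aa, "AV", "random", 0L, supp)
  }

  # --- planted residues around role mutations --------------------------
  for (i in seq_along(som)) {
    s <- som[[i]]
    nt <- .fxVariantNt(s$type)
    setRes(s$gene, s$aa, nt$refAa, nt$refCodon)
  }
  gB <- roleGene["best"]; mB <- mPos[gB]
  setRes(gB, mB - 3L, "W"); setRes(gB, mB + 4L, "W")      # class I anchors
  setRes(gB, mB - 2L, "M"); setRes(gB, mB + 5L, "M")      # class II core
  for (rl in c("tier2", "exprTrap", "wtTrap")) {
    g <- roleGene[rl]
    setRes(g, mPos[g] - 7L, "W")                          # second anchor
  }
  setRes(roleGene["hyper"], hyperPos[1] - 7L, "W")
  gL <- roleGene["linked"]; mL <- mPos[gL]
  setRes(gL, mL - 7L, "L", "TTG")   # edited to W by the linked SNP
  setRes(gL, mL - 4L, "L", "TTG")   # opposite-haplotype decoy SNP target

  # --- germline SNP plan -----------------------------------------------
  germ <- list()
  addGerm <- function(gene, aa, type, role, gt_t, gt_n, ps, callers) {
    germ[[length(germ) + 1L]] <<- list(gene = gene, aa = aa, type = type,
                                       role = role, gt_t = gt_t,
                                       gt_n = gt_n, ps = ps,
                                       callers = callers)
  }
  psLinked <- 900001L
  if (linkedOn) {
    addGerm(gL, mL - 7L, "LW", "linked_snp", "0|1", "0/1", psLinked,
            "gatk,varscan")
    addGerm(gL, mL - 4L, "LW", "opposite_snp", "1|0", "0/1", psLinked,
            "gatk,varscan")
    nBenign <- min(nRandom, ceiling(spec@fractionPhasedLinked * nRandom))
    benignTargets <- which(vapply(som, function(s)
      s$role == "random" && s$aa >= 30L, logical(1)))
    benignTargets <- head(benignTargets, nBenign)
    for (bi in benignTargets) {
      s <- som[[bi]]
      aa <- s$aa - 5L
      setRes(s$gene, aa, "A")
      addGerm(s$gene, aa, "AV", "benign_linked", "0|1", "0/1",
              900100L + bi, "gatk,varscan")
      som[[bi]]$ps <- 900100L + bi
    }
  }
  setRes(host, 30L, "A"); setRes(host, 60L, "A")
  addGerm(host, 30L, "AV", "unlinked_snp", "0/1", "0/1", NA, "gatk,varscan")
  addGerm(host, 60L, "AV", "unlinked_snp", "0/1", "0/1", NA, "gatk,varscan")

  # synonymous somatic extra (gene 8)
  synGene <- 8L; synAa <- L[synGene] - 20L
  setRes(synGene, synAa, "A")
  # host-gene sites used further down: germline-only call, multi-allelic
  # site, no-majority conflict
  setRes(host, 70L, "A"); setRes(host, 80L, "A"); setRes(host, 90L, "A")

  # wild-type identity trap: embed the trap mutant 9-mer in the host
  gT <- roleGene["wtTrap"]; mT <- mPos[gT]
  trapPep <- prot[[gT]][(mT - 8L):mT]
  trapPep[9L] <- "W"  # the somatic edit
  trapPep <- paste(trapPep, collapse = "")
  for (k in 1:9) setRes(host, 99L + k, substr(trapPep, k, k),
                        .FX_CODON[[substr(trapPep, k, k)]])
  guard <- function(avoid) .FX_BG[.FX_BG != avoid][1]
  setRes(host, 99L, guard(prot[[gT]][mT - 9L]))
  setRes(host, 109L, guard(prot[[gT]][mT + 1L]))

  # --- genome assembly --------------------------------------------------
  spacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  geneStart <- integer(nG)
  pieces <- character(0)
  at <- 1L
  for (g in seq_len(nG)) {
    sp <- spacer(30L)
    pieces <- c(pieces, sp)
    at <- at + 30L
    geneStart[g] <- at
    cdsNt <- paste0(paste(codon[[g]], collapse = ""), "TAA")
    pieces <- c(pieces, cdsNt)
    at <- at + nchar(cdsNt)
  }
  pieces <- c(pieces, spacer(30L))
  genome <- paste(pieces, collapse = "")
  gset <- DNAStringSet(genome); names(gset) <- "1"
  writeXStringSet(gset, file.path(dir, "genome.fa"), width = 70L)

  gpos <- function(g, aa, offset) geneStart[g] + 3L * (aa - 1L) + offset - 1L
  cdsEnd <- function(g) geneStart[g] + 3L * L[g] + 2L  # incl. stop codon

  gff <- c("##gff-version 3")
  for (g in seq_len(nG)) {
    gn <- .fxGeneName(g); tx <- .fxTxName(g)
    s <- geneStart[g]; e <- cdsEnd(g)
    gff <- c(gff,
      paste("1", "neovax", "gene", s, e, ".", "+", ".",
            sprintf("ID=gene:%s;Name=%s", gn, gn), sep = "\t"),
      paste("1", "neovax", "mRNA", s, e, ".", "+", ".",
            sprintf("ID=%s;Parent=gene:%s;gene_name=%s", tx, gn, gn),
            sep = "\t"),
      paste("1", "neovax", "exon", s, e, ".", "+", ".",
            sprintf("Parent=%s", tx), sep = "\t"),
      paste("1", "neovax", "CDS", s, e, ".", "+", "0",
            sprintf("ID=CDS:%s;Parent=%s", tx, tx), sep = "\t"))
  }
  writeLines(gff, file.path(dir, "annotation.gff3"))

  # --- VCF rows ---------------------------------------------------------
  rows <- list()
  addRow <- function(pos, ref, alt, class, callers, gt_t, gt_n, ps = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      pos = pos, ref = ref, alt = alt, class = class, callers = callers,
      gt_t = gt_t, gt_n = gt_n, ps = ps, stringsAsFactors = FALSE)
  }
  somId <- character(length(som))
  for (i in seq_along(som)) {
    s <- som[[i]]
    nt <- .fxVariantNt(s$type)
    pos <- gpos(s$gene, s$aa, nt$offset)
    phasedLinked <- linkedOn && s$role == "linked"
    phasedBenign <- !is.null(s$ps)
    gt_t <- if (phasedLinked || phasedBenign) "0|1" else "0/1"
    ps <- if (phasedLinked) psLinked else if (phasedBenign) s$ps else NA
    addRow(pos, nt$ref, nt$alt, "somatic", s$supporters, gt_t, "0/0", ps)
    somId[i] <- .variantId("1", pos, nt$ref, nt$alt)
    som[[i]]$pos <- pos
    som[[i]]$id <- somId[i]
  }
  germId <- character(length(germ))
  for (i in seq_along(germ)) {
    gm <- germ[[i]]
    nt <- .fxVariantNt(gm$type)
    pos <- gpos(gm$gene, gm$aa, nt$offset)
    addRow(pos, nt$ref, nt$alt, "germline", gm$callers, gm$gt_t, gm$gt_n,
           gm$ps)
    germId[i] <- .variantId("1", pos, nt$ref, nt$alt)
    germ[[i]]$pos <- pos
    germ[[i]]$id <- germId[i]
  }
  # synonymous somatic (all callers)
  synPos <- gpos(synGene, synAa, 3L)
  addRow(synPos, "T", "C", "somatic", all3, "0/1", "0/0")
  synId <- .variantId("1", synPos, "T", "C")
  # germline-only call (excluded with a warning downstream)
  goPos <- gpos(host, 70L, 2L)
  addRow(goPos, "C", "T", "germline_only", "gatk", "0/0", "0/1")
  # multi-allelic germline site (both ALTs kept by the majority rule)
  maPos <- gpos(host, 80L, 2L)
  addRow(maPos, "C", "T,G", "germline", "gatk,varscan", "1/2", "1/2")
  # no-majority conflict: two callers disagree 1 vs 1 -> coordinate rejected
  rjPos <- gpos(host, 90L, 2L)
  addRow(rjPos, "C", "T", "somatic", "gatk", "0/1", "0/0")
  addRow(rjPos, "C", "G", "somatic", "varscan", "0/1", "0/0")
  rowsDf <- do.call(rbind, rows)
  for (cl in .CALLERS)
    .fxWriteVcf(file.path(dir, paste0(cl, ".vcf")), rowsDf, cl,
                nchar(genome))

  # --- expression table -------------------------------------------------
  nS <- spec@nExprSamples
  exprGenes <- setdiff(seq_len(nG), nG - 1L)  # one gene missing on purpose
  expr <- do.call(rbind, lapply(exprGenes, function(g) {
    tp <- if (g == roleGene[["exprTrap"]])
      rlnorm(nS, meanlog = log(0.2), sdlog = 0.2)
    else rlnorm(nS, meanlog = log(20), sdlog = 0.4)
    as.data.frame(c(list(gene = .fxGeneName(g), tissue = spec@tissue),
                    setNames(as.list(round(tp, 3)), paste0("s", seq_len(nS)))))
  }))
  write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- ligand database --------------------------------------------------
  protStr <- vapply(prot, paste, character(1), collapse = "")
  entry <- paste0(.fxTxName(seq_len(nG)), "|", .fxGeneName(seq_len(nG)))
  lig <- list()
  addLig <- function(pep, cl, src) {
    lig[[length(lig) + 1L]] <<- data.frame(
      peptide = pep, hla_class = cl, source_protein = src,
      n_observations = sample(1:40, 1L), stringsAsFactors = FALSE)
  }
  subP <- function(g, from, to) substr(protStr[g], from, to)
  addLig(subP(gB, mB - 4L, mB + 4L), "I", entry[gB])            # EXACT I
  addLig(subP(gB, mB - 7L, mB + 7L), "II", entry[gB])           # EXACT II
  g2 <- roleGene[["tier2"]]
  addLig(subP(g2, mPos[g2] - 4L, mPos[g2] + 3L), "I", entry[g2])  # INCLUDED
  addLig(subP(gT, mT - 12L, mT - 4L), "I", entry[gT])           # PARTIAL
  g7 <- roleGene[["dbExact"]]
  addLig(subP(g7, mPos[g7] - 4L, mPos[g7] + 4L), "I", entry[g7])  # EXACT I
  mutAt <- lapply(seq_len(nG), function(g)
    vapply(Filter(function(s) s$gene == g, som), function(s) s$aa, integer(1)))
  for (k in seq_len(spec@nDbLigands)) {
    g <- sample(c(8:nG), 1L)
    cl <- if (k %% 3L == 0L) "II" else "I"
    w <- if (cl == "I") sample(9:11, 1L) else sample(14:16, 1L)
    ok <- FALSE
    for (try in 1:50) {
      st <- sample(2:(L[g] - w), 1L)
      if (!length(mutAt[[g]]) ||
          all(abs(mutAt[[g]] - st) > w + 25L)) { ok <- TRUE; break }
    }
    if (ok) addLig(subP(g, st, st + w - 1L), cl, entry[g])
  }
  ligDf <- do.call(rbind, lig)
  write.table(ligDf, file.path(dir, "ligands.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- PWM motif files --------------------------------------------------
  mkMat <- function(len, anchors, residue) {
    M <- matrix(0, nrow = len, ncol = 20L,
                dimnames = list(NULL, AA_STANDARD))
    M[anchors, residue] <- .FX_ANCHOR_W
    M
  }
  for (len in 9:12) {
    writePwmMatrix(mkMat(len, c(2L, 5L, 9L), "W"),
                   file.path(dir, "pwm", sprintf("A0101_L%d.tsv", len)))
    writePwmMatrix(mkMat(len, c(2L, 8L), "W"),
                   file.path(dir, "pwm", sprintf("B0702_L%d.tsv", len)))
  }
  writePwmMatrix(mkMat(9L, c(2L, 9L), "M"),
                 file.path(dir, "pwm", "DRB10101_core.tsv"))
  hla <- data.frame(allele = c("A0101", "B0702", "DRB10101"),
                    hla_class = c("I", "I", "II"))
  write.table(hla, file.path(dir, "hla.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- driver list and identified peptides ------------------------------
  drv <- data.frame(gene = c(.fxGeneName(g2), .fxGeneName(9L)),
                    status = c("Driver", "Passenger"))
  write.table(drv, file.path(dir, "drivers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mut2ctx <- function(g, m, cfrom, cto) {
    # mutant context chars cfrom..cto (context coord, mutated index 16)
    p <- prot[[g]]
    p[m] <- .fxVariantNt(Filter(function(s) s$gene == g && s$aa == m,
                                som)[[1]]$type)$mutAa
    paste(p[(m - 16L + cfrom):(m - 16L + cto)], collapse = "")
  }
  obsMut <- mut2ctx(g2, mPos[g2], 10L, 18L)
  obsWt <- subP(host, 10L, 20L)
  obsBad <- "PEPTIDEXZ"
  obsMiss <- "WWWWWWWWW"
  write.table(data.frame(peptide = c(obsMut, obsWt, obsBad, obsMiss)),
              file.path(dir, "identified_peptides.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- config -----------------------------------------------------------
  cfg <- list(tumorSample = "TUMOR", germlineSample = "NORMAL",
              tissue = spec@tissue, tpmThreshold = 1, rankCutoff = 5,
              strictCutoff = TRUE, hypermutatedK = 3, underrepThreshold = 0,
              topN = 10, includeIndels = FALSE,
              decoyN = spec@decoyN, decoySeed = spec@seed + 1000L)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  # --- ground truth -----------------------------------------------------
  isHc <- function(supp) {
    ss <- strsplit(supp, ",")[[1]]
    "mutect" %in% ss || length(ss) >= 2L
  }
  mutTruth <- lapply(som, function(s) {
    nt <- .fxVariantNt(s$type)
    hc <- isHc(s$supporters)
    filt <- if (!hc) "low_confidence"
      else if (s$role == "exprTrap") "expression"
      else if (s$role == "hyper") "hypermutated"
      else "none"
    list(id = s$id, gene = .fxGeneName(s$gene),
         transcript = .fxTxName(s$gene), chrom = "1", pos = s$pos,
         ref = nt$ref, alt = nt$alt, protein_pos = s$aa,
         hgvs = hgvsP(nt$refAa, s$aa, nt$mutAa), role = s$role,
         tier = s$tier, supporters = strsplit(s$supporters, ",")[[1]],
         high_confidence = hc, expected_filter = filt,
         is_binder = (s$tier >= 2L && filt == "none") || s$role == "dbExact")
  })
  roleId <- function(role) som[[which(vapply(som, function(s)
    s$role == role, logical(1)))[1]]]$id
  expDesign <- list()
  expDesign[[roleId("best")]] <- list(start = 3L, end = 31L,
    n_binders_I = 4L, n_binders_II = 60L, n_alleles_I = 1L,
    n_alleles_II = 1L, ipmsdb_I = "EXACT", ipmsdb_II = "EXACT")
  expDesign[[roleId("tier2")]] <- list(start = 8L, end = 19L,
    n_binders_I = 4L, n_binders_II = 0L, n_alleles_I = 1L,
    n_alleles_II = 0L, ipmsdb_I = "INCLUDED", ipmsdb_II = "NONE")
  if (linkedOn)
    expDesign[[roleId("linked")]] <- list(start = 8L, end = 19L,
      n_binders_I = 4L, n_binders_II = 0L, n_alleles_I = 1L,
      n_alleles_II = 0L, ipmsdb_I = "NONE", ipmsdb_II = "NONE")
  expDesign[[roleId("wtTrap")]] <- list(start = 8L, end = 19L,
    n_binders_I = 3L, n_binders_II = 0L, n_alleles_I = 1L,
    n_alleles_II = 0L, ipmsdb_I = "PARTIAL", ipmsdb_II = "NONE")
  expDesign[[roleId("dbExact")]] <- list(start = 12L, end = 20L,
    n_binders_I = 1L, n_binders_II = 0L, n_alleles_I = 0L,
    n_alleles_II = 0L, ipmsdb_I = "EXACT", ipmsdb_II = "NONE")
  rankOrder <- c(roleId("best"), roleId("tier2"),
                 if (linkedOn) roleId("linked"), roleId("wtTrap"),
                 roleId("dbExact"))
  germTruth <- lapply(germ, function(gm) {
    list(id = gm$id, gene = .fxGeneName(gm$gene), role = gm$role,
         phase_set = if (is.na(gm$ps)) NULL else gm$ps,
         linked_to = if (linkedOn && gm$role == "linked_snp") roleId("linked")
           else if (gm$role == "benign_linked") {
             hit <- Filter(function(s) !is.null(s$ps) &&
                             identical(s$ps, gm$ps), som)
             if (length(hit)) hit[[1]]$id else NULL
           } else NULL)
  })
  truth <- list(
    seed = spec@seed,
    n_somatic = spec@nSomatic,
    n_high_confidence_nonsyn = sum(vapply(som, function(s)
      isHc(s$supporters), logical(1))),
    # the planted synonymous somatic (supported by all callers) is also
    # high confidence at the variant level; it drops out at the context stage
    n_high_confidence_somatic = sum(vapply(som, function(s)
      isHc(s$supporters), logical(1))) + 1L,
    planted_best = roleId("best"),
    expected_rank_order = rankOrder,
    expected_report_ids = rankOrder,
    expected_design = expDesign,
    mutations = mutTruth,
    germline_snps = germTruth,
    synonymous_somatic = synId,
    germline_only = .variantId("1", goPos, "C", "T"),
    multiallelic = list(.variantId("1", maPos, "C", "T"),
                        .variantId("1", maPos, "C", "G")),
    rejected_coordinate = list(chrom = "1", pos = rjPos),
    wt_identity_removed = trapPep,
    observed_peptides = list(mutant = obsMut, wt = obsWt,
                             unmapped = c(obsBad, obsMiss)))
  write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
             pretty = TRUE, digits = NA)
  invisible(list(dir = dir, truth = truth))
}

#' Read the ground truth of a generated cohort
#'
#' The truth JSON schema is documented in [generateCohort()]: per-mutation
#' expected caller support, confidence, filter outcome and binder status;
#' expected long-peptide designs and rank order; linked-SNP, rejected
#' coordinate and observed-peptide expectations.
#'
#' @param dir cohort directory.
#' @return the truth list.
#' @export
expectedTruth <- function(dir) {
  path <- file.path(dir, "truth.json")
  if (!file.exists(path)) stop("no truth.json in ", dir)
  read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
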
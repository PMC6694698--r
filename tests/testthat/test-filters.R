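# Exclusion filters and hotspot-overlap classification.

test_that("the 90th percentile uses linear interpolation and a strict threshold", {
  expect_equal(expressionP90(1:10), 9.1)
  expr <- data.frame(gene = c("G1", "G2", "G3"), tissue = "pancreas",
                     p90 = c(0.5, 1.0, 7))
  muts <- data.frame(mutation_id = paste0("m", 1:4),
                     gene = c("G1", "G2", "G3", "G9"))
  out <- filterExpression(muts, expr, "pancreas")
  # TPM 0.5 excluded; exactly 1.0 retained ("TPM < 1" is strict)
  expect_setequal(out$gene, c("G2", "G3", "G9"))
  # missing gene retained with a flag
  expect_true(out$expression_missing[out$gene == "G9"])
  expect_false(any(out$expression_missing[out$gene != "G9"]))
  expect_error(filterExpression(muts, expr, "lung"), "tissue")
})

test_that("expression table sample columns reduce to p90", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "G1", tissue = "pancreas",
                         t(setNames(1:10, paste0("s", 1:10)))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readExpressionTable(path)
  expect_equal(tab$p90, 9.1)
})

test_that("wild-type identity filter matches a naive substring scan", {
  set.seed(31)
  for (rep in 1:20) {
    prots <- Biostrings::AAStringSet(vapply(1:5, function(i)
      paste(sample(AA_STANDARD, 60, replace = TRUE), collapse = ""),
      character(1)))
    names(prots) <- paste0("P", 1:5)
    peps <- c(
      # half random, half planted as true substrings
      vapply(1:6, function(i) paste(sample(AA_STANDARD, 9, replace = TRUE),
                                    collapse = ""), character(1)),
      vapply(1:4, function(i) {
        p <- sample(5L, 1); s <- sample(50L, 1)
        substr(as.character(prots[[p]]), s, s + 8L)
      }, character(1)))
    cand <- data.frame(sequence = peps)
    got <- filterWtIdentity(cand, prots)$sequence
    naive <- peps[!vapply(peps, function(x)
      any(vapply(as.character(prots), function(pr)
        grepl(x, pr, fixed = TRUE), logical(1))), logical(1))]
    expect_setequal(got, naive)
  }
  # only mutant identity matters: the wild-type form being present is fine
  prot <- Biostrings::AAStringSet(c(P1 = "MAKPLEAKYV"))
  cand <- data.frame(sequence = c("AKPLE", "AKVLE"))
  expect_equal(filterWtIdentity(cand, prot)$sequence, "AKVLE")
})

test_that("hypermutated-gene filter drops whole genes above the count", {
  muts <- data.frame(mutation_id = paste0("m", 1:7),
                     gene = c(rep("HYP", 5), "G1", "G2"))
  out <- filterHypermutated(muts, k = 3)
  expect_setequal(out$gene, c("G1", "G2"))
  expect_equal(nrow(filterHypermutated(muts, k = Inf)), 7L)
  # counts can come from a wider somatic table than the filtered one
  out2 <- filterHypermutated(muts[muts$gene == "HYP", ][1, ], k = 3,
                             geneCounts = table(muts$gene))
  expect_equal(nrow(out2), 0L)
})

test_that("hotspot overlap classifies EXACT, INCLUDED, PARTIAL and NONE", {
  set.seed(30)
  prot <- paste(sample(AA_STANDARD, 60, replace = TRUE), collapse = "")
  proteome <- Biostrings::AAStringSet(setNames(prot, "TX1|G1"))
  ctx <- makeContextRow(mutation_id = "m1",
                        seq = substr(prot, 15, 45), mutated_index = 16L)
  ctx$transcript_id <- "TX1"; ctx$aa_pos <- 30L
  cand <- rbind(
    enumerateCandidates(ctx, "I"),
    enumerateCandidates(ctx, "II"))
  cand$mutation_id <- "m1"
  mkdb <- function(pep, cl = "I", src = "TX1|G1")
    data.frame(peptide = pep, hla_class = cl, source_protein = src,
               n_observations = 2L)
  wt9 <- substr(prot, 26, 34)   # equals the wt form of a 9-mer candidate
  res <- classifyIpmsdbOverlap(ctx, cand, mkdb(wt9), proteome)
  expect_equal(res$I, "EXACT")
  expect_equal(res$II, "NONE")
  # an 8-mer ligand inside a wild-type form: INCLUDED (never EXACT)
  res2 <- classifyIpmsdbOverlap(ctx, cand, mkdb(substr(prot, 27, 34)),
                                proteome)
  expect_equal(res2$I, "INCLUDED")
  # same-protein ligand overlapping a wt form by >= 5 residues: PARTIAL
  res3 <- classifyIpmsdbOverlap(ctx, cand, mkdb(substr(prot, 14, 26)),
                                proteome)
  expect_equal(res3$I, "PARTIAL")
  # < 5 residue overlap stays NONE
  res4 <- classifyIpmsdbOverlap(ctx, cand, mkdb(substr(prot, 5, 16)),
                                proteome)
  expect_equal(res4$I, "NONE")
})

test_that("EXACT is never down-classified when the database grows", {
  set.seed(32)
  prot <- paste(sample(AA_STANDARD, 80, replace = TRUE), collapse = "")
  proteome <- Biostrings::AAStringSet(setNames(prot, "TX1|G1"))
  ctx <- makeContextRow(mutation_id = "m1", seq = substr(prot, 25, 55),
                        mutated_index = 16L)
  ctx$transcript_id <- "TX1"; ctx$aa_pos <- 40L
  cand <- enumerateCandidates(ctx, "I"); cand$mutation_id <- "m1"
  base <- data.frame(peptide = substr(prot, 36, 44), hla_class = "I",
                     source_protein = "TX1|G1", n_observations = 1L)
  expect_equal(classifyIpmsdbOverlap(ctx, cand, base, proteome)$I, "EXACT")
  for (rep in 1:10) {
    extra <- data.frame(peptide = paste(sample(AA_STANDARD, 9,
                                               replace = TRUE),
                                        collapse = ""),
                        hla_class = "I", source_protein = "TX1|G1",
                        n_observations = 1L)
    grown <- rbind(base, extra)
    expect_equal(classifyIpmsdbOverlap(ctx, cand, grown, proteome)$I,
                 "EXACT")
  }
})

test_that("underrepresentation filter is inert at threshold zero", {
  prot <- Biostrings::AAStringSet(setNames(strrep("A", 50), "TX1|G1"))
  muts <- data.frame(mutation_id = "m1", transcript_id = "TX1")
  emptyDb <- data.frame(peptide = character(0), hla_class = character(0),
                        source_protein = character(0),
                        n_observations = integer(0))
  expect_equal(nrow(filterUnderrepresented(muts, emptyDb, prot, 0)), 1L)
  expect_equal(nrow(filterUnderrepresented(muts, emptyDb, prot, 0.01)), 0L)
  fullDb <- data.frame(peptide = strrep("A", 50), hla_class = "I",
                       source_protein = "TX1|G1", n_observations = 1L)
  out <- filterUnderrepresented(muts, fullDb, prot, 0.99)
  expect_equal(nrow(out), 1L)
  expect_equal(out$db_coverage, 1)
})

test_that("expression, wild-type and hypermutated filters commute", {
  set.seed(33)
  prots <- Biostrings::AAStringSet(setNames(
    vapply(1:3, function(i) paste(sample(AA_STANDARD, 40, replace = TRUE),
                                  collapse = ""), character(1)),
    paste0("TX", 1:3, "|G", 1:3)))
  for (rep in 1:10) {
    n <- 12L
    muts <- data.frame(
      mutation_id = paste0("m", 1:n),
      gene = sample(c("G1", "G2", "G3", "HYP", "HYP", "HYP", "HYP"), n,
                    replace = TRUE),
      sequence = c(vapply(1:(n - 2), function(i)
        paste(sample(AA_STANDARD, 9, replace = TRUE), collapse = ""),
        character(1)),
        substr(as.character(prots[[1]]), 3, 11),
        substr(as.character(prots[[2]]), 10, 18)))
    expr <- data.frame(gene = c("G1", "G2", "G3", "HYP"),
                       tissue = "pancreas", p90 = c(0.3, 5, 2, 9))
    counts <- table(muts$gene)
    fE <- function(m) filterExpression(m, expr, "pancreas")
    fW <- function(m) filterWtIdentity(m, prots)
    fH <- function(m) filterHypermutated(m, 3, geneCounts = counts)
    orders <- list(c(fE, fW, fH), c(fE, fH, fW), c(fW, fE, fH),
                   c(fW, fH, fE), c(fH, fE, fW), c(fH, fW, fE))
    ids <- lapply(orders, function(fs)
      sort(fs[[3]](fs[[2]](fs[[1]](muts)))$mutation_id))
    for (k in 2:6) expect_identical(ids[[k]], ids[[1]])
  }
})
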
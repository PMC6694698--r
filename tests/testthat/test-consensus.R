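# Variant consensus: VCF parsing, majority-rule merging, origin
# classification, high-confidence selection and phased linked SNPs.

test_that("VCF parsing maps genotypes, splits multi-allelics and handles empty bodies", {
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), data.frame(
    pos = c(100, 200, 300), ref = c("A", "C", "G"),
    alt = c("T", "T,G", "A"),
    gt_t = c("0/1", "1/2", "0/0"), gt_n = c("0/0", "1/2", "0/1"),
    ps = NA))
  cs <- readCallerVcf(vcf, "gatk")
  # biallelic tumor-only SNV
  m <- S4Vectors::mcols(cs)
  i <- which(GenomicRanges::start(cs) == 100)
  expect_length(i, 1L)
  expect_true(m$in_tumor[i]); expect_false(m$in_germline[i])
  # multi-allelic record splits into two caller variants at the same pos
  j <- which(GenomicRanges::start(cs) == 200)
  expect_length(j, 2L)
  expect_setequal(m$alt[j], c("T", "G"))
  expect_true(all(m$in_tumor[j] & m$in_germline[j]))
  # germline-only variant is retained at parse level
  k <- which(GenomicRanges::start(cs) == 300)
  expect_false(m$in_tumor[k]); expect_true(m$in_germline[k])

  empty <- writeTestVcf(tempfile(fileext = ".vcf"),
                        data.frame(pos = integer(0), ref = character(0),
                                   alt = character(0), gt_t = character(0),
                                   gt_n = character(0)))
  expect_length(readCallerVcf(empty, "gatk"), 0L)
})

test_that("missing sample columns raise a configuration error", {
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), data.frame(
    pos = 100, ref = "A", alt = "T", gt_t = "0/1", gt_n = "0/0"),
    samples = c("S1", "S2"))
  expect_error(readCallerVcf(vcf, "gatk"), "sample column")
})

test_that("merging resolves conflicts by strict majority and rejects ties", {
  mk <- function(caller, alt) callerCallSet(
    data.frame(chrom = "1", pos = 50, ref = "A", alt = alt), caller)
  # 2 vs 1: majority call kept with its supporters
  res <- mergeCallSets(list(mk("mutect", "T"), mk("varscan", "T"),
                            mk("gatk", "G")))
  expect_length(res, 1L)
  expect_equal(S4Vectors::mcols(res)$alt, "T")
  expect_setequal(S4Vectors::mcols(res)$supporters[[1]],
                  c("mutect", "varscan"))
  # 1 vs 1: coordinate rejected entirely
  expect_message(res2 <- mergeCallSets(list(mk("mutect", "T"),
                                            mk("gatk", "G"))),
                 "no majority")
  expect_length(res2, 0L)
  expect_equal(S4Vectors::metadata(res2)$rejected$pos, 50)
  # a single caller's call survives (union semantics)
  res3 <- mergeCallSets(list(mk("gatk", "T")))
  expect_length(res3, 1L)
  expect_equal(S4Vectors::mcols(res3)$supporters[[1]], "gatk")
})

test_that("merge equals the brute-force majority oracle on random instances", {
  set.seed(41)
  for (rep in 1:250) {
    calls <- randomCallerInstance(sample(3:10, 1))
    if (is.null(calls)) next
    sets <- lapply(split(calls, calls$caller), function(g)
      callerCallSet(g[, c("chrom", "pos", "ref", "alt")], g$caller[1]))
    got <- suppressMessages(suppressWarnings(mergeCallSets(sets)))
    gotDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(got)),
                        pos = GenomicRanges::start(got),
                        ref = S4Vectors::mcols(got)$ref,
                        alt = S4Vectors::mcols(got)$alt,
                        supporters = vapply(S4Vectors::mcols(got)$supporters,
                                            paste, character(1),
                                            collapse = ","))
    exp <- oracleMajority(calls)
    rownames(gotDf) <- rownames(exp) <- NULL
    expect_equal(gotDf, exp)
  }
})

test_that("union property: every non-rejected input variant appears exactly once", {
  set.seed(99)
  for (rep in 1:50) {
    calls <- randomCallerInstance(6L)
    if (is.null(calls)) next
    sets <- lapply(split(calls, calls$caller), function(g)
      callerCallSet(g[, c("chrom", "pos", "ref", "alt")], g$caller[1]))
    got <- suppressMessages(suppressWarnings(mergeCallSets(sets)))
    rejected <- S4Vectors::metadata(got)$rejected
    ids <- S4Vectors::mcols(got)$variant_id
    expect_false(anyDuplicated(ids) > 0)
    inputIds <- unique(with(calls, paste(chrom, pos, ref, alt, sep = ":")))
    kept <- oracleMajority(calls)
    keptIds <- with(kept, paste(chrom, pos, ref, alt, sep = ":"))
    expect_setequal(ids, keptIds)
    expect_true(all(ids %in% inputIds))
  }
})

test_that("origin classification is conservative and drops germline-only calls", {
  gr <- mergeCallSets(list(
    callerCallSet(data.frame(chrom = "1", pos = 10, ref = "A", alt = "T",
                             in_tumor = TRUE, in_germline = FALSE), "mutect"),
    callerCallSet(data.frame(chrom = "1", pos = c(10, 20, 30),
                             ref = "A", alt = "T",
                             in_tumor = c(TRUE, TRUE, FALSE),
                             in_germline = c(TRUE, TRUE, TRUE)), "varscan")))
  expect_warning(out <- classifyOrigin(gr), "germline-only")
  m <- S4Vectors::mcols(out)
  # mutect says tumor-only, varscan says both -> germline evidence wins
  expect_equal(m$origin[GenomicRanges::start(out) == 10], "germline_snp")
  expect_equal(m$origin[GenomicRanges::start(out) == 20], "germline_snp")
  expect_false(30 %in% GenomicRanges::start(out))

  som <- classifyOrigin(mergeCallSets(list(callerCallSet(
    data.frame(chrom = "1", pos = 5, ref = "A", alt = "T"), "mutect"))))
  expect_equal(S4Vectors::mcols(som)$origin, "somatic")
})

test_that("high-confidence rule: MuTect alone or at least two callers", {
  mkSom <- function(pos, callers) lapply(callers, function(cl)
    callerCallSet(data.frame(chrom = "1", pos = pos, ref = "A", alt = "T"),
                  cl))
  gr <- classifyOrigin(mergeCallSets(c(mkSom(10, "mutect"),
                                       mkSom(20, "gatk"),
                                       mkSom(30, c("gatk", "varscan")))))
  hc <- selectHighConfidence(gr)
  expect_setequal(GenomicRanges::start(hc), c(10, 30))
  expect_true(all(S4Vectors::mcols(hc)$high_confidence))
})

test_that("removing MuTect support from a single-caller variant removes it", {
  set.seed(7)
  for (rep in 1:20) {
    cl <- sample(c("gatk", "mutect", "varscan"), 1)
    gr <- classifyOrigin(mergeCallSets(list(callerCallSet(
      data.frame(chrom = "1", pos = 10, ref = "A", alt = "T"), cl))))
    hc <- selectHighConfidence(gr)
    expect_equal(length(hc), as.integer(cl == "mutect"))
  }
})

test_that("phase-linked SNPs require the same phase set and haplotype", {
  rows <- data.frame(
    pos = c(100, 130, 160, 190),
    ref = "A", alt = "T",
    gt_t = c("0|1", "0|1", "1|0", "0/1"),
    gt_n = c("0/0", "0/1", "0/1", "0/1"),
    ps = c(100, 100, 100, NA))
  vcf <- writeTestVcf(tempfile(fileext = ".vcf"), rows)
  cs <- readCallerVcf(vcf, "gatk")
  # add mutect support so the somatic variant is high confidence
  cs2 <- callerCallSet(data.frame(chrom = "1", pos = 100, ref = "A",
                                  alt = "T"), "mutect")
  gr <- linkPhasedSnps(classifyOrigin(mergeCallSets(list(cs, cs2))))
  m <- S4Vectors::mcols(gr)
  linked <- m$linked_snps[[which(GenomicRanges::start(gr) == 100)]]
  expect_equal(linked, "1:130:A:T")          # same set, same haplotype
  expect_false("1:160:A:T" %in% linked)      # opposite haplotype
  expect_false("1:190:A:T" %in% linked)      # unphased
  hc <- selectHighConfidence(gr)
  expect_setequal(GenomicRanges::start(hc), c(100, 130))
  # high-confidence output is a subset of somatic plus linked SNPs
  expect_true(all(S4Vectors::mcols(hc)$origin %in%
                    c("somatic", "germline_snp")))
})
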
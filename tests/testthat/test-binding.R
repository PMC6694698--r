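# Candidate enumeration, PWM scoring, decoy calibration, external score
# tables and binder calls.

uniformMat <- function(len) matrix(1, nrow = len, ncol = 20,
                                   dimnames = list(NULL, AA_STANDARD))

smallModel <- function(hlaClass = "I", seed = 5L, decoyN = 2000L,
                       mats = NULL) {
  if (is.null(mats)) {
    mats <- if (hlaClass == "I")
      setNames(lapply(9:12, function(L) {
        m <- matrix(runif(20 * L), nrow = L,
                    dimnames = list(NULL, AA_STANDARD)); m
      }), 9:12)
    else list(core = matrix(runif(180), nrow = 9,
                            dimnames = list(NULL, AA_STANDARD)))
  }
  pwmModel("AL", hlaClass, mats, seed = seed, decoyN = decoyN)
}

test_that("candidate counts match the closed form on the full 31-mer", {
  ctx <- makeContextRow(seq = paste(rep("A", 31), collapse = ""),
                        mutated_index = 16L)
  cI <- enumerateCandidates(ctx, "I")
  cII <- enumerateCandidates(ctx, "II")
  expect_equal(nrow(cI), 42L)   # 9 + 10 + 11 + 12 windows through the centre
  # a length-k window through centre 16 of a 31-mer has min(k, 32 - k)
  # placements: 12 + 13 + 14 + 15 + 16 + 15 + 14 + 13
  expect_equal(nrow(cII), 112L)
  expect_equal(nrow(cII), sum(pmin(12:19, 32L - 12:19)))
  expect_true(all(cI$covers_mutation))
  # a context of exactly 9 residues yields a single class I window
  ctx9 <- makeContextRow(seq = paste(rep("A", 9), collapse = ""),
                         mutated_index = 5L)
  expect_equal(nrow(enumerateCandidates(ctx9, "I", lengths = 9L)), 1L)
  # too-short context warns and yields nothing
  ctx5 <- makeContextRow(seq = "AAAAA", mutated_index = 3L)
  expect_warning(none <- enumerateCandidates(ctx5, "I"), "shorter")
  expect_equal(nrow(none), 0L)
})

test_that("candidate counts equal a brute-force window enumeration", {
  set.seed(21)
  for (rep in 1:30) {
    L <- sample(9:31, 1)
    mi <- sample(1:L, 1)
    ctx <- makeContextRow(seq = paste(sample(AA_STANDARD, L, replace = TRUE),
                                      collapse = ""), mutated_index = mi)
    got <- suppressWarnings(enumerateCandidates(ctx, "I"))
    # oracle: loop over all (start, length) pairs
    cnt <- 0L
    for (len in 9:12) {
      if (len > L) next
      for (s in 1:(L - len + 1)) if (s <= mi && mi <= s + len - 1) cnt <- cnt + 1L
    }
    expect_equal(nrow(got), cnt)
  }
})

test_that("PWM scoring follows the matrix definition", {
  # uniform matrix: all same-length peptides score alike
  m <- smallModel(mats = setNames(lapply(9:12, uniformMat), 9:12))
  expect_equal(scorePwm(c("AAAAAAAAA", "CDEFGHIKL"), m), c(9, 9))
  # single-position indicator matrix
  M <- matrix(0, 9, 20, dimnames = list(NULL, AA_STANDARD)); M[1, "A"] <- 1
  m2 <- pwmModel("X", "I", list(`9` = M), seed = 1, decoyN = 500)
  expect_equal(scorePwm(c("AWWWWWWWW", "CWWWWWWWW"), m2), c(1, 0))
  # class II: max core score; plant one high core at offset 3
  Mc <- matrix(0, 9, 20, dimnames = list(NULL, AA_STANDARD))
  Mc[1, "W"] <- 5
  m3 <- pwmModel("D", "II", list(core = Mc), seed = 1, decoyN = 500)
  pep <- paste0("AAA", "W", strrep("A", 8))  # W at position 4 -> core offset 3
  expect_equal(scorePwm(pep, m3), 5)
  # non-standard residues drop with a warning
  expect_warning(s <- scorePwm("AAAAAAAAB", m2), "non-standard")
  expect_true(is.na(s))
})

test_that("percentile ranks are calibrated against the decoys", {
  m <- smallModel(decoyN = 1000L)
  d <- m@decoys[["9"]]
  # score above all decoys -> percent rank 0 and p-value 0
  top <- calibratePercentRank(max(d) + 1, m, 9L)
  expect_equal(top$percent_rank, 0)
  expect_equal(top$p_value, 0)
  # score at the decoy median -> about 50
  med <- calibratePercentRank(stats::median(d), m, 9L)
  expect_true(abs(med$percent_rank - 50) <= 0.2)
  # p_value and percent_rank agree by construction
  sc <- runif(20, min(d), max(d))
  cal <- calibratePercentRank(sc, m, 9L)
  expect_equal(cal$p_value, cal$percent_rank / 100)
  # identical matrices and seed -> identical decoys and output
  m2 <- pwmModel(m@allele, m@hlaClass, m@matrices, seed = m@seed,
                 decoyN = m@decoyN)
  expect_identical(m@decoys, m2@decoys)
  expect_identical(calibratePercentRank(sc, m, 9L),
                   calibratePercentRank(sc, m2, 9L))
})

test_that("percent rank is monotone non-increasing in score", {
  set.seed(23)
  for (cl in c("I", "II")) {
    m <- smallModel(cl, decoyN = 1500L)
    L <- if (cl == "I") sample(9:12, 1) else sample(12:19, 1)
    sc <- sort(runif(50, 0, if (cl == "I") L else 9))
    pr <- calibratePercentRank(sc, m, L)$percent_rank
    expect_true(all(diff(pr) <= 0))
  }
})

test_that("external score tables attach by peptide and allele", {
  ctx <- makeContextRow(seq = paste(rep("A", 12), collapse = ""),
                        mutated_index = 6L)
  cand <- enumerateCandidates(ctx, "I")
  tab <- data.frame(peptide = unique(cand$sequence), allele = "A0201",
                    score = 1, percent_rank = 2)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- loadExternalScores(path, cand)
  expect_length(attr(sc, "unscored"), 0L)
  expect_equal(unique(sc$p_value), 0.02)  # derived from percent_rank
  # a missing peptide is flagged unscored and never a binder
  tab2 <- tab[-1, ]
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(sc2 <- loadExternalScores(path, cand), "unscored")
  expect_equal(attr(sc2, "unscored"), tab$peptide[1])
  called <- callBinders(cand, sc2, cutoff = 100)
  expect_false(any(called$is_binder[called$sequence == tab$peptide[1]]))
  # conflicting duplicates error
  tab3 <- rbind(tab, transform(tab[1, ], score = 99))
  write.table(tab3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadExternalScores(path, cand), "conflicting")
})

test_that("binder calls respect the cutoff and the ligand database rescue", {
  cand <- data.frame(mutation_id = "m", hla_class = "I",
                     context_start = 1:3, length = 9L,
                     sequence = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                     wt_sequence = c("WAAAAAAAA", "WCCCCCCCC", "WDDDDDDDD"),
                     covers_mutation = TRUE)
  sc <- cand
  sc$allele <- "A0101"
  sc$score <- 1
  sc$percent_rank <- c(4.9, 5.1, 80)
  sc$p_value <- sc$percent_rank / 100
  db <- data.frame(peptide = "WDDDDDDDD", hla_class = "I",
                   source_protein = "P", n_observations = 3L)
  out <- callBinders(cand, sc, db, cutoff = 5, strict = TRUE)
  expect_equal(out$is_binder, c(TRUE, FALSE, TRUE))
  # 5.0 is excluded under the strict default but included with <=
  sc$percent_rank[2] <- 5.0
  expect_false(callBinders(cand, sc, NULL, 5, TRUE)$is_binder[2])
  expect_true(callBinders(cand, sc, NULL, 5, FALSE)$is_binder[2])
  # cutoff 100: every scored candidate binds; cutoff 0 + empty db: none
  expect_true(all(callBinders(cand, sc, NULL, 100)$is_binder))
  expect_false(any(callBinders(cand, sc, NULL, 0)$is_binder))
})
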
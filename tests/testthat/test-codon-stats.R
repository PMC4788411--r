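test_that("gc3 follows its definition and rejects malformed input", {
  expect_equal(unname(gc3("AAAAAA")), 0)
  expect_equal(unname(gc3("GGGGGG")), 1)
  expect_equal(unname(gc3("AAGAAC")), 1)        # third bases G, C
  expect_equal(unname(gc3("ATTAAATAG")), 1 / 3) # the stop codon is counted
  expect_error(gc3("AAAA"), "frame")
  expect_error(gc3("ATGNNN"), "non-ACGT")
  # lower case is normalized, not rejected
  expect_equal(unname(gc3("atggcc")), 1)
})

test_that("gc3 agrees with the per-position brute-force count", {
  set.seed(42)
  for (i in 1:50) {
    s <- randomCodonString(sample(5:60, 1))
    expect_equal(unname(gc3(s)), bruteGc3(s))
  }
})

test_that("usage tables aggregate counts and normalize within families", {
  tab <- buildUsageTable("ATGAAATAA")
  f <- codonFreq(tab)
  expect_equal(unname(f[c("ATG", "AAA", "AAG")]), c(1, 1, 0))
  expect_equal(unname(f[c("TAA", "TAG", "TGA")]), c(1, 0, 0))
  expect_equal(nCds(tab), 1L)
  expect_true("F" %in% tab@emptyFamilies)
  expect_error(buildUsageTable(character(0)), "empty")

  # stop exclusion zeroes the stop family
  tab2 <- buildUsageTable("ATGAAATAA", includeStops = FALSE)
  expect_equal(sum(codonCounts(tab2)[c("TAA", "TAG", "TGA")]), 0L)
})

test_that("family frequencies sum to one across random tables", {
  set.seed(7)
  code <- plastidReporter:::geneticCodeMap("11")
  fam <- split(names(code), code)
  for (i in 1:40) {
    cds <- vapply(seq_len(sample(2:6, 1)),
      function(k) randomCodonString(sample(10:80, 1)), character(1))
    tab <- buildUsageTable(cds)
    f <- codonFreq(tab)
    cnt <- codonCounts(tab)
    for (aa in names(fam)) {
      tot <- sum(cnt[fam[[aa]]])
      if (tot > 0) expect_equal(sum(f[fam[[aa]]]), 1, tolerance = 1e-12)
      else expect_equal(sum(f[fam[[aa]]]), 0)
    }
  }
})

test_that("single-codon families have frequency exactly 1 when observed", {
  tab <- buildUsageTable(c("ATGTGGTAA"))
  expect_identical(unname(codonFreq(tab)[["ATG"]]), 1)
  expect_identical(unname(codonFreq(tab)[["TGG"]]), 1)
})

test_that("codon classification: optimal by family maximum, rare at <= 0.10 inclusive", {
  # Lys observed 9:1 -> AAG sits exactly on the inclusive boundary
  tab <- buildUsageTable(c(paste0("ATG", strrep("AAA", 9), "AAG", "TAA")))
  cls <- classifyCodon(c("ATG", "AAA", "AAG"), tab)
  expect_equal(as.character(cls), c("optimal", "optimal", "rare"))
  expect_error(classifyCodon("AXG", tab), "invalid triplet")
  # unobserved family members are rare (never seen in the reference)
  expect_equal(as.character(classifyCodon("TTT", tab)), "rare")
})

test_that("tied family maxima are broken lexicographically and flagged", {
  tab <- buildUsageTable("ATGAAAAAGTAA")   # Lys AAA:AAG = 1:1
  expect_true("K" %in% tab@tieFamilies)
  cls <- classifyCodon(c("AAA", "AAG"), tab)
  expect_equal(as.character(cls), c("optimal", "intermediate"))
})

test_that("compareSynonymous counts changes, segments them, and is symmetric", {
  a <- "ATGAAAAAGTTATAA"
  b <- "ATGAAGAAGTTGTAA"   # positions 2 and 4 recoded
  cmp <- compareSynonymous(a, b, segmentSize = 2)
  expect_equal(nChanged(cmp), 2L)
  expect_equal(cmp@changedPositions, c(2L, 4L))
  expect_equal(perSegment(cmp), c(1L, 1L, 0L))
  cmp2 <- compareSynonymous(b, a, segmentSize = 2)
  expect_equal(nChanged(cmp2), nChanged(cmp))
  expect_equal(perSegment(cmp2), perSegment(cmp))
  # self comparison is zero everywhere
  self <- compareSynonymous(a, a)
  expect_equal(nChanged(self), 0L)
  # rejections: unequal length, non-synonymous change (with position)
  expect_error(compareSynonymous(a, "ATGAAA"), "unequal")
  expect_error(compareSynonymous("ATGAAATAA", "ATGAACTAA"),
    "non-synonymous.*2")
})

test_that("constructed recodings are counted exactly", {
  set.seed(11)
  code <- Biostrings::getGeneticCode("11")
  names(code) <- chartr("U", "T", names(code))
  fam <- split(names(code), code)
  for (rep in 1:10) {
    s <- randomValidCds(10)
    cods <- substring(s, 3 * (1:10) - 2, 3 * (1:10))
    recodable <- which(lengths(fam[code[cods]]) > 1)
    pick <- sample(recodable, 3)
    for (i in pick) {
      alts <- setdiff(fam[[code[[cods[i]]]]], cods[i])
      cods[i] <- sample(alts, 1)
    }
    cmp <- compareSynonymous(s, paste0(cods, collapse = ""))
    expect_equal(nChanged(cmp), 3L)
    expect_equal(cmp@changedPositions, as.integer(unname(sort(pick))))
  }
})

test_that("meanFreqDiff is zero for a gene matching its own table and needs a known variant", {
  g <- "ATGAAATTATAA"
  tab <- buildUsageTable(g)
  for (v in c("global", "position", "present"))
    expect_equal(meanFreqDiff(g, tab, v), 0)
  expect_error(meanFreqDiff(g, tab, "bogus"))
})

test_that("diagnostics are invariant under codon-level permutation", {
  rp <- syntheticReporterPair()
  s <- unname(rp$native)
  n <- nchar(s) / 3
  cods <- substring(s, 3 * (1:n) - 2, 3 * (1:n))
  set.seed(3)
  perm <- paste0(sample(cods), collapse = "")
  d1 <- diagnoseCds(s, rp$table)
  d2 <- diagnoseCds(perm, rp$table)
  expect_equal(d1@gc3, d2@gc3)
  expect_equal(d1@nOptimal, d2@nOptimal)
  expect_equal(d1@nRare, d2@nRare)
  expect_equal(d1@meanFreqDiff, d2@meanFreqDiff)
})

test_that("diagnose populates every field consistently", {
  rp <- syntheticReporterPair()
  d <- diagnoseCds(rp$optimized, rp$table)
  expect_s4_class(d, "DiagnosticsReport")
  expect_length(d@perCodonClass, d@nCodons)
  expect_equal(d@fracOptimal, d@nOptimal / d@nCodons)
  expect_equal(d@fracRare, d@nRare / d@nCodons)
  expect_equal(sum(d@perCodonClass == "optimal"), d@nOptimal)
  # a gene of only family-maximum codons is fully optimal, never rare
  allOpt <- optimizeCds(rp$native, rp$table, strategy = "max")
  expect_equal(allOpt$after@fracOptimal, 1)
  expect_equal(allOpt$after@nRare, 0L)
})

test_that("usage-table TSV round-trips at stated precision", {
  rp <- syntheticReporterPair()
  path <- tempfile(fileext = ".tsv")
  writeUsageTable(rp$table, path)
  back <- readUsageTable(path)
  expect_equal(codonCounts(back), codonCounts(rp$table))
  expect_equal(codonFreq(back), codonFreq(rp$table), tolerance = 1e-12)
  df <- read.delim(path)
  expect_equal(nrow(df), 64L)
  expect_equal(sum(df$is_optimal), 21L)  # one per observed family incl. stop
})

test_that("diagnostics and change reports serialize to JSON", {
  rp <- syntheticReporterPair()
  d <- diagnoseCds(rp$optimized, rp$table)
  js <- jsonlite::fromJSON(reportAsJson(d))
  expect_equal(js$n_optimal, 174L)
  cmp <- compareSynonymous(rp$native, rp$optimized)
  js2 <- jsonlite::fromJSON(reportAsJson(cmp))
  expect_equal(js2$per_segment, c(72L, 71L, 69L))
})
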
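test_that("FASTA round-trips, enforces unique ids, upper-cases on read", {
  set.seed(5)
  recs <- setNames(vapply(1:3, function(i) randomCodonString(20),
    character(1)), c("a", "b", "c"))
  f <- tempfile(fileext = ".fasta")
  writeFastaCds(recs, f)
  back <- readFastaCds(f)
  expect_identical(back, recs)
  # wrapping at 60 columns
  expect_true(all(nchar(readLines(f)) <= 60))
  # mixed case upper-cased on read
  writeLines(c(">x", "atgaaa", ">y", "AtGcCc"), f)
  expect_identical(unname(readFastaCds(f)), c("ATGAAA", "ATGCCC"))
  # duplicate ids rejected
  writeLines(c(">x", "ATG", ">x", "AAA"), f)
  expect_error(readFastaCds(f), "duplicate")
})

test_that("GenBank coordinates convert 1-based inclusive <-> 0-based half-open exactly", {
  gb2z <- plastidReporter:::gbToZeroBased
  z2gb <- plastidReporter:::zeroBasedToGb
  for (i in 1:50) {
    a <- sample(1:1000, 1); b <- a + sample(0:500, 1)
    z <- gb2z(a, b)
    expect_equal(unname(z[, "end"] - z[, "start"]), b - a + 1)  # width kept
    back <- z2gb(z[, "start"], z[, "end"])
    expect_equal(unname(back[, "start"]), a)
    expect_equal(unname(back[, "end"]), b)
  }
})

toyGenBank <- function(sequence, locs, genes = NULL, pseudo = NULL,
    path = tempfile(fileext = ".gb")) {
  feats <- data.frame(key = "CDS", location = locs,
    gene = if (is.null(genes)) NA_character_ else genes,
    pseudo = if (is.null(pseudo)) FALSE else pseudo)
  writeGenBankRecord(sequence, feats, path)
  path
}

test_that("a forward CDS is extracted verbatim", {
  f <- toyGenBank(paste0("ATGAAATAA", "GGGG"), "1..9", "toy")
  ex <- extractCds(f)
  expect_equal(unname(ex$cds), "ATGAAATAA")
  expect_equal(names(ex$cds), "toy")
  expect_equal(ex$report$status, "accepted")
})

test_that("complement(join()) locations splice and strand-resolve correctly", {
  # hand-assembled: exons GAT TTC and AAA TAG on the minus strand; the
  # CDS ATGGAAATC...: construct explicitly instead
  # CDS = ATG GAA TAA; genome carries its reverse complement split in two
  cds <- "ATGGAATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  # place rc exon2 (first 5 nt) then spacer then exon1 (last 4 nt):
  # reading complement(join(exon_of_last4, exon_of_first5)) must return cds
  genome <- paste0("TT", substr(rc, 1, 5), "CCCC", substr(rc, 6, 9), "AA")
  # join parts listed in ascending genome order; the whole join is then
  # reverse-complemented
  f <- toyGenBank(genome, "complement(join(3..7,12..15))", "minus")
  ex <- extractCds(f, minLengthCodons = 2)
  expect_equal(unname(ex$cds), cds)
})

test_that("extraction re-derives the identical CDS after genome reverse-complement", {
  set.seed(9)
  cds <- randomValidCds(15)
  L <- 8 + nchar(cds) + 6
  genome <- paste0(strrep("T", 8), cds, strrep("A", 6))
  f1 <- toyGenBank(genome, sprintf("%d..%d", 9, 8 + nchar(cds)), "g")
  rcGenome <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome)))
  # same gene seen from the other strand
  a <- L - (8 + nchar(cds)) + 1; b <- L - 9 + 1
  f2 <- toyGenBank(rcGenome, sprintf("complement(%d..%d)", a, b), "g")
  e1 <- extractCds(f1); e2 <- extractCds(f2)
  expect_identical(unname(e1$cds), unname(e2$cds))
})

test_that("extraction policy rejects and logs without failing", {
  cds <- "ATGAAATAA"
  genome <- paste0(cds, "GG", cds, "CC", "ATGTAAAAATAA", "TT", "ATGAA")
  f <- toyGenBank(genome,
    locs = c("1..9", "12..20", "23..34", sprintf("37..%d", nchar(genome)),
      "1..9"),
    genes = c("dup", "dup", "intstop", "short", "pseu"),
    pseudo = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ex <- extractCds(f, minLengthCodons = 3)
  rep <- ex$report
  expect_equal(sum(rep$status == "accepted"), 1L)
  expect_setequal(rep$reason[rep$status == "rejected"],
    c("inverted-repeat duplicate", "internal stop codon",
      "length not a multiple of 3", "pseudo gene"))
  # duplicates kept when dedupe is off
  ex2 <- extractCds(f, minLengthCodons = 3, dedupeInvertedRepeat = FALSE)
  expect_equal(sum(ex2$report$status == "accepted"), 2L)
  # internal stops kept when allowed
  ex3 <- extractCds(f, minLengthCodons = 3, allowInternalStops = TRUE)
  expect_equal(sum(ex3$report$status == "accepted"), 2L)
  # report TSV
  tsv <- tempfile(fileext = ".tsv")
  writeExtractionReport(ex, tsv)
  expect_equal(nrow(read.delim(tsv)), nrow(rep))
})

test_that("extraction agrees with an independent Biopython parse", {
  pl <- syntheticPlastome(nGenes = 12, meanLengthCodons = 60,
    nIrDuplicates = 2, seed = 21)
  f <- tempfile(fileext = ".gb")
  writeGenBankRecord(pl$sequence, pl$features, f)
  out <- tempfile(fileext = ".txt")
  script <- sprintf("
from Bio import SeqIO
rec = next(SeqIO.parse(%s, 'genbank'))
seqs = []
for ft in rec.features:
    if ft.type == 'CDS':
        seqs.append(str(ft.extract(rec.seq)))
open(%s, 'w').write('\\n'.join(seqs) + '\\n')
", shQuote(f), shQuote(out))
  py <- tempfile(fileext = ".py")
  writeLines(script, py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  pySeqs <- readLines(out)
  mySeqs <- extractCds(f, dedupeInvertedRepeat = FALSE, requireMod3 = FALSE,
    excludePseudo = FALSE, allowInternalStops = TRUE)$cds
  expect_equal(length(pySeqs), length(mySeqs))
  expect_identical(toupper(pySeqs), unname(mySeqs))
})

test_that("the synthetic plastome census survives the full extraction pipeline", {
  pl <- syntheticPlastome(nGenes = 20, meanLengthCodons = 80,
    nIrDuplicates = 3, seed = 4)
  f <- tempfile(fileext = ".gb")
  writeGenBankRecord(pl$sequence, pl$features, f)
  ex <- extractCds(f)
  expect_equal(sum(ex$report$status == "accepted"), 20L)
  expect_identical(sort(unname(ex$cds)), sort(unname(pl$cds)))
  expect_equal(sum(ex$report$reason == "inverted-repeat duplicate"), 3L)
})
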
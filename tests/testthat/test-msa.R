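test_that("progressive alignment conserves residues and handles simple cases", {
  # identical sequences align without gaps
  two <- progressive_align(c(a = "MKVLDE", b = "MKVLDE"))
  expect_equal(ncol(two), 6L)
  expect_false(any(unclass(two) == "-"))
  # ACD vs AD: exactly one gap in row 2 (pairwise DP oracle: any positive
  # gap cost prefers one gap over two)
  pa <- progressive_align(c(x = "ACD", y = "AD"))
  expect_equal(ncol(pa), 3L)
  expect_equal(sum(unclass(pa)["y", ] == "-"), 1L)
  expect_equal(sum(unclass(pa)["x", ] == "-"), 0L)
  # residue conservation property on random inputs
  set.seed(14)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- setNames(vapply(1:6, function(i)
    paste(sample(aa, sample(20:40, 1), replace = TRUE), collapse = ""), ""),
    paste0("s", 1:6))
  aln <- progressive_align(seqs)
  m <- unclass(aln)
  for (id in names(seqs))
    expect_identical(paste(m[id, m[id, ] != "-"], collapse = ""), unname(seqs[id]))
  # single sequence comes back as a 1-row alignment
  one <- progressive_align(c(z = "MKV"))
  expect_equal(nrow(one), 1L)
})

test_that("column trimming uses an inclusive occupancy threshold", {
  rows <- c(sprintf("s%02d", 1:100))
  strings <- setNames(c("AA", rep("A-", 99)), rows)  # column 2 occupancy 0.01
  aln <- as_alignment(strings, "protein")
  kept_005 <- trim_columns(aln, 0.05)
  expect_equal(ncol(kept_005), 1L)
  expect_equal(attr(kept_005, "removed_columns"), 2L)
  kept_001 <- trim_columns(aln, 0.01)   # 0.01 >= 0.01: kept
  expect_equal(ncol(kept_001), 2L)
  gapfree <- as_alignment(c(a = "MK", b = "ML"), "protein")
  expect_equal(ncol(trim_columns(gapfree, 1)), 2L)
  expect_error(trim_columns(as_alignment(c(a = "--", b = "A-"), "protein"), 0.9),
               "lower")
  # idempotence
  expect_identical(alignment_strings(trim_columns(kept_005, 0.05)),
                   alignment_strings(kept_005))
})

test_that("poorly aligned sequences are removed by core-column coverage", {
  core <- paste(rep("A", 200), collapse = "")
  sparse <- paste0("A", paste(rep("-", 199), collapse = ""))
  aln <- as_alignment(c(full1 = core, full2 = core, full3 = core, ghost = sparse),
                      "protein")
  out <- remove_poorly_aligned(aln, 0.5)
  expect_identical(attr(out, "removed_sequences"), "ghost")
  expect_identical(rownames(remove_poorly_aligned(aln, 0)), rownames(aln))
})

test_that("back-translation threads codons through protein gaps", {
  aa <- as_alignment(c(s1 = "M-A", s2 = "MKA"), "protein")
  caln <- backtranslate(aa, c(s1 = "ATGGCT", s2 = "ATGAAAGCA"))
  expect_identical(caln[["s1"]], "ATG---GCT")
  expect_identical(caln[["s2"]], "ATGAAAGCA")
  expect_equal(nchar(caln[[1]]), 3L * ncol(aa))
  expect_error(backtranslate(aa, c(s1 = "ATGTAAGCT", s2 = "ATGAAAGCA")),
               "stop|disagrees")
  expect_error(backtranslate(aa, c(s1 = "ATGGGG", s2 = "ATGAAAGCA")),
               "position 2")
})

test_that("window completeness keeps rows gapless over the reference span", {
  aln <- as_alignment(c(ref = "MKVLDE",
                        good = "M-VLDE",    # gap outside window 3..6
                        bad = "MKV-DE"),    # gap inside
                      "protein")
  out <- window_complete_filter(aln, 3, 6, "ref")
  expect_setequal(rownames(out), c("ref", "good"))
  # full-window filter on a gap-free alignment is the identity
  gf <- as_alignment(c(ref = "MKV", x = "MLV"), "protein")
  expect_identical(rownames(window_complete_filter(gf, 1, 3, "ref")),
                   rownames(gf))
  expect_error(window_complete_filter(aln, 1, 3, "absent"), "not in alignment")
})

test_that("clean-data filtering drops every ambiguous or gapped codon column", {
  caln <- backtranslate(as_alignment(c(a = "MKA", b = "M-A"), "protein"),
                        c(a = "ATGAAAGCA", b = "ATGGCA"))
  out <- clean_codon_columns(caln)
  expect_equal(attr(out, "removed_columns"), 2L)
  amb <- structure(c(a = "ATGNNNGCA", b = "ATGAAAGCA"),
                   class = "radphy_codon_alignment")
  expect_equal(attr(clean_codon_columns(amb), "removed_columns"), 2L)
  clean <- structure(c(a = "ATGAAA", b = "ATGAAG"), class = "radphy_codon_alignment")
  expect_length(attr(clean_codon_columns(clean), "removed_columns"), 0L)
  # translating each ungapped backtranslated row reproduces the protein
  prot <- as_alignment(c(a = "MKA", b = "MA-"), "protein")
  ct <- backtranslate(prot, c(a = "ATGAAAGCA", b = "ATGGCA"))
  for (id in names(ct)) {
    cd <- gsub("-", "", ct[[id]])
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(cd))),
      gsub("-", "", paste(unclass(prot)[id, ], collapse = "")))
  }
})
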
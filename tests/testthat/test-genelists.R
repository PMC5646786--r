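test_that("symbol normalization case-folds, strips and resolves aliases", {
  expect_identical(normalize_symbol("Braf"), "BRAF")
  expect_identical(normalize_symbol(" GRIK3 "), "GRIK3")
  al <- alias_table("PPAP2A", "PLPP1")
  expect_identical(normalize_symbol("PPAP2A", al), "PLPP1")
  expect_identical(normalize_symbol("ppap2a", al), "PLPP1")

  # packaged alias fixture drives the same lookup
  packaged <- read_alias_tsv(alias_fixture_path())
  expect_identical(normalize_symbol("PPAP2A", packaged), "PLPP1")
  expect_identical(normalize_symbol("PVRL3", packaged), "NECTIN3")

  expect_error(normalize_symbol("   "), "empty")
  expect_error(normalize_symbol(""), "empty")
})

test_that("normalization is idempotent, with and without aliases", {
  al <- read_alias_tsv(alias_fixture_path())
  raws <- c("Braf", " grik3 ", "PPAP2A", "pvrl3", "MKL1", "NewGene7")
  for (r in raws) {
    once <- normalize_symbol(r, al)
    expect_identical(normalize_symbol(once, al), once)
  }
})

test_that("alias tables must be functional with fixed-point targets", {
  expect_error(alias_table(c("A", "A"), c("B", "C")), "multiple targets")
  # key B maps away while also being a target -> not a fixed point
  expect_error(alias_table(c("A", "B"), c("B", "C")), "fixed point")
  # self-mapping keys are fine
  expect_silent(alias_table(c("A", "B"), c("B", "B")))
})

test_that("non-coding records are filtered, unknowns retained with a note", {
  rec <- make_records(c("BRAF", "MIR155"), gene_class = c("protein_coding", "miRNA"))
  expect_identical(filter_noncoding(rec)$symbol, "BRAF")

  empty <- make_records(character(0))
  expect_identical(nrow(filter_noncoding(empty)), 0L)

  classes <- c(rep("antisense", 3), rep("protein_coding", 4),
               rep("unknown", 2), "other_noncoding")
  rec10 <- make_records(paste0("G", 1:10), gene_class = classes)
  expect_message(out <- filter_noncoding(rec10), "2 record")
  expect_identical(nrow(out), 6L)  # 4 coding + 2 unknown
  rec7 <- make_records(paste0("G", 1:10),
                       gene_class = c(rep("antisense", 3),
                                      rep("protein_coding", 7)))
  expect_identical(nrow(filter_noncoding(rec7, quiet = TRUE)), 7L)
})

test_that("pool building is a deduplicating union, order/repetition invariant", {
  rA <- make_records(c("A", "B"), species = "dog")
  rB <- make_records(c("B", "C"), species = "cat")
  p <- build_pool("two", rA, rB)
  expect_identical(p$size, 3L)
  expect_identical(p$symbols, c("A", "B", "C"))
  expect_setequal(p$species_set, c("dog", "cat"))

  expect_identical(build_pool("dup", rA, rA)$size, 2L)

  # permuting or repeating lists never changes the symbol set
  set.seed(42)
  lists <- lapply(1:4, function(i) {
    make_records(sample(LETTERS, sample(3:8, 1)),
                 species = sample(c("dog", "cat", "cattle", "horse"), 1))
  })
  ref <- build_pool("ref", lists)$symbols
  for (i in 1:5) {
    perm <- sample(lists, replace = TRUE)
    expect_identical(build_pool("perm", c(lists, perm))$symbols, ref)
  }
})

test_that("pooled size matches a naive union oracle on planted fixtures", {
  # cat+dog+cattle+horse synthetic lists, 6 planted shared symbols
  # (the smallest list can only hold 5 of them)
  shared <- sprintf("GSH%02d", 1:6)
  sizes <- c(cat = 10, dog = 12, cattle = 8, horse = 5)
  own <- sprintf("GOWN%03d", 1:35)  # disjoint from shared
  lists <- list()
  taken <- 0
  for (sp in names(sizes)) {
    sh <- shared[seq_len(min(6, sizes[[sp]]))]
    k <- sizes[[sp]] - length(sh)
    lists[[sp]] <- make_records(c(sh, own[taken + seq_len(k)]), species = sp)
    taken <- taken + k
  }
  # oracle: naive union over the concatenated lists
  oracle <- length(unique(unlist(lapply(lists, function(r) r$symbol))))
  expect_identical(build_pool("dom", lists)$size, oracle)
  expect_equal(oracle, 6 + sum(pmax(sizes - 6, 0)))
})

test_that("gene-list TSV round-trips and rejects malformed files", {
  rec <- gene_records(
    species = c("amh", "dog", "cat"),
    symbol_raw = c(" Braf", "GRIK3", "rnpc3 "),
    comparison = c("AMH vs Altai", "dog vs wolf", "cat vs wildcat"),
    source = c("srcA", "srcB", "srcC"),
    gene_class = c("protein_coding", "unknown", "miRNA")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genelist_tsv(rec, path)
  back <- read_genelist_tsv(path)
  expect_identical(back, rec)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tcomparison\tsource\tgene_class",
               "amh\tx\ty\tunknown"), bad)
  expect_error(read_genelist_tsv(bad), "symbol_raw")

  badsp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tcomparison\tsource\tsymbol_raw",
               "marsian\tx\ty\tBRAF"), badsp)
  expect_error(read_genelist_tsv(badsp), "unknown species")
})

test_that("the packaged overlap table carries 41 genes", {
  expect_identical(nrow(table1_overlap(long = FALSE)), 41L)
  expect_identical(length(unique(table1_overlap()$symbol)), 41L)
})
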
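test_that("identical neighborhoods are conserved with all flanks shared", {
  v <- compare_neighborhoods(make_nb("amh"), make_nb("dog"))
  expect_identical(v$shared_flanks, 6L)
  expect_true(v$order_consistent)
  expect_true(v$conserved)
})

test_that("whole-block reversal does not break conservation", {
  A <- make_nb("amh")
  B <- reverse_neighborhood(make_nb("cattle"))
  v <- compare_neighborhoods(A, B)
  expect_true(v$conserved)
})

test_that("disjoint flanks and mismatched focals are handled", {
  A <- make_nb("amh")
  B <- make_nb("dog", up = c("X1", "X2", "X3"), dn = c("X4", "X5", "X6"))
  v <- compare_neighborhoods(A, B)
  expect_identical(v$shared_flanks, 0L)
  expect_false(v$conserved)

  expect_error(
    compare_neighborhoods(A, make_nb("dog", focal = "GENE2")),
    "different focal"
  )
})

test_that("neighborhood invariants are enforced", {
  expect_error(synteny_neighborhood("amh", "F", character(0), "D1"), "1\\.\\.8")
  expect_error(synteny_neighborhood("amh", "F", paste0("U", 1:9), "D1"), "1\\.\\.8")
  expect_error(synteny_neighborhood("amh", "F", c("A", "A"), "D1"), "repeat")
  expect_error(synteny_neighborhood("amh", "F", "F", "D1"), "own flanks")
})

test_that("comparison is symmetric and reversal-invariant on random cases", {
  set.seed(21)
  pool <- sprintf("GN%02d", 1:20)
  for (i in 1:12) {
    symsA <- sample(pool, 6)
    # B shares a random subset of A's flanks, in a random arrangement
    symsB <- c(sample(symsA, sample(0:6, 1)),
               sample(setdiff(pool, symsA)))[1:6]
    A <- synteny_neighborhood("amh", "FOCAL", symsA[1:3], symsA[4:6])
    B <- synteny_neighborhood("dog", "FOCAL", symsB[1:3], symsB[4:6])
    ab <- compare_neighborhoods(A, B)
    ba <- compare_neighborhoods(B, A)
    expect_identical(ab$conserved, ba$conserved)
    expect_identical(ab$shared_flanks, ba$shared_flanks)
    arb <- compare_neighborhoods(A, reverse_neighborhood(B))
    expect_identical(arb$conserved, ab$conserved)
  }
})

test_that("relaxing thresholds never flips a conserved verdict to false", {
  set.seed(33)
  pool <- sprintf("GN%02d", 1:18)
  for (i in 1:10) {
    symsA <- sample(pool, 8)
    # mix of sharing levels, plus the fully shared case (i == 1)
    symsB <- if (i == 1) symsA else {
      c(sample(symsA, sample(2:8, 1)), sample(setdiff(pool, symsA)))[1:8]
    }
    A <- synteny_neighborhood("amh", "FOCAL", symsA[1:4], symsA[5:8])
    B <- synteny_neighborhood("cat", "FOCAL", symsB[1:4], symsB[5:8])
    for (ms in 4:1) {
      for (mi in 0:3) {
        now <- compare_neighborhoods(A, B, min_shared = ms,
                                     max_insertions = mi)$conserved
        stricter <- compare_neighborhoods(A, B, min_shared = ms + 1,
                                          max_insertions = mi)$conserved
        expect_true(now || !stricter)      # conserved survives relaxation
        if (mi > 0) {
          tighter <- compare_neighborhoods(A, B, min_shared = ms,
                                           max_insertions = mi - 1)$conserved
          expect_true(now || !tighter)
        }
      }
    }
  }
})

test_that("a single tolerated insertion still confirms orthology", {
  # 5 species, 3+3 flanks; one species carries one inserted gene
  species <- c("amh", "cattle", "horse", "dog", "cat")
  nbs <- lapply(species, make_nb)
  nbs[[4]] <- synteny_neighborhood("dog", "GENE1",
                                   upstream = c("U1", "INS1", "U2"),
                                   downstream = c("D1", "D2", "D3"))
  res <- confirm_orthology(nbs, min_shared = 4, max_insertions = 1)
  expect_true(res$conserved_in_all_pairs)
  expect_length(res$verdicts, 4)

  # but with no insertions tolerated the inserted gene breaks the block
  res0 <- confirm_orthology(nbs, min_shared = 4, max_insertions = 0)
  expect_false(res0$conserved_in_all_pairs)
})

test_that("shuffled flanks break orthology; identical species confirm it", {
  species <- c("amh", "cattle", "horse", "dog", "cat")
  expect_true(confirm_orthology(lapply(species, make_nb))$conserved_in_all_pairs)

  shuffled <- generate_neighborhoods(rearrangement = "shuffle", seed = 8)
  expect_false(confirm_orthology(shuffled$neighborhoods)$conserved_in_all_pairs)

  expect_error(confirm_orthology(list(make_nb("amh"))), "at least 2")
})

test_that("a translocated focal gene is never called conserved", {
  tr <- generate_neighborhoods(rearrangement = "translocation", seed = 4)
  nbs <- tr$neighborhoods
  for (ms in 1:8) {
    res <- confirm_orthology(nbs, min_shared = ms)
    expect_false(res$conserved_in_all_pairs)
  }
})

test_that("neighborhood TSV round-trips", {
  nbs <- list(make_nb("amh"), make_nb("dog", up = c("U1", "U9", "U3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_neighborhood_tsv(nbs, path)
  back <- read_neighborhood_tsv(path)
  ord <- order(vapply(back, function(x) x$species, character(1)))
  back <- back[ord]
  expect_identical(back[[1]]$upstream, nbs[[1]]$upstream)
  expect_identical(back[[2]]$upstream, nbs[[2]]$upstream)
  expect_identical(back[[1]]$downstream, nbs[[1]]$downstream)
  expect_identical(back[[2]]$species, "dog")
})

test_that("neighborhoods can be extracted from a GFF3 annotation", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  genes <- c("FLK1", "FLK2", "FLK3", "TARGET", "FLK4", "FLK5", "NCRNA1")
  starts <- c(1000, 3000, 5000, 7000, 9000, 11000, 12000)
  biot <- c(rep("protein_coding", 6), "lncRNA")
  writeLines(c(
    "##gff-version 3",
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t+\t.\tID=g%d;Name=%s;gene_biotype=%s",
            starts, starts + 500, seq_along(genes), genes, biot)
  ), gff)
  nb <- neighborhood_from_gff(gff, "TARGET", species = "amh",
                              flanks_per_side = 2)
  expect_identical(nb$upstream, c("FLK3", "FLK2"))   # nearest first
  expect_identical(nb$downstream, c("FLK4", "FLK5")) # non-coding excluded
  expect_identical(nb$chrom, "chr1")
})
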
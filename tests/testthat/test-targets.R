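test_that("column divergence counts differing comparable pairs", {
  msa <- as_msa(c(a = "AAAA", b = "AAAG", c = "AACG", d = "A-TG"))
  # all identical
  expect_equal(column_divergence(msa, 1), 0)
  # col 4: A,G,G,G -> 3 differing of 6 pairs
  expect_equal(column_divergence(msa, 4), 0.5)
  # gap excluded: col 2 has 3 comparable identical bases
  expect_equal(column_divergence(msa, 2), 0)
  # two taxa, one difference -> 1
  two <- as_msa(c(x = "AT", y = "AA"))
  expect_equal(column_divergence(two, 2), 1)
  # fewer than two comparable bases -> NA
  sparse <- as_msa(c(x = "A-", y = "--", z = "--"))
  expect_true(is.na(column_divergence(sparse, 2)))
})

test_that("column divergence matches the exhaustive pairwise oracle", {
  set.seed(41)
  for (rep in 1:10) {
    seqs <- vapply(1:6, function(i) {
      paste(sample(c("A", "C", "G", "T", "N", "-"), 50, replace = TRUE,
                   prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
    }, character(1))
    msa <- as_msa(stats::setNames(seqs, paste0("t", 1:6)))
    mine <- column_divergence(msa)
    ref <- vapply(1:50, function(j) oracle_column_divergence(msa, j),
                  numeric(1))
    expect_equal(mine, ref)
  }
})

# a hand-built alignment: invariant flanks around one divergent block
block_msa <- function(flank = 100, block = 500, n_taxa = 4, every = 8) {
  set.seed(42)
  ref <- sample(c("A", "C", "G", "T"), flank * 2 + block, replace = TRUE)
  msa <- matrix(rep(ref, each = n_taxa), nrow = n_taxa)
  rownames(msa) <- paste0("t", 1:n_taxa)
  var_cols <- seq(flank + 1, flank + block, by = every)
  var_cols <- unique(c(flank + 1, flank + block, var_cols))
  for (cc in var_cols) {
    alt <- setdiff(c("A", "C", "G", "T"), ref[cc])[1]
    msa[1:2, cc] <- alt
  }
  list(msa = msa, start = flank + 1, end = flank + block)
}

test_that("the region scan finds a divergent block between conserved flanks", {
  bm <- block_msa()
  regions <- scan_variable_regions(bm$msa, min_len = 400, max_len = 1000,
                                   flank_len = 25)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, bm$start)
  expect_equal(regions$end, bm$end)
  expect_equal(regions$left_flank_div, 0)
  expect_equal(regions$right_flank_div, 0)
  expect_gt(regions$divergence, 0)
  # a fully invariant alignment yields nothing
  inv <- as_msa(c(a = strrep("ACGT", 200), b = strrep("ACGT", 200)))
  expect_equal(nrow(scan_variable_regions(inv, min_len = 400)), 0)
  # an alignment shorter than any window warns and returns empty
  expect_warning(
    short <- scan_variable_regions(as_msa(c(a = "ACGT", b = "ACGT"))),
    "shorter")
  expect_equal(nrow(short), 0)
})

test_that("scan output is non-overlapping, ranked, and occupancy-aware", {
  sim <- simulate_plastome_msa(length = 30000, n_blocks = 10, seed = 43)
  regions <- scan_variable_regions(sim$msa)
  expect_equal(nrow(regions), 10)
  ord <- order(regions$start)
  r <- regions[ord, ]
  expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  expect_equal(regions$divergence, sort(regions$divergence,
                                        decreasing = TRUE))
  expect_equal(regions$rank, seq_len(nrow(regions)))
  # a block without room for a conserved flank is not reported
  tight <- block_msa(flank = 10)
  expect_equal(nrow(scan_variable_regions(tight$msa, flank_len = 25)), 0)
})

test_that("conserved islands pair up at amplifiable separations", {
  # 30 bp islands covered by 2 taxa, 500 columns apart
  width <- 1200
  aln <- matrix("-", nrow = 3, ncol = width,
                dimnames = list(c("t1", "t2", "t3"), NULL))
  isl1 <- 101:130; isl2 <- 631:660
  aln[1:2, isl1] <- "A"
  aln[1:2, isl2] <- "C"
  res <- find_conserved_islands(aln)
  expect_equal(nrow(res$islands), 2)
  expect_equal(res$islands$start, c(101, 631))
  expect_equal(nrow(res$candidates), 1)
  expect_equal(res$candidates$separation, 500)
  # 300 apart fails without introns, qualifies with one predicted intron
  aln2 <- matrix("-", nrow = 2, ncol = 800,
                 dimnames = list(c("t1", "t2"), NULL))
  aln2[, 101:130] <- "G"
  aln2[, 431:460] <- "T"
  expect_equal(nrow(find_conserved_islands(aln2)$candidates), 0)
  withintron <- find_conserved_islands(aln2, introns = 250)
  expect_equal(withintron$candidates$effective_sep, 400)
  expect_equal(nrow(withintron$candidates), 1)
  # single-taxon coverage never forms an island
  solo <- matrix("-", nrow = 2, ncol = 100,
                 dimnames = list(c("t1", "t2"), NULL))
  solo[1, 10:90] <- "A"
  expect_equal(nrow(find_conserved_islands(solo)$islands), 0)
})

test_that("alignment cleaning drops under-occupied columns, idempotently", {
  rows <- c(rep("A-AN", 3), rep("AAAA", 7))
  msa <- as_msa(stats::setNames(rows, sprintf("t%02d", 1:10)))
  # col 2 has 7/10 bases (>= 0.5, kept); make a worse column
  msa[4:7, 2] <- "-"   # now 3/10 bases in col 2
  cleaned <- clean_alignment(msa, occupancy = 0.5)
  expect_equal(ncol(cleaned), 3)
  expect_equal(attr(cleaned, "kept_columns"), c(1, 3, 4))
  # N does not count as occupancy
  expect_equal(unname(colSums(cleaned != "-" & cleaned != "N") >= 5),
               rep(TRUE, 3))
  # gap-free alignments pass through; occupancy 0 keeps everything
  full <- as_msa(c(a = "ACGT", b = "ACGT"))
  expect_equal(ncol(clean_alignment(full)), 4)
  expect_equal(ncol(clean_alignment(msa, occupancy = 0)), 4)
  # idempotence
  expect_equal(unclass(clean_alignment(cleaned, 0.5))[, ],
               unclass(cleaned)[, ])
})

test_that("concatenation fills absent taxa with gaps and partitions exactly", {
  m1 <- as_msa(c(a = "ACGT", b = "ACGA", c = "ACGC"))
  m2 <- as_msa(c(a = "TTTTTT", b = "TTATTT"))
  res <- concat_alignments(list(loc1 = m1, loc2 = m2))
  expect_equal(ncol(res$supermatrix), 10)
  expect_equal(res$partitions$start, c(1, 5))
  expect_equal(res$partitions$end, c(4, 10))
  # taxon c missing from loc2 -> gap block
  expect_equal(paste(res$supermatrix["c", 5:10], collapse = ""), "------")
  # slicing by partition recovers each input for shared taxa
  sl <- res$supermatrix[c("a", "b"), 5:10]
  expect_equal(sl, m2[c("a", "b"), ])
  # many loci stay contiguous and cover the matrix
  msas <- lapply(1:12, function(i) m1)
  names(msas) <- paste0("L", 1:12)
  big <- concat_alignments(msas)
  expect_equal(big$partitions$start,
               c(1, head(big$partitions$end, -1) + 1))
  expect_equal(tail(big$partitions$end, 1), ncol(big$supermatrix))
})
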
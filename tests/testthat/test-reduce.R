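test_that("3' trimming removes the requested bases from each mate", {
  set.seed(21)
  reads <- data.frame(id = "r1", r1_seq = random_seq(300),
                      r1_qual = strrep("I", 300),
                      r2_seq = random_seq(300),
                      r2_qual = strrep("I", 300),
                      stringsAsFactors = FALSE)
  tr <- trim_pair(reads, 75, 150)
  expect_equal(nchar(tr$r1_seq), 225)
  expect_equal(nchar(tr$r2_seq), 150)
  expect_equal(tr$r1_seq, substr(reads$r1_seq, 1, 225))
  expect_equal(nchar(tr$r1_qual), 225)
  # zero trim is the identity
  expect_identical(trim_pair(reads, 0, 0), reads)
  # trimming a whole read empties it with a warning
  short <- data.frame(id = "r", r1_seq = "ACGTACGTAC",
                      r1_qual = "IIIIIIIIII", r2_seq = "ACGTACGTAC",
                      r2_qual = "IIIIIIIIII", stringsAsFactors = FALSE)
  expect_warning(tr2 <- trim_pair(short, 10, 0), "empty")
  expect_equal(tr2$r1_seq, "")
})

test_that("mate joining prefers clean overlaps and otherwise concatenates", {
  set.seed(22)
  amplicon <- random_seq(250)
  # mates overlapping by 50 bases with no mismatches
  r1 <- substr(amplicon, 1, 150)
  r2 <- revcomp(substr(amplicon, 101, 250))
  j <- join_pair(r1, r2)
  expect_true(j$joined)
  expect_equal(nchar(j$sequence), 150 + 150 - 50)
  expect_equal(j$sequence, amplicon)
  # 9 identical terminal bases are below the 10 bp floor: concatenate
  a <- random_seq(60)
  tail9 <- substr(a, 52, 60)
  b <- paste0(tail9, random_seq(51))
  jj <- join_pair(a, revcomp(b), min_overlap = 10)
  expect_false(jj$joined)
  expect_equal(jj$sequence, paste0(a, b))
  expect_equal(jj$junction, 60)
  # 400 bp amplicon read as 225 + 150 trimmed mates cannot overlap
  amp <- random_seq(400)
  r1t <- substr(amp, 1, 225)
  r2t <- substr(revcomp(amp), 1, 150)
  jt <- join_pair(r1t, r2t)
  expect_false(jt$joined)
  expect_equal(nchar(jt$sequence), 375)
  # disagreements resolve toward the higher-quality base
  left <- random_seq(40); ov <- random_seq(30); right <- random_seq(40)
  r1d <- paste0(left, ov)
  ov2 <- ov; substr(ov2, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                            substr(ov, 15, 15))[1]
  r2d <- revcomp(paste0(ov2, right))
  q1 <- strrep("5", 70); q2 <- strrep("I", 70)  # read 2 higher quality
  jd <- join_pairs(data.frame(id = "x", r1_seq = r1d, r1_qual = q1,
                              r2_seq = r2d, r2_qual = q2,
                              stringsAsFactors = FALSE))
  expect_true(jd$joined)
  expect_equal(substr(jd$sequence, 41, 70), ov2)
})

test_that("modal-length reduction keeps the dominant length, ties go long", {
  set.seed(23)
  seqs <- c(replicate(90, random_seq(300)), replicate(10, random_seq(299)))
  m <- reduce_to_modal_length(seqs)
  expect_equal(m$modal_length, 300)
  expect_equal(sum(m$keep), 90)
  # all equal lengths: identity
  expect_true(all(reduce_to_modal_length(seqs[1:90])$keep))
  # 50/50 tie between 300 and 310: keep the longer
  tie <- c(replicate(50, random_seq(300)), replicate(50, random_seq(310)))
  expect_equal(reduce_to_modal_length(tie)$modal_length, 310)
})

test_that("consensus thresholds gate ambiguity codes site by site", {
  base <- "AAGCT"
  # 10 identical reads: identical consensus in both modes
  expect_equal(consensus_sequence(rep(base, 10), "consensus"), base)
  expect_equal(consensus_sequence(rep(base, 10), "ambiguity"), base)
  # site 3 split 60 G / 40 A over 100 reads: R with thresholds 5 reads / 5%
  seqs <- c(rep("AAGCT", 60), rep("AAACT", 40))
  expect_equal(consensus_sequence(seqs, "ambiguity"), "AARCT")
  expect_equal(consensus_sequence(seqs, "consensus"), "AAGCT")
  # 96/4: the 4-read variant misses the absolute threshold in both modes
  seqs2 <- c(rep("AAGCT", 96), rep("AAACT", 4))
  expect_equal(consensus_sequence(seqs2, "ambiguity"), "AAGCT")
  expect_equal(consensus_sequence(seqs2, "consensus"), "AAGCT")
  # plurality ties break alphabetically
  expect_equal(consensus_sequence(c("A", "C"), "consensus"), "A")
})

test_that("allele recovery applies both support thresholds exactly", {
  set.seed(24)
  p <- random_seq(120)
  q <- substitute_at(p, c(10, 60))
  singles <- replicate(5, random_seq(120))
  pool <- c(rep(p, 55), rep(q, 40), singles)
  as <- call_alleles(pool)
  expect_equal(as$status, "ok")
  expect_equal(nrow(as$alleles), 2)
  expect_equal(as$alleles$sequence, c(p, q))
  expect_equal(as$alleles$count, c(55, 40))
  expect_equal(as$alleles$frequency, c(0.55, 0.40))
  # one unanimous allele
  uni <- call_alleles(rep(p, 100))
  expect_equal(nrow(uni$alleles), 1)
  expect_equal(uni$alleles$frequency, 1.0)
  # four alleles at 25 reads each all survive
  quad <- call_alleles(c(rep(p, 25), rep(q, 25),
                         rep(substitute_at(p, 30), 25),
                         rep(substitute_at(p, 90), 25)))
  expect_equal(nrow(quad$alleles), 4)
  # all-distinct pool: nothing passes, the target is discarded
  lost <- call_alleles(replicate(100, random_seq(120)))
  expect_equal(as.character(lost$status), "discarded")
  expect_equal(nrow(lost$alleles), 0)
  # frequencies always sum to <= 1
  expect_lte(sum(quad$alleles$frequency), 1)
})

test_that("full pool reduction recovers simulated truth without noise", {
  set.seed(25)
  sim <- simulate_pool(n_alleles = 2, depth = 80, error_rate = 0)
  red <- reduce_pool(sim$pool, reduce_config(mode = "occurrence"))
  expect_equal(red$category, "joined")
  expect_equal(sort(red$alleles$alleles$sequence), sim$truth_alleles)
  # empty pool fails cleanly
  empty <- make_pool(character(0))
  empty$reads <- empty$reads[0, ]
  expect_equal(reduce_pool(empty)$category, "failed")
  # 4 reads cannot satisfy the 5-read floor in occurrence mode
  small <- make_pool(rep("ACGTACGTACGTACGTACGT", 4))
  rs <- reduce_pool(small, reduce_config(mode = "occurrence"))
  expect_equal(rs$category, "failed")
  expect_equal(rs$alleles$status, "discarded")
})

test_that("reduction is deterministic and idempotent on reduced input", {
  set.seed(26)
  sim <- simulate_pool(n_alleles = 3, depth = 60, error_rate = 0.002)
  r1 <- reduce_pool(sim$pool, reduce_config(mode = "occurrence"))
  r2 <- reduce_pool(sim$pool, reduce_config(mode = "occurrence"))
  expect_identical(r1, r2)
  # a pool already reduced to one sequence reduces to itself
  one <- make_pool(rep("ACGTTGCAACGTTGCAACGTACGTTGCA", 12))
  cons <- reduce_pool(one, reduce_config(mode = "consensus"))
  expect_equal(cons$consensus, "ACGTTGCAACGTTGCAACGTACGTTGCA")
  again <- make_pool(rep(cons$consensus, 12))
  expect_equal(reduce_pool(again,
                           reduce_config(mode = "consensus"))$consensus,
               cons$consensus)
})

test_that("lenient ambiguity settings reduce to the strict consensus", {
  set.seed(27)
  seqs <- c(rep("ACGTA", 7), rep("ACTTA", 3))
  # with s = 1 and f > 0.5 only the majority base can pass per column
  expect_equal(consensus_sequence(seqs, "ambiguity", min_reads = 1,
                                  min_freq = 0.51),
               consensus_sequence(seqs, "consensus"))
})
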
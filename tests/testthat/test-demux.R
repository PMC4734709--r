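bc_table <- data.frame(name = c("bc1", "bc2", "bc3"),
                       sequence = c("ACGTACGT", "TTGGCCAA", "GGAACCTT"),
                       stringsAsFactors = FALSE)

test_that("barcode lookup accepts single errors and rejects ambiguity", {
  # identity
  hit <- match_barcode("ACGTACGT", bc_table)
  expect_equal(hit$name, "bc1")
  expect_equal(hit$dist, 0)
  # one substitution from exactly one barcode
  hit <- match_barcode("ACGTACGA", bc_table, max_dist = 1)
  expect_equal(hit$name, "bc1")
  expect_equal(hit$dist, 1)
  # two substitutions from the nearest barcode: unmatched
  obs <- "ACGTAGCT"
  expect_equal(oracle_barcode(obs, bc_table$sequence)$dist, 2)
  expect_true(is.na(match_barcode(obs, bc_table)$name))
  # equidistant between two barcodes differing at 2 positions: unmatched
  two <- data.frame(name = c("x", "y"),
                    sequence = c("AAAAAAAA", "AAAAAATT"))
  expect_true(is.na(match_barcode("AAAAAAAT", two, max_dist = 1)$name))
})

test_that("barcode lookup agrees with brute-force nearest search", {
  set.seed(101)
  bcs <- amplikit:::random_barcodes(12)
  tab <- data.frame(name = paste0("b", seq_along(bcs)), sequence = bcs)
  for (i in 1:300) {
    obs <- substitute_at(sample(bcs, 1), sample(8, sample(0:3, 1)))
    mine <- match_barcode(obs, tab, max_dist = 1)
    ref <- oracle_barcode(obs, bcs, max_dist = 1)
    expect_equal(is.na(mine$name), is.na(ref$idx))
    if (!is.na(ref$idx)) {
      expect_equal(mine$name, tab$name[ref$idx])
      expect_equal(mine$dist, ref$dist)
    }
  }
})

test_that("firm-end primer matching follows the edit and anchor rules", {
  primer <- "ACGGTTCAGCTAAGGCTTCA"   # 20 nt, firm 3' block "TTCA"
  primers <- data.frame(target = "tg", seq = primer)
  cfg <- demux_config()
  pad <- strrep("T", 20)
  # exact prefix
  hit <- match_primer(paste0(primer, pad), primers, cfg)
  expect_equal(hit$target, "tg")
  expect_equal(hit$dist, 0)
  expect_equal(hit$consumed, 20)
  # 4 substitutions, none in the 3'-terminal firm block: still a match
  mutated <- primer
  substr(mutated, 1, 1) <- "C"; substr(mutated, 5, 5) <- "A"
  substr(mutated, 9, 9) <- "T"; substr(mutated, 13, 13) <- "C"
  expect_equal(oracle_firm_end(paste0(mutated, pad), primer,
                               max_dist = 20), 4)
  hit <- match_primer(paste0(mutated, pad), primers, cfg)
  expect_equal(hit$target, "tg")
  expect_equal(hit$dist, 4)
  # one substitution inside the firm block: no match
  firmhit <- primer
  substr(firmhit, 18, 18) <- "G"
  expect_true(is.na(match_primer(paste0(firmhit, pad), primers,
                                 cfg)$target))
  # five edits exceed the default budget
  five <- mutated
  substr(five, 15, 15) <- "C"
  expect_gt(oracle_firm_end(paste0(five, pad), primer, max_dist = 20), 4)
  expect_true(is.na(match_primer(paste0(five, pad), primers, cfg)$target))
  # an indel before the firm block shifts the consumed length
  del <- paste0(substr(primer, 1, 7), substr(primer, 9, 20))
  hit <- match_primer(paste0(del, pad), primers, cfg)
  expect_equal(hit$target, "tg")
  expect_equal(hit$dist, 1)
  expect_equal(hit$consumed, 19)
})

test_that("firm-end matching agrees with the exhaustive oracle", {
  set.seed(202)
  cfg <- demux_config()
  for (i in 1:400) {
    plen <- sample(15:25, 1)
    primer <- random_seq(plen)
    read <- paste0(substitute_at(primer, sample(plen, sample(0:5, 1))),
                   random_seq(15))
    ref <- oracle_firm_end(read, primer)
    mine <- match_primer(read, data.frame(target = "t", seq = primer), cfg)
    if (is.na(ref)) {
      expect_true(is.na(mine$dist) || mine$dist > 4 || is.na(mine$target))
      expect_true(is.na(mine$target))
    } else {
      expect_equal(mine$dist, ref)
    }
  }
})

noise_free_run <- function(n_samples = 4, n_targets = 3, depth = 50,
                           seed = 77) {
  simulate_run(sim_config(n_samples = n_samples, n_targets = n_targets,
                          depth_mean = depth, depth_dispersion = Inf,
                          error_rate = 0, barcode_error_rate = 0,
                          seed = seed))
}

test_that("an error-free run demultiplexes completely into even pools", {
  run <- noise_free_run()
  res <- demultiplex(run$reads, run$sheets)
  expect_equal(res$report$fraction_assigned, 1)
  expect_equal(res$report$n_pools, 4 * 3)
  expect_true(all(res$report$pool_counts$reads == 50))
  # conservation holds read by read
  expect_equal(res$report$assigned + res$report$unassigned,
               res$report$total_reads)
  # primer bases were stripped: pooled read 1 starts at the insert
  pool <- res$pools[[1]]
  tg <- pool$target_id
  truth <- run$truth$alleles
  inserts <- truth$sequence[truth$sample == pool$sample_id &
                              truth$target == tg]
  expect_true(all(substr(pool$reads$r1_seq, 1, 50) %in%
                    substr(inserts, 1, 50)))
})

test_that("a barcode ruined at 2 positions leaves its read unassigned", {
  run <- noise_free_run()
  reads <- run$reads
  reads$r1_bc[1] <- substitute_at(reads$r1_bc[1], c(1, 3))
  res <- demultiplex(reads, run$sheets)
  expect_equal(res$report$assigned, nrow(reads) - 1)
  expect_equal(res$assignments$fail_reason[1], "barcode")
  expect_equal(res$assignments$sample_id[1], "UNASSIGNED")
})

test_that("raising the primer budget never loses reads; relabeling is neutral", {
  run <- simulate_run(sim_config(n_samples = 4, n_targets = 3,
                                 depth_mean = 30, error_rate = 0.02,
                                 seed = 13))
  counts <- vapply(0:4, function(d) {
    demultiplex(run$reads, run$sheets,
                demux_config(max_primer_dist = d))$report$assigned
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # permuting sample labels permutes pools but leaves counts unchanged
  sheets2 <- run$sheets
  sheets2$samples$sample <- rev(sheets2$samples$sample)
  a <- demultiplex(run$reads, run$sheets)$report
  b <- demultiplex(run$reads, sheets2)$report
  expect_equal(a$assigned, b$assigned)
  expect_equal(sort(a$pool_counts$reads), sort(b$pool_counts$reads))
})

test_that("run bookkeeping arithmetic matches the array design", {
  bk <- multiplex_bookkeeping()
  expect_equal(bk$pools_per_array, 2304)
  expect_equal(bk$barcode_pairs, 864)
  expect_equal(bk$max_multiplexed_samples, 1152)
  expect_equal(bk$total_amplicons, 55296)
  expect_equal(bk$arrays_required, 24)
  expect_equal(bk$plates_required_two_step, 1152)
})
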
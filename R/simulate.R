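## Synthetic microfluidic amplicon runs with full ground truth.
##
## A simulated read pair mirrors the four-primer amplicon anatomy: the
## amplicon is fwd_primer + insert + revcomp(rev_primer); read 1 is its
## 5' prefix, read 2 the 5' prefix of its reverse complement, and the dual
## barcodes travel as index sequences with their own (synthesis/sequencing)
## error rate. Substitution errors ramp up toward read 3' ends, the
## dominant MiSeq error mode; indels are not simulated because allele
## identity downstream is exact sequence match.

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

## substitute each site with probability `rate`; force at least
## `min_changes` substitutions (used to guarantee distinct alleles)
mutate_seq <- function(seq, rate, min_changes = 0) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit) < min_changes) {
    hit <- unique(c(hit, sample(length(bases), min_changes)))
  }
  for (i in hit) {
    bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1)
  }
  paste(bases, collapse = "")
}

## positional per-base error rates: linear ramp from the 5' to the 3' end
## with 3'/5' ratio `ramp`, scaled so the mean equals `mean_rate`
position_error_rates <- function(len, mean_rate, ramp = 4) {
  if (len == 0) return(numeric(0))
  if (mean_rate <= 0) return(rep(0, len))
  a <- 2 / (ramp + 1)
  if (len == 1) return(mean_rate)
  mean_rate * (a + a * (ramp - 1) * (seq_len(len) - 1) / (len - 1))
}

rates_to_qual <- function(rates) {
  q <- ifelse(rates <= 0, 40L,
              pmin(40L, pmax(2L, as.integer(round(-10 * log10(rates))))))
  intToUtf8(33L + q, multiple = FALSE)
}

## inject substitution errors into a vector of equal-length reads;
## returns list(seqs, n_errors per read)
add_read_errors <- function(seqs, rates) {
  n <- length(seqs)
  len <- length(rates)
  n_err <- integer(n)
  if (n == 0 || len == 0 || all(rates <= 0)) {
    return(list(seqs = seqs, n_errors = n_err))
  }
  u <- matrix(stats::runif(n * len), nrow = n)
  hits <- which(u < matrix(rates, nrow = n, ncol = len, byrow = TRUE),
                arr.ind = TRUE)
  if (nrow(hits) > 0) {
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1]; p <- hits[k, 2]
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, cur), 1)
    }
    tab <- tabulate(hits[, 1], nbins = n)
    n_err <- tab
  }
  list(seqs = seqs, n_errors = n_err)
}

#' Simulation configuration
#'
#' Defaults emulate one small microfluidic run: 300 bp paired-end reads over
#' amplicons of 350-550 bp (so untrimmed mates overlap and join), 8 bp dual
#' barcodes, ~20 bp target-specific primers, negative-binomial pool depth
#' (amplicon recovery is uneven in practice), substitution errors ramping
#' toward read 3' ends, and per-sample ploidy cycling through haploid,
#' diploid and tetraploid.
#'
#' @param n_samples,n_targets run dimensions (defaults 8 and 6).
#' @param target_len_range amplicon length range including primers
#'   (default c(350, 550)).
#' @param ploidy integer vector of per-sample ploidies in {1,2,4}, recycled
#'   to `n_samples`; default cycles 1, 2, 4.
#' @param heterozygosity probability that a locus copy pair is heterozygous
#'   (per homeolog pair in tetraploids). Default 0.5.
#' @param allele_divergence substitutions/site between alleles of a pair
#'   (default 0.01; at least one substitution is guaranteed when
#'   heterozygous).
#' @param homeolog_divergence substitutions/site between tetraploid
#'   subgenome copies (default 0.02, at least one substitution).
#' @param depth_mean,depth_dispersion negative-binomial pool depth (mean and
#'   size); `depth_dispersion = Inf` gives constant depth. Defaults 50, 8.
#' @param read_len read length (default 300).
#' @param error_rate mean per-base substitution error rate (default 0.002).
#' @param error_ramp ratio of the 3'-end to 5'-end error rate (default 4).
#' @param barcode_error_rate per-base substitution rate on index reads
#'   (default 0.001).
#' @param seed mandatory RNG seed; the same seed reproduces the run
#'   byte-for-byte.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 8, n_targets = 6,
                       target_len_range = c(350, 550), ploidy = NULL,
                       heterozygosity = 0.5, allele_divergence = 0.01,
                       homeolog_divergence = 0.02, depth_mean = 50,
                       depth_dispersion = 8, read_len = 300,
                       error_rate = 0.002, error_ramp = 4,
                       barcode_error_rate = 0.001, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed",
                          call. = FALSE)
  if (is.null(ploidy)) ploidy <- rep_len(c(1L, 2L, 4L), n_samples)
  ploidy <- rep_len(as.integer(ploidy), n_samples)
  stopifnot(all(ploidy %in% c(1L, 2L, 4L)),
            heterozygosity >= 0, heterozygosity <= 1,
            allele_divergence >= 0, allele_divergence <= 1,
            error_rate >= 0, error_rate <= 1,
            barcode_error_rate >= 0, barcode_error_rate <= 1,
            depth_mean >= 1, read_len >= 50,
            target_len_range[1] >= read_len / 2)
  structure(list(n_samples = as.integer(n_samples),
                 n_targets = as.integer(n_targets),
                 target_len_range = as.integer(target_len_range),
                 ploidy = ploidy, heterozygosity = heterozygosity,
                 allele_divergence = allele_divergence,
                 homeolog_divergence = homeolog_divergence,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 read_len = as.integer(read_len), error_rate = error_rate,
                 error_ramp = error_ramp,
                 barcode_error_rate = barcode_error_rate,
                 seed = as.integer(seed)), class = "sim_config")
}

## random barcode set with pairwise edit distance > min_dist
random_barcodes <- function(n, len = 8, min_dist = 2) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(len)
    if (length(out) == 0 ||
        all(edit_distance(rep(cand, length(out)), out) > min_dist)) {
      out <- c(out, cand)
    }
  }
  out
}

#' Generate run sheets for a simulation
#'
#' Barcodes are 8 bp with pairwise edit distance > 2 within each end (the
#' design rule that keeps single-error reads unambiguous); primers are
#' 20 bp with pairwise distance >= 10 so that firm-end matching with up to
#' 4 edits can never be ambiguous. Samples take barcode pairs in row-major
#' (P5-major) order.
#'
#' @param config a [sim_config()]; uses the session RNG (callers seed it).
#' @param n_p5,n_p7 barcode counts per end (defaults: smallest counts whose
#'   product covers `n_samples`).
#' @param genome genome label for all simulated targets (default
#'   "nuclear").
#' @return an `amplikit_sheets` list as from [load_sheets()].
#' @export
simulate_sheets <- function(config, n_p5 = NULL, n_p7 = NULL,
                            genome = "nuclear") {
  n <- config$n_samples
  if (is.null(n_p5)) n_p5 <- max(2L, ceiling(sqrt(n)))
  if (is.null(n_p7)) n_p7 <- max(2L, ceiling(n / n_p5))
  if (n_p5 * n_p7 < n) stop("not enough barcode pairs for n_samples",
                            call. = FALSE)
  barcodes <- data.frame(
    name = c(sprintf("P5_%02d", seq_len(n_p5)),
             sprintf("P7_%02d", seq_len(n_p7))),
    end = c(rep("P5", n_p5), rep("P7", n_p7)),
    sequence = c(random_barcodes(n_p5), random_barcodes(n_p7)),
    stringsAsFactors = FALSE)
  primers <- data.frame(
    target = sprintf("target_%02d", seq_len(config$n_targets)),
    genome = rep_len(genome, config$n_targets),
    fwd = random_barcodes(config$n_targets, len = 20, min_dist = 9),
    rev = random_barcodes(config$n_targets, len = 20, min_dist = 9),
    stringsAsFactors = FALSE)
  pairs <- expand.grid(p7 = seq_len(n_p7), p5 = seq_len(n_p5))
  samples <- data.frame(
    sample = sprintf("sample_%02d", seq_len(n)),
    p5 = sprintf("P5_%02d", pairs$p5[seq_len(n)]),
    p7 = sprintf("P7_%02d", pairs$p7[seq_len(n)]),
    project = "sim", stringsAsFactors = FALSE)
  structure(list(barcodes = barcodes, primers = primers, samples = samples,
                 barcode_pairs = n_p5 * n_p7), class = "amplikit_sheets")
}

## draw the distinct allele inserts and copy proportions for one
## (sample, target) given ploidy and the target's base insert
draw_alleles <- function(base_insert, ploidy, het, allele_div, homeo_div,
                         haploid_genome = FALSE) {
  if (haploid_genome || ploidy == 1L) {
    copies <- mutate_seq(base_insert, allele_div)
  } else if (ploidy == 2L) {
    a <- mutate_seq(base_insert, allele_div)
    b <- if (stats::runif(1) < het) mutate_seq(a, allele_div, 1) else a
    copies <- c(a, b)
  } else {
    h1 <- mutate_seq(base_insert, allele_div)
    h2 <- mutate_seq(h1, homeo_div, 1)
    p1 <- if (stats::runif(1) < het) mutate_seq(h1, allele_div, 1) else h1
    p2 <- if (stats::runif(1) < het) mutate_seq(h2, allele_div, 1) else h2
    copies <- c(h1, p1, h2, p2)
  }
  tab <- table(copies)
  list(alleles = names(tab), proportions = as.numeric(tab) / length(copies))
}

apply_barcode_errors <- function(bcs, rate) {
  if (rate <= 0) return(bcs)
  add_read_errors(bcs, rep(rate, nchar(bcs[1])))$seqs
}

#' Simulate a complete dual-barcoded amplicon run
#'
#' Emits a read-pair table (and optionally FASTQ files) together with the
#' full ground truth: every (sample, target) allele mixture and every
#' read's source allele and injected error count. Deterministic under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param sheets run sheets; default generated by [simulate_sheets()].
#' @param out_dir optional directory; when given, writes `r1.fastq`,
#'   `r2.fastq` (headers carry `BC1+BC2` after the last colon), the three
#'   sheets and the truth tables.
#' @return list of class `sim_run`: `reads` (read-pair data.frame as
#'   [read_fastq_pairs()] returns), `sheets`, and `truth` (list with
#'   `samples` — sample/species/ploidy —, `alleles` — sample, target,
#'   allele insert sequence, proportion —, and `reads` — id, sample,
#'   target, allele index, error counts per mate).
#' @export
simulate_run <- function(config, sheets = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(sheets)) sheets <- simulate_sheets(config)
  if (nrow(sheets$samples) < config$n_samples) {
    stop("sheets provide fewer samples than n_samples", call. = FALSE)
  }
  primers <- sheets$primers[seq_len(config$n_targets), , drop = FALSE]
  samples <- sheets$samples[seq_len(config$n_samples), , drop = FALSE]
  bc_seq <- stats::setNames(sheets$barcodes$sequence, sheets$barcodes$name)

  rl <- config$read_len
  rates <- position_error_rates(rl, config$error_rate, config$error_ramp)
  qual <- rates_to_qual(rates)

  ## per-target base inserts
  target_len <- sample(seq(config$target_len_range[1],
                           config$target_len_range[2]),
                       config$n_targets, replace = TRUE)
  base_insert <- vapply(seq_len(config$n_targets), function(t) {
    random_dna(target_len[t] - nchar(primers$fwd[t]) -
                 nchar(primers$rev[t]))
  }, character(1))

  reads_acc <- vector("list", config$n_samples * config$n_targets)
  allele_rows <- vector("list", length(reads_acc))
  read_rows <- vector("list", length(reads_acc))
  counter <- 0L
  k <- 0L
  for (s in seq_len(config$n_samples)) {
    for (t in seq_len(config$n_targets)) {
      k <- k + 1L
      mix <- draw_alleles(base_insert[t], config$ploidy[s],
                          config$heterozygosity, config$allele_divergence,
                          config$homeolog_divergence,
                          primers$genome[t] == "chloroplast")
      allele_rows[[k]] <- data.frame(
        sample = samples$sample[s], target = primers$target[t],
        allele = seq_along(mix$alleles), sequence = mix$alleles,
        proportion = mix$proportions, stringsAsFactors = FALSE)
      depth <- if (is.finite(config$depth_dispersion)) {
        stats::rnbinom(1, mu = config$depth_mean,
                       size = config$depth_dispersion)
      } else as.integer(config$depth_mean)
      if (depth == 0) next
      src <- sample(seq_along(mix$alleles), depth, replace = TRUE,
                    prob = mix$proportions)
      amplicon <- paste0(primers$fwd[t], mix$alleles,
                         revcomp(primers$rev[t]))
      r1 <- substr(amplicon[src], 1L, rl)
      r2 <- substr(revcomp(amplicon)[src], 1L, rl)
      e1 <- add_read_errors(r1, rates)
      e2 <- add_read_errors(r2, rates)
      ids <- sprintf("sim:%07d", counter + seq_len(depth))
      counter <- counter + depth
      reads_acc[[k]] <- data.frame(
        id = ids, r1_seq = e1$seqs, r1_qual = substring(qual, 1, nchar(r1)),
        r2_seq = e2$seqs, r2_qual = substring(qual, 1, nchar(r2)),
        r1_bc = apply_barcode_errors(rep(bc_seq[[samples$p5[s]]], depth),
                                     config$barcode_error_rate),
        r2_bc = apply_barcode_errors(rep(bc_seq[[samples$p7[s]]], depth),
                                     config$barcode_error_rate),
        stringsAsFactors = FALSE)
      read_rows[[k]] <- data.frame(
        id = ids, sample = samples$sample[s], target = primers$target[t],
        allele = src, n_errors_r1 = e1$n_errors, n_errors_r2 = e2$n_errors,
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, reads_acc[!vapply(reads_acc, is.null,
                                            logical(1))])
  rownames(reads) <- NULL
  truth <- list(
    samples = data.frame(sample = samples$sample,
                         species = paste0("sp_", samples$sample),
                         ploidy = config$ploidy, stringsAsFactors = FALSE),
    alleles = do.call(rbind, allele_rows),
    reads = do.call(rbind, read_rows[!vapply(read_rows, is.null,
                                             logical(1))]))
  rownames(truth$alleles) <- rownames(truth$reads) <- NULL
  run <- structure(list(reads = reads, sheets = sheets, truth = truth),
                   class = "sim_run")
  if (!is.null(out_dir)) write_sim_run(run, out_dir)
  run
}

write_sim_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- run$reads
  hdr1 <- sprintf("%s 1:N:0:%s+%s", reads$id, reads$r1_bc, reads$r2_bc)
  hdr2 <- sprintf("%s 2:N:0:%s+%s", reads$id, reads$r1_bc, reads$r2_bc)
  write_fastq(hdr1, reads$r1_seq, reads$r1_qual,
              file.path(out_dir, "r1.fastq"))
  write_fastq(hdr2, reads$r2_seq, reads$r2_qual,
              file.path(out_dir, "r2.fastq"))
  write_table(run$sheets$barcodes, file.path(out_dir, "barcodes.tsv"))
  write_table(run$sheets$primers, file.path(out_dir, "primers.tsv"))
  write_table(run$sheets$samples, file.path(out_dir, "samples.tsv"))
  write_table(run$truth$samples, file.path(out_dir, "truth_samples.tsv"))
  write_table(run$truth$alleles, file.path(out_dir, "truth_alleles.tsv"))
  write_table(run$truth$reads, file.path(out_dir, "truth_reads.tsv"))
  invisible(out_dir)
}

#' Simulate one demultiplexed amplicon pool with a known allele count
#'
#' Convenience generator for reduction benchmarks: `n_alleles` distinct
#' insert sequences at the given proportions, sequenced to `depth` with the
#' usual 3'-ramped substitution errors. Reads are primer-stripped (as they
#' come out of demultiplexing). Uses the session RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param n_alleles number of distinct alleles (1-4).
#' @param insert_len insert length (default 450).
#' @param depth pool read count (default 100).
#' @param read_len post-strip read length (default 280).
#' @param error_rate,error_ramp substitution model (defaults 0.002, 4).
#' @param allele_divergence substitutions/site between alleles (default
#'   0.01, at least 1 guaranteed).
#' @param proportions allele mixture (default equal).
#' @return list with `pool` (an `amplicon_pool`) and `truth_alleles`
#'   (character vector of the distinct insert sequences).
#' @export
simulate_pool <- function(n_alleles, insert_len = 450, depth = 100,
                          read_len = 280, error_rate = 0.002,
                          error_ramp = 4, allele_divergence = 0.01,
                          proportions = NULL) {
  stopifnot(n_alleles >= 1, insert_len <= 2 * read_len)
  alleles <- random_dna(insert_len)
  while (length(alleles) < n_alleles) {
    cand <- mutate_seq(alleles[1], allele_divergence, 1)
    if (!cand %in% alleles) alleles <- c(alleles, cand)
  }
  if (is.null(proportions)) proportions <- rep(1 / n_alleles, n_alleles)
  rates <- position_error_rates(read_len, error_rate, error_ramp)
  qual <- rates_to_qual(rates)
  src <- sample(seq_len(n_alleles), depth, replace = TRUE,
                prob = proportions)
  r1 <- substr(alleles[src], 1L, read_len)
  r2 <- substr(revcomp(alleles)[src], 1L, read_len)
  e1 <- add_read_errors(r1, rates[seq_len(nchar(r1[1]))])
  e2 <- add_read_errors(r2, rates[seq_len(nchar(r2[1]))])
  pool <- structure(list(
    sample_id = "sim_sample", target_id = "sim_target",
    reads = data.frame(id = sprintf("pool:%05d", seq_len(depth)),
                       r1_seq = e1$seqs, r1_qual = substr(qual, 1,
                                                          nchar(r1[1])),
                       r2_seq = e2$seqs, r2_qual = substr(qual, 1,
                                                          nchar(r2[1])),
                       stringsAsFactors = FALSE)),
    class = "amplicon_pool")
  list(pool = pool, truth_alleles = sort(alleles))
}

#' Simulate a plastome-like alignment with seeded divergent blocks
#'
#' An invariant background across `n_taxa` sequences with `n_blocks`
#' non-overlapping divergent blocks. Within a block, variable columns are
#' sprinkled at the density needed to hit the block's target mean pairwise
#' divergence (each variable column splits the taxa into two base groups),
#' and the block's first and last columns are always variable so the block
#' span is well defined. Truth block coordinates are returned for recovery
#' benchmarks.
#'
#' @param n_taxa number of sequences (default 6).
#' @param length alignment length in columns (default 125000).
#' @param n_blocks number of divergent blocks (default 48).
#' @param block_len_range block lengths in columns (default c(400, 1000)).
#' @param block_div_range target mean pairwise divergence per block
#'   (default c(0.008, 0.075)).
#' @param min_gap minimum invariant gap between blocks and to the alignment
#'   ends (default 200 columns).
#' @param seed mandatory RNG seed.
#' @return list with `msa` (alignment matrix) and `blocks` (data.frame
#'   start/end 1-based inclusive, target_divergence).
#' @export
simulate_plastome_msa <- function(n_taxa = 6, length = 125000,
                                  n_blocks = 48,
                                  block_len_range = c(400, 1000),
                                  block_div_range = c(0.008, 0.075),
                                  min_gap = 200, seed) {
  if (missing(seed)) stop("simulate_plastome_msa requires a seed",
                          call. = FALSE)
  set.seed(seed)
  ref <- sample(DNA_BASES, length, replace = TRUE)
  msa <- matrix(rep(ref, each = n_taxa), nrow = n_taxa)
  rownames(msa) <- sprintf("taxon_%d", seq_len(n_taxa))
  if (n_blocks == 0) {
    return(list(msa = msa,
                blocks = data.frame(start = integer(0), end = integer(0),
                                    target_divergence = numeric(0))))
  }
  block_len <- sample(seq(block_len_range[1], block_len_range[2]),
                      n_blocks, replace = TRUE)
  slack <- length - sum(block_len) - min_gap * (n_blocks + 1)
  if (slack < 0) stop("blocks do not fit in the alignment", call. = FALSE)
  extra <- if (slack > 0) {
    e <- stats::rmultinom(1, slack, rep(1, n_blocks + 1))[, 1]
    as.integer(e)
  } else rep(0L, n_blocks + 1)
  gaps <- min_gap + extra
  starts <- cumsum(gaps[seq_len(n_blocks)] +
                     c(0L, block_len[-n_blocks])) + 1L
  ends <- starts + block_len - 1L
  div <- stats::runif(n_blocks, block_div_range[1], block_div_range[2])

  ## a variable column splits taxa half/half -> per-column divergence
  k <- floor(n_taxa / 2)
  col_div <- (k * (n_taxa - k)) / choose(n_taxa, 2)
  for (b in seq_len(n_blocks)) {
    cols <- starts[b]:ends[b]
    dens <- min(1, div[b] / col_div)
    if (dens <= 0) next
    var_cols <- cols[stats::runif(length(cols)) < dens]
    var_cols <- unique(c(starts[b], ends[b], var_cols))
    for (cc in var_cols) {
      alt <- sample(setdiff(DNA_BASES, ref[cc]), 1)
      msa[sample(n_taxa, k), cc] <- alt
    }
  }
  list(msa = msa, blocks = data.frame(start = starts, end = ends,
                                      target_divergence = div))
}
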
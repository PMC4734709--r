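## Pool reduction: 3' trimming, overlap joining, modal-length filtering,
## then strict consensus, IUPAC-ambiguity consensus, or allele recovery by
## read-frequency thresholds.

#' Reduction configuration
#'
#' @param mode "consensus" (plurality base per column), "ambiguity" (IUPAC
#'   code over the bases passing the support thresholds per column), or
#'   "occurrence" (allele recovery: groups of identical reads passing the
#'   support thresholds).
#' @param trim1,trim2 bases removed from the 3' ends of read 1 / read 2
#'   before joining (default 0; MiSeq error accumulates at 3' ends,
#'   especially read 2, so values such as 75/150 are typical for 300 bp
#'   reads).
#' @param min_overlap minimum mate overlap (bases) for joining; pairs below
#'   it are concatenated instead. Default 10.
#' @param max_mismatch maximum mismatch fraction tolerated in the chosen
#'   overlap for a join. Default 0.25.
#' @param min_reads absolute support threshold s: a base variant (ambiguity
#'   mode) or candidate allele (occurrence mode) needs at least this many
#'   reads. Default 5.
#' @param min_freq relative support threshold f: same, as a fraction of the
#'   pool's (post modal-length) read total. Default 0.05.
#' @return list of class `reduce_config`.
#' @export
reduce_config <- function(mode = c("ambiguity", "consensus", "occurrence"),
                          trim1 = 0, trim2 = 0, min_overlap = 10,
                          max_mismatch = 0.25, min_reads = 5,
                          min_freq = 0.05) {
  mode <- match.arg(mode)
  stopifnot(trim1 >= 0, trim2 >= 0, min_overlap >= 1, min_reads >= 1,
            min_freq > 0, min_freq <= 1, max_mismatch >= 0, max_mismatch <= 1)
  structure(list(mode = mode, trim1 = as.integer(trim1),
                 trim2 = as.integer(trim2),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch = max_mismatch,
                 min_reads = as.integer(min_reads), min_freq = min_freq),
            class = "reduce_config")
}

#' Trim read-pair 3' ends
#'
#' Removes exactly `trim1` bases from the 3' end of every read 1 and `trim2`
#' from every read 2 (bases and qualities). A read shorter than its trim is
#' reduced to empty with a warning.
#'
#' @param reads read-pair data.frame (columns r1_seq/r1_qual/r2_seq/r2_qual).
#' @param trim1,trim2 bases to remove.
#' @return the trimmed data.frame.
#' @export
trim_pair <- function(reads, trim1 = 0, trim2 = 0) {
  l1 <- pmax(nchar(reads$r1_seq) - trim1, 0L)
  l2 <- pmax(nchar(reads$r2_seq) - trim2, 0L)
  if (any(l1 == 0L & nchar(reads$r1_seq) > 0L) ||
      any(l2 == 0L & nchar(reads$r2_seq) > 0L)) {
    warning(sprintf("%d read(s) trimmed to empty",
                    sum(l1 == 0L) + sum(l2 == 0L)), call. = FALSE)
  }
  reads$r1_seq <- substr(reads$r1_seq, 1L, l1)
  reads$r1_qual <- substr(reads$r1_qual, 1L, l1)
  reads$r2_seq <- substr(reads$r2_seq, 1L, l2)
  reads$r2_qual <- substr(reads$r2_qual, 1L, l2)
  reads
}

#' Join trimmed mate pairs by overlap, or concatenate
#'
#' Read 2 is reverse-complemented, every overlap of at least `min_overlap`
#' bases with read 1 is scored, and the overlap with the lowest mismatch
#' fraction (ties broken toward the longest) is accepted when that fraction
#' is at most `max_mismatch`. Disagreements inside an accepted overlap
#' resolve toward the higher-quality base (tie toward read 1); the kept
#' quality is the higher one. Pairs with no acceptable overlap are
#' concatenated as `r1 + revcomp(r2)` with the junction column recorded so
#' downstream users can split the two halves.
#'
#' @param reads trimmed read-pair data.frame.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch maximum overlap mismatch fraction (default 0.25).
#' @return data.frame with columns `id`, `sequence`, `qual`, `joined`
#'   (logical), `junction` (0-based index of the concatenation point, NA
#'   when joined) and `overlap` (accepted overlap length, 0 when
#'   concatenated).
#' @export
join_pairs <- function(reads, min_overlap = 10, max_mismatch = 0.25) {
  keep <- nchar(reads$r1_seq) > 0 & nchar(reads$r2_seq) > 0
  if (!all(keep)) {
    warning(sprintf("%d pair(s) with an empty mate dropped before joining",
                    sum(!keep)), call. = FALSE)
    reads <- reads[keep, , drop = FALSE]
  }
  if (nrow(reads) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      qual = character(0), joined = logical(0),
                      junction = integer(0), overlap = integer(0),
                      stringsAsFactors = FALSE))
  }
  r2rc <- revcomp(reads$r2_seq)
  q2r <- reverse_strings(reads$r2_qual)
  m <- .cpp_merge_pairs(reads$r1_seq, r2rc, reads$r1_qual, q2r,
                        as.integer(min_overlap), max_mismatch)
  data.frame(id = reads$id, sequence = m$sequence, qual = m$qual,
             joined = m$joined, junction = m$junction, overlap = m$overlap,
             stringsAsFactors = FALSE)
}

#' Join a single mate pair
#'
#' Convenience scalar wrapper around [join_pairs()].
#'
#' @param r1,r2 mate sequences (read 2 in sequencing orientation).
#' @param q1,q2 quality strings (defaults: uniform).
#' @param min_overlap,max_mismatch see [join_pairs()].
#' @return one-row data.frame as in [join_pairs()].
#' @export
join_pair <- function(r1, r2, q1 = strrep("I", nchar(r1)),
                      q2 = strrep("I", nchar(r2)), min_overlap = 10,
                      max_mismatch = 0.25) {
  join_pairs(data.frame(id = "pair", r1_seq = toupper(r1), r1_qual = q1,
                        r2_seq = toupper(r2), r2_qual = q2,
                        stringsAsFactors = FALSE),
             min_overlap, max_mismatch)
}

#' Reduce reads to the modal amplicon length
#'
#' Keeps only reads whose sequence length equals the most frequent length in
#' the pool; all other length variants are excluded from downstream
#' consensus/allele calculation. A tie between lengths is broken toward the
#' longer variant (deterministic).
#'
#' @param sequences character vector of joined/concatenated sequences.
#' @return list with `keep` (logical vector) and `modal_length`.
#' @export
reduce_to_modal_length <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  len <- nchar(sequences)
  tab <- table(len)
  best <- as.integer(names(tab)[tab == max(tab)])
  modal <- max(best)
  list(keep = len == modal, modal_length = modal)
}

base_count_matrix <- function(sequences) {
  mat <- matrix(unlist(strsplit(sequences, ""), use.names = FALSE),
                nrow = length(sequences), byrow = TRUE)
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, DNA_BASES))
  t(counts)  # 4 x L, rows A,C,G,T
}

#' Column-wise consensus over equal-length reads
#'
#' In "consensus" mode every column yields the plurality base (ties broken
#' alphabetically A < C < G < T). In "ambiguity" mode a column yields the
#' IUPAC code over the set of bases supported by at least `min_reads` reads
#' and at least `min_freq` of the pool total; when no base passes both
#' thresholds the column falls back to the plurality base.
#'
#' @param sequences equal-length character vector (post modal-length
#'   filtering).
#' @param mode "consensus" or "ambiguity".
#' @param min_reads,min_freq support thresholds for ambiguity mode.
#' @return single consensus string.
#' @export
consensus_sequence <- function(sequences, mode = c("consensus", "ambiguity"),
                               min_reads = 5, min_freq = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(sequences) >= 1)
  if (length(unique(nchar(sequences))) != 1) {
    stop("consensus requires equal-length sequences; apply modal-length reduction first",
         call. = FALSE)
  }
  counts <- base_count_matrix(sequences)
  total <- length(sequences)
  plurality <- DNA_BASES[max.col(t(counts), ties.method = "first")]
  if (mode == "consensus") return(paste(plurality, collapse = ""))
  pass <- counts >= min_reads & counts / total >= min_freq
  out <- plurality
  ## a single passing base is necessarily the plurality base
  multi <- which(colSums(pass) >= 2)
  for (j in multi) {
    out[j] <- iupac_code_for(DNA_BASES[pass[, j]])
  }
  paste(out, collapse = "")
}

#' Recover candidate alleles from a pool by frequency thresholds
#'
#' Groups reads by exact sequence identity; a group is kept as an allele
#' when it has at least `min_reads` reads and represents at least `min_freq`
#' of the pool's reads. When no group passes both thresholds the
#' sample-by-target combination is discarded. The rationale: after PCR the
#' true alleles dominate the pool, while reads carrying sequencing errors
#' are scattered across many low-frequency variants.
#'
#' @param sequences character vector of joined/concatenated reads (post
#'   modal-length filtering; the threshold denominator is this vector's
#'   length).
#' @param min_reads,min_freq support thresholds (defaults 5 and 0.05).
#' @param sample_id,target_id labels carried through to the result.
#' @return list of class `allele_set`: `sample_id`, `target_id`, `alleles`
#'   (data.frame sequence/count/frequency, sorted by descending count then
#'   sequence), `total_reads`, `status` ("ok" or "discarded").
#' @export
call_alleles <- function(sequences, min_reads = 5, min_freq = 0.05,
                         sample_id = NA_character_,
                         target_id = NA_character_) {
  stopifnot(length(sequences) >= 1)
  total <- length(sequences)
  tab <- table(sequences)
  count <- as.integer(tab)
  seqs <- names(tab)
  keep <- count >= min_reads & count / total >= min_freq
  alleles <- data.frame(sequence = seqs[keep], count = count[keep],
                        stringsAsFactors = FALSE)
  ord <- order(-alleles$count, alleles$sequence)
  alleles <- alleles[ord, , drop = FALSE]
  alleles$frequency <- alleles$count / total
  rownames(alleles) <- NULL
  structure(list(sample_id = sample_id, target_id = target_id,
                 alleles = alleles, total_reads = total,
                 status = if (nrow(alleles) > 0) "ok" else "discarded"),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("allele_set %s / %s: %d allele(s) from %d reads [%s]\n",
              x$sample_id, x$target_id, nrow(x$alleles), x$total_reads,
              x$status))
  invisible(x)
}

#' Reduce one amplicon pool
#'
#' Full pipeline for one (sample, target): trim 3' ends, join or concatenate
#' mates, keep the modal amplicon length, then either call a consensus
#' (strict or IUPAC-ambiguity) or recover alleles, per `config$mode`. The
#' pool's geometry category records whether its reads overlapped ("joined"),
#' were concatenated ("concatenated"; majority vote over kept reads), or
#' produced nothing ("failed": empty pool, or no candidate passing the
#' thresholds in occurrence mode).
#'
#' @param pool an `amplicon_pool` (from [demultiplex()]) or a read-pair
#'   data.frame.
#' @param config a [reduce_config()].
#' @return list of class `reduced_pool`: `sample_id`, `target_id`, `mode`,
#'   `category`, `n_reads` (post modal-length), `modal_length`, and either
#'   `consensus` (string) or `alleles` (an `allele_set`).
#' @export
reduce_pool <- function(pool, config = reduce_config()) {
  if (inherits(pool, "amplicon_pool")) {
    reads <- pool$reads
    sample_id <- pool$sample_id
    target_id <- pool$target_id
  } else {
    reads <- pool
    sample_id <- NA_character_
    target_id <- NA_character_
  }
  empty <- structure(list(sample_id = sample_id, target_id = target_id,
                          mode = config$mode, category = "failed",
                          n_reads = 0L, modal_length = NA_integer_,
                          consensus = NULL, alleles = NULL),
                     class = "reduced_pool")
  if (is.null(reads) || nrow(reads) == 0) return(empty)
  reads <- trim_pair(reads, config$trim1, config$trim2)
  joined <- join_pairs(reads, config$min_overlap, config$max_mismatch)
  if (nrow(joined) == 0) return(empty)
  modal <- reduce_to_modal_length(joined$sequence)
  kept <- joined[modal$keep, , drop = FALSE]
  category <- if (mean(kept$joined) >= 0.5) "joined" else "concatenated"
  out <- empty
  out$category <- category
  out$n_reads <- nrow(kept)
  out$modal_length <- modal$modal_length
  if (config$mode == "occurrence") {
    out$alleles <- call_alleles(kept$sequence, config$min_reads,
                                config$min_freq, sample_id, target_id)
    if (out$alleles$status == "discarded") out$category <- "failed"
  } else {
    out$consensus <- consensus_sequence(kept$sequence, config$mode,
                                        config$min_reads, config$min_freq)
  }
  out
}

#' Reduce every pool of a demultiplexed run
#'
#' @param pools named list of `amplicon_pool` objects (e.g.
#'   `demultiplex(...)$pools`).
#' @param config a [reduce_config()] applied to every pool.
#' @return list of class `reduce_result`:
#'   \describe{
#'     \item{reduced}{list of `reduced_pool` objects.}
#'     \item{consensus}{data.frame id/target/sequence for consensus modes
#'       (id = sample), or allele FASTA records `sample|allele_n` for
#'       occurrence mode.}
#'     \item{allele_counts}{occurrence mode: one row per kept allele with
#'       sample, target, allele index, count, frequency, total_reads,
#'       status; discarded pools appear with status "discarded".}
#'     \item{coverage}{per-pool table sample/target/category/n_reads (the
#'       heat-map-style run overview).}
#'   }
#' @export
reduce_run <- function(pools, config = reduce_config()) {
  reduced <- lapply(pools, reduce_pool, config = config)
  coverage <- data.frame(
    sample = vapply(reduced, `[[`, character(1), "sample_id"),
    target = vapply(reduced, `[[`, character(1), "target_id"),
    category = vapply(reduced, `[[`, character(1), "category"),
    n_reads = vapply(reduced, `[[`, integer(1), "n_reads"),
    stringsAsFactors = FALSE, row.names = NULL)
  consensus <- NULL
  allele_counts <- NULL
  if (config$mode == "occurrence") {
    rows <- list()
    fasta <- list()
    for (r in reduced) {
      if (is.null(r$alleles)) next
      a <- r$alleles
      if (a$status == "discarded") {
        rows[[length(rows) + 1]] <- data.frame(
          sample = a$sample_id, target = a$target_id, allele = NA_integer_,
          count = NA_integer_, frequency = NA_real_,
          total_reads = a$total_reads, status = "discarded",
          stringsAsFactors = FALSE)
        next
      }
      for (i in seq_len(nrow(a$alleles))) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = a$sample_id, target = a$target_id, allele = i,
          count = a$alleles$count[i], frequency = a$alleles$frequency[i],
          total_reads = a$total_reads, status = "ok",
          stringsAsFactors = FALSE)
        fasta[[length(fasta) + 1]] <- data.frame(
          id = sprintf("%s|allele_%d|%s", a$sample_id, i, a$target_id),
          target = a$target_id, sequence = a$alleles$sequence[i],
          stringsAsFactors = FALSE)
      }
    }
    allele_counts <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(sample = character(0), target = character(0),
                 allele = integer(0), count = integer(0),
                 frequency = numeric(0), total_reads = integer(0),
                 status = character(0), stringsAsFactors = FALSE)
    consensus <- if (length(fasta) > 0) do.call(rbind, fasta) else
      data.frame(id = character(0), target = character(0),
                 sequence = character(0), stringsAsFactors = FALSE)
  } else {
    ok <- !vapply(reduced, function(r) is.null(r$consensus), logical(1))
    consensus <- data.frame(
      id = vapply(reduced[ok], `[[`, character(1), "sample_id"),
      target = vapply(reduced[ok], `[[`, character(1), "target_id"),
      sequence = vapply(reduced[ok], `[[`, character(1), "consensus"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(reduced = reduced, consensus = consensus,
                 allele_counts = allele_counts, coverage = coverage),
            class = "reduce_result")
}

#' Write reduction outputs
#'
#' Per-target FASTA (one record per sample, or per sample-allele in
#' occurrence mode), `allele_counts.tsv` (occurrence mode) and
#' `coverage_matrix.tsv`.
#'
#' @param result a `reduce_result`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_reduce_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$consensus) && nrow(result$consensus) > 0) {
    for (tg in unique(result$consensus$target)) {
      sub <- result$consensus[result$consensus$target == tg, , drop = FALSE]
      write_fasta(stats::setNames(sub$sequence, sub$id),
                  file.path(out_dir, paste0(tg, ".fasta")))
    }
  }
  if (!is.null(result$allele_counts)) {
    write_table(result$allele_counts,
                file.path(out_dir, "allele_counts.tsv"))
  }
  write_table(result$coverage, file.path(out_dir, "coverage_matrix.tsv"))
  invisible(out_dir)
}
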
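## Demultiplexing: dual-barcode sample lookup plus anchored fuzzy primer
## matching, pooling reads by (sample, target).

#' Demultiplexing configuration
#'
#' @param max_bc_dist maximum edit distance per barcode (each of P5 and P7
#'   separately; Hamming when lengths match, Levenshtein otherwise).
#'   Default 1.
#' @param max_primer_dist maximum Levenshtein distance for the fuzzy part of
#'   a primer match. Default 4.
#' @param firm_end_len number of 3'-terminal primer bases that must match
#'   the read exactly and contiguously ("firm end"). Default 4.
#' @param rescue_swapped_mates if TRUE, reads whose primers fail in the
#'   standard orientation are retried with mates swapped. Default FALSE.
#' @return list of class `demux_config`.
#' @export
demux_config <- function(max_bc_dist = 1, max_primer_dist = 4,
                         firm_end_len = 4, rescue_swapped_mates = FALSE) {
  stopifnot(max_bc_dist >= 0, max_primer_dist >= 0, firm_end_len >= 0)
  structure(list(max_bc_dist = as.integer(max_bc_dist),
                 max_primer_dist = as.integer(max_primer_dist),
                 firm_end_len = as.integer(firm_end_len),
                 rescue_swapped_mates = isTRUE(rescue_swapped_mates)),
            class = "demux_config")
}

#' Match an observed index sequence against a barcode table
#'
#' Returns the unique barcode within `max_dist` of the observed sequence;
#' when no barcode qualifies, or two or more tie at the minimum distance
#' (ambiguity), the read stays unassigned rather than being guessed.
#'
#' @param observed character vector of observed index sequences.
#' @param barcodes data.frame with columns `name` and `sequence` (one end's
#'   barcodes), or a named character vector.
#' @param max_dist maximum edit distance (default 1).
#' @return data.frame with columns `name` (NA when unmatched) and `dist`
#'   (distance to the nearest barcode; NA for empty input sequences).
#' @export
match_barcode <- function(observed, barcodes, max_dist = 1) {
  if (is.data.frame(barcodes)) {
    seqs <- toupper(barcodes$sequence)
    names <- barcodes$name
  } else {
    seqs <- toupper(unname(barcodes))
    names <- names(barcodes)
  }
  observed <- toupper(as.character(observed))
  ok <- !is.na(observed) & nchar(observed) > 0
  res <- matrix(0L, nrow = length(observed), ncol = 2)
  if (any(ok)) res[ok, ] <- .cpp_bc_match(observed[ok], seqs,
                                          as.integer(max_dist))
  name <- ifelse(ok & res[, 1] > 0, names[pmax(res[, 1], 1L)], NA_character_)
  dist <- ifelse(ok & res[, 2] >= 0, res[, 2], NA_integer_)
  data.frame(name = name, dist = dist, stringsAsFactors = FALSE)
}

#' Anchored fuzzy primer match against read prefixes
#'
#' Aligns each candidate primer against the start of the read, allowing
#' Levenshtein edits (including indels) everywhere except the primer's
#' 3'-terminal `firm_end_len` bases, which must match the read exactly and
#' contiguously ("firm ends", protecting the polymerase extension point).
#' The unique candidate with minimal distance at most `max_primer_dist`
#' wins; ties between candidates leave the read unmatched. Because indels
#' are allowed in the fuzzy head, the number of read bases consumed (to be
#' stripped) can differ from the primer length. Reads shorter than a primer
#' never match that primer.
#'
#' @param read_5prime character vector of read sequences (prefix is used).
#' @param primers data.frame with columns `target` and `seq`, or a named
#'   character vector of primer sequences.
#' @param config a [demux_config()].
#' @return data.frame with columns `target` (NA when unmatched), `dist`
#'   (distance of the best admissible candidate, NA when none), and
#'   `consumed` (read bases covered by the primer; 0 when unmatched).
#' @export
match_primer <- function(read_5prime, primers, config = demux_config()) {
  if (is.data.frame(primers)) {
    seqs <- toupper(primers$seq)
    targets <- primers$target
  } else {
    seqs <- toupper(unname(primers))
    targets <- names(primers)
  }
  read_5prime <- toupper(as.character(read_5prime))
  res <- .cpp_primer_match(read_5prime, seqs, config$firm_end_len,
                           config$max_primer_dist)
  data.frame(
    target = ifelse(res[, 1] > 0, targets[pmax(res[, 1], 1L)],
                    NA_character_),
    dist = ifelse(res[, 2] >= 0, res[, 2], NA_integer_),
    consumed = res[, 3], stringsAsFactors = FALSE)
}

#' Demultiplex a read-pair table into sample-by-target amplicon pools
#'
#' A read pair is assigned to a sample when both its P5 and P7 index
#' sequences match barcodes (each within `max_bc_dist`) whose pair appears
#' in the sample sheet, and to a target when the forward primer matches the
#' start of read 1 and the reverse primer of the same target matches the
#' start of read 2 (firm-end fuzzy matching). Primer bases are stripped
#' from pooled reads. Every input read ends up either in exactly one pool
#' or in the unassigned tally with a failure reason.
#'
#' @param reads read-pair data.frame from [read_fastq_pairs()] or
#'   [simulate_run()].
#' @param sheets run sheets from [load_sheets()] (or an equivalent list).
#' @param config a [demux_config()].
#' @return list of class `demux_result` with elements:
#'   \describe{
#'     \item{pools}{named list of `amplicon_pool` objects, keyed
#'       `sample<TAB>target`; each has `sample_id`, `target_id` and a
#'       primer-stripped read data.frame.}
#'     \item{assignments}{per-read table: sample, target, barcode and
#'       primer distances, fail_reason in none/barcode/primer/both.}
#'     \item{report}{totals: reads, assigned, unassigned by reason,
#'       fraction_assigned, and per-pool read counts.}
#'   }
#' @export
demultiplex <- function(reads, sheets, config = demux_config()) {
  barcodes <- sheets$barcodes
  primers <- sheets$primers
  samples <- sheets$samples
  n <- nrow(reads)

  p5 <- match_barcode(reads$r1_bc, barcodes[barcodes$end == "P5", ],
                      config$max_bc_dist)
  p7 <- match_barcode(reads$r2_bc, barcodes[barcodes$end == "P7", ],
                      config$max_bc_dist)
  key <- paste(p5$name, p7$name, sep = "\r")
  sample_lut <- stats::setNames(samples$sample,
                                paste(samples$p5, samples$p7, sep = "\r"))
  sample_id <- unname(sample_lut[key])
  sample_id[is.na(p5$name) | is.na(p7$name)] <- NA_character_

  fwd <- match_primer(reads$r1_seq,
                      data.frame(target = primers$target, seq = primers$fwd,
                                 stringsAsFactors = FALSE), config)
  rev <- match_primer(reads$r2_seq,
                      data.frame(target = primers$target, seq = primers$rev,
                                 stringsAsFactors = FALSE), config)
  target_id <- ifelse(!is.na(fwd$target) & !is.na(rev$target) &
                        fwd$target == rev$target, fwd$target, NA_character_)

  swapped <- rep(FALSE, n)
  if (config$rescue_swapped_mates && any(is.na(target_id))) {
    idx <- which(is.na(target_id))
    fwd2 <- match_primer(reads$r2_seq[idx],
                         data.frame(target = primers$target,
                                    seq = primers$fwd,
                                    stringsAsFactors = FALSE), config)
    rev2 <- match_primer(reads$r1_seq[idx],
                         data.frame(target = primers$target,
                                    seq = primers$rev,
                                    stringsAsFactors = FALSE), config)
    hit <- !is.na(fwd2$target) & !is.na(rev2$target) &
      fwd2$target == rev2$target
    if (any(hit)) {
      target_id[idx[hit]] <- fwd2$target[hit]
      swapped[idx[hit]] <- TRUE
      fwd$consumed[idx[hit]] <- rev2$consumed[hit]
      rev$consumed[idx[hit]] <- fwd2$consumed[hit]
      fwd$dist[idx[hit]] <- rev2$dist[hit]
      rev$dist[idx[hit]] <- fwd2$dist[hit]
    }
  }

  bc_fail <- is.na(sample_id)
  pr_fail <- is.na(target_id)
  fail_reason <- rep("none", n)
  fail_reason[bc_fail & !pr_fail] <- "barcode"
  fail_reason[!bc_fail & pr_fail] <- "primer"
  fail_reason[bc_fail & pr_fail] <- "both"

  assignments <- data.frame(
    read_id = reads$id,
    sample_id = ifelse(bc_fail, "UNASSIGNED", sample_id),
    target_id = ifelse(pr_fail, "UNASSIGNED", target_id),
    bc_dist_p5 = p5$dist, bc_dist_p7 = p7$dist,
    primer_dist_f = fwd$dist, primer_dist_r = rev$dist,
    fail_reason = fail_reason, stringsAsFactors = FALSE)

  assigned <- !bc_fail & !pr_fail
  pools <- list()
  if (any(assigned)) {
    idx_assigned <- which(assigned)
    r1_stripped <- substring(reads$r1_seq, fwd$consumed + 1L)
    r1_q <- substring(reads$r1_qual, fwd$consumed + 1L)
    r2_stripped <- substring(reads$r2_seq, rev$consumed + 1L)
    r2_q <- substring(reads$r2_qual, rev$consumed + 1L)
    if (any(swapped)) {
      sw <- which(swapped & assigned)
      tmp_s <- substring(reads$r2_seq[sw], fwd$consumed[sw] + 1L)
      tmp_q <- substring(reads$r2_qual[sw], fwd$consumed[sw] + 1L)
      r2_stripped[sw] <- substring(reads$r1_seq[sw], rev$consumed[sw] + 1L)
      r2_q[sw] <- substring(reads$r1_qual[sw], rev$consumed[sw] + 1L)
      r1_stripped[sw] <- tmp_s
      r1_q[sw] <- tmp_q
    }
    pool_key <- paste(sample_id[idx_assigned], target_id[idx_assigned],
                      sep = "\t")
    split_idx <- split(idx_assigned, pool_key)
    pools <- lapply(names(split_idx), function(k) {
      ii <- split_idx[[k]]
      parts <- strsplit(k, "\t", fixed = TRUE)[[1]]
      structure(list(
        sample_id = parts[1], target_id = parts[2],
        reads = data.frame(id = reads$id[ii],
                           r1_seq = r1_stripped[ii], r1_qual = r1_q[ii],
                           r2_seq = r2_stripped[ii], r2_qual = r2_q[ii],
                           stringsAsFactors = FALSE)),
        class = "amplicon_pool")
    })
    names(pools) <- names(split_idx)
  }

  pool_counts <- data.frame(
    sample = vapply(pools, `[[`, character(1), "sample_id"),
    target = vapply(pools, `[[`, character(1), "target_id"),
    reads = vapply(pools, function(p) nrow(p$reads), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  report <- structure(list(
    total_reads = n,
    assigned = sum(assigned),
    unassigned = sum(!assigned),
    unassigned_barcode = sum(fail_reason == "barcode"),
    unassigned_primer = sum(fail_reason == "primer"),
    unassigned_both = sum(fail_reason == "both"),
    fraction_assigned = if (n > 0) sum(assigned) / n else NA_real_,
    n_pools = length(pools),
    pool_counts = pool_counts), class = "demux_report")

  structure(list(pools = pools, assignments = assignments, report = report),
            class = "demux_result")
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf(
    "demux: %d reads, %d assigned (%.1f%%) into %d pools; unassigned: %d barcode, %d primer, %d both\n",
    x$total_reads, x$assigned, 100 * x$fraction_assigned, x$n_pools,
    x$unassigned_barcode, x$unassigned_primer, x$unassigned_both))
  invisible(x)
}

#' Write demultiplexed pools and report to disk
#'
#' Emits one FASTQ pair per (sample, target) pool plus `demux_report.tsv`.
#'
#' @param result a `demux_result` from [demultiplex()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report table path.
#' @export
write_demux_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in result$pools) {
    base <- file.path(out_dir, paste0(p$sample_id, "_", p$target_id))
    write_fastq(p$reads$id, p$reads$r1_seq, p$reads$r1_qual,
                paste0(base, "_R1.fastq"))
    write_fastq(p$reads$id, p$reads$r2_seq, p$reads$r2_qual,
                paste0(base, "_R2.fastq"))
  }
  rep_path <- file.path(out_dir, "demux_report.tsv")
  write_table(result$report$pool_counts, rep_path)
  invisible(rep_path)
}
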
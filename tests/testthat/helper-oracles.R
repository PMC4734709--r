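# Independent reference implementations used to cross-check the package's
# matching and divergence code. These deliberately take the slow, exhaustive
# route: base R's adist() for edit distances and explicit loops everywhere.

# Exhaustive firm-end match: enumerate every placement of the primer's firm
# 3' block on the read, score the head with adist(), return the minimal
# total distance (NA when no placement is admissible within max_dist).
oracle_firm_end <- function(read, primer, firm = 4, max_dist = 4) {
  P <- nchar(primer)
  if (nchar(read) < P || P < firm) return(NA_integer_)
  h <- P - firm
  head <- substr(primer, 1, h)
  block <- substr(primer, h + 1, P)
  best <- Inf
  for (m in 0:(nchar(read) - firm)) {
    if (substr(read, m + 1, m + firm) != block) next
    d <- utils::adist(head, substr(read, 1, m))[1, 1]
    if (d < best) best <- d
  }
  if (best <= max_dist) as.integer(best) else NA_integer_
}

# Oracle for the panel decision: unique minimum within max_dist wins.
oracle_best_primer <- function(read, primer_seqs, firm = 4, max_dist = 4) {
  d <- vapply(primer_seqs, oracle_firm_end, integer(1), read = read,
              firm = firm, max_dist = max_dist)
  if (all(is.na(d))) return(list(idx = NA_integer_, dist = NA_integer_))
  mn <- min(d, na.rm = TRUE)
  hits <- which(!is.na(d) & d == mn)
  list(idx = if (length(hits) == 1) hits else NA_integer_, dist = mn)
}

# Brute-force nearest-barcode search (Hamming for equal lengths, matching
# the documented metric; character-by-character, no shared code path).
oracle_barcode <- function(obs, barcodes, max_dist = 1) {
  d <- unname(vapply(barcodes, function(bc) {
    if (nchar(bc) == nchar(obs)) {
      sum(strsplit(obs, "")[[1]] != strsplit(bc, "")[[1]])
    } else {
      utils::adist(obs, bc)[1, 1]
    }
  }, numeric(1)))
  mn <- min(d)
  hits <- which(d == mn)
  list(idx = if (mn <= max_dist && length(hits) == 1) hits else NA_integer_,
       dist = mn)
}

# Exhaustive pairwise column divergence.
oracle_column_divergence <- function(msa, col) {
  bases <- msa[, col]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  n <- length(bases)
  if (n < 2) return(NA_real_)
  diff <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (bases[i] != bases[j]) diff <- diff + 1
  }
  diff / pairs
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Apply n random edits (substitution, insertion or deletion) anywhere.
apply_edits <- function(seq, n) {
  for (i in seq_len(n)) {
    p <- sample(nchar(seq), 1)
    op <- sample(c("sub", "ins", "del"), 1)
    seq <- switch(op,
      sub = substitute_at(seq, p),
      ins = paste0(substr(seq, 1, p), sample(c("A", "C", "G", "T"), 1),
                   substr(seq, p + 1, nchar(seq))),
      del = paste0(substr(seq, 1, p - 1), substr(seq, p + 1, nchar(seq))))
  }
  seq
}

# Apply k random substitutions at distinct positions.
substitute_at <- function(seq, positions) {
  for (p in positions) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

make_pool <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  structure(list(sample_id = "s1", target_id = "t1",
                 reads = data.frame(id = sprintf("r%03d", seq_along(seqs)),
                                    r1_seq = seqs, r1_qual = quals,
                                    r2_seq = revcomp(seqs),
                                    r2_qual = quals,
                                    stringsAsFactors = FALSE)),
            class = "amplicon_pool")
}
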
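## Amplification-target selection from multiple sequence alignments:
## sliding scan for divergent regions with conserved primer-ready flanks,
## conserved-island detection for nuclear loci, and the alignment
## cleaning/concatenation utilities.
##
## Alignments are plain character matrices (rows = taxa, cols = columns,
## upper-case over A/C/G/T/N/-/IUPAC). Coordinates are 0-based half-open
## internally; emitted tables are 1-based inclusive (the convention of
## phylogenetic partition files).

#' Build an alignment matrix from sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return character matrix with taxa as rownames.
#' @export
as_msa <- function(seqs) {
  if (length(seqs) < 2) stop("an alignment needs >= 2 sequences",
                             call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must be equal length", call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- if (is.null(names(seqs)))
    paste0("taxon", seq_along(seqs)) else names(seqs)
  mat
}

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @return character matrix as in [as_msa()].
#' @export
read_msa <- function(path) as_msa(read_fasta(path))

#' Write an alignment matrix as FASTA
#'
#' @param msa character matrix.
#' @param path output file.
#' @export
write_msa <- function(msa, path) {
  write_fasta(stats::setNames(apply(msa, 1, paste, collapse = ""),
                              rownames(msa)), path)
}

msa_base_counts <- function(msa) {
  counts <- vapply(DNA_BASES, function(b) colSums(msa == b),
                   numeric(ncol(msa)))
  if (ncol(msa) == 1) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, DNA_BASES))
  t(counts)
}

## per-column summary used by the scan and by column_divergence
msa_profile <- function(msa) {
  counts <- msa_base_counts(msa)
  n <- colSums(counts)                       # comparable (unambiguous) bases
  pairs <- n * (n - 1) / 2
  same <- colSums(counts * (counts - 1) / 2)
  div <- ifelse(pairs >= 1, 1 - same / pairs, NA_real_)
  occupancy <- colSums(msa != "-" & msa != "N") / nrow(msa)
  ambiguous <- colSums(msa != "-" & !(msa %in% c(DNA_BASES, "-"))) > 0
  list(divergence = div, occupancy = occupancy, ambiguous = ambiguous,
       n_comparable = n)
}

#' Per-column pairwise divergence of an alignment
#'
#' Fraction of pairwise taxon comparisons that differ at the column,
#' ignoring any pair where either base is a gap, N or other ambiguity code.
#' Columns with fewer than two comparable bases are reported as NA.
#'
#' @param msa alignment matrix from [as_msa()]/[read_msa()].
#' @param col optional column index/indices; default all columns.
#' @return numeric vector of divergences in `[0, 1]` (NA where
#'   incomparable).
#' @export
column_divergence <- function(msa, col = NULL) {
  div <- msa_profile(msa)$divergence
  if (is.null(col)) div else div[col]
}

#' Scan an alignment for variable regions with conserved flanks
#'
#' Finds candidate amplification targets: stretches of elevated sequence
#' divergence, `min_len` to `max_len` columns long, bracketed on both sides
#' by `flank_len` conserved columns suitable for primer design. A flank
#' column counts as conserved when its divergence is at most
#' `max_flank_div` and, by default, every taxon has an unambiguous base
#' there (regions absent from a taxon, or with ambiguity codes at primer
#' sites, cannot be amplified reliably and are discarded). Divergent spans
#' shorter than `min_len` are padded symmetrically into their conserved
#' neighbourhoods when possible. Candidates are ranked by mean region
#' divergence (ties toward the leftmost) and pruned greedily so the
#' reported regions never overlap.
#'
#' @param msa alignment matrix.
#' @param min_len,max_len admissible region lengths in columns (defaults
#'   400 and 1000, a typical amplicon size window for 300 bp paired-end
#'   sequencing).
#' @param flank_len conserved flank length in columns (default 25, room for
#'   a primer).
#' @param max_flank_div maximum flank-column divergence (default 0:
#'   strictly conserved flanks).
#' @param min_region_div regions must exceed this mean divergence (default
#'   0: any observed divergence ranks).
#' @param require_full_occupancy,forbid_ambiguity flank primer-site rules
#'   (defaults TRUE).
#' @param max_poly_x optional pre-filter: reject candidates whose flanks
#'   contain a homopolymer run longer than this (e.g. 3); NULL disables.
#' @return data.frame with 1-based inclusive `start`, `end`, plus `length`,
#'   `divergence`, `left_flank_div`, `right_flank_div`, `rank`; zero rows
#'   when nothing qualifies.
#' @export
scan_variable_regions <- function(msa, min_len = 400, max_len = 1000,
                                  flank_len = 25, max_flank_div = 0,
                                  min_region_div = 0,
                                  require_full_occupancy = TRUE,
                                  forbid_ambiguity = TRUE,
                                  max_poly_x = NULL) {
  stopifnot(min_len <= max_len, flank_len >= 1)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), divergence = numeric(0),
                      left_flank_div = numeric(0),
                      right_flank_div = numeric(0), rank = integer(0))
  L <- ncol(msa)
  if (L < min_len + 2 * flank_len) {
    warning("alignment shorter than the smallest admissible window",
            call. = FALSE)
    return(empty)
  }
  prof <- msa_profile(msa)
  div0 <- ifelse(is.na(prof$divergence), 0, prof$divergence)
  conserved <- !is.na(prof$divergence) &
    prof$divergence <= max_flank_div &
    (!require_full_occupancy | prof$occupancy == 1) &
    (!forbid_ambiguity | !prof$ambiguous)

  ## maximal runs of non-conserved ("variable") columns, then greedy
  ## left-to-right clustering: a variable region may contain conserved
  ## stretches, so consecutive runs are merged while the combined span
  ## stays within max_len (two well-separated regions cannot merge because
  ## each admissible region is at least min_len long)
  r <- rle(conserved)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  var_runs <- which(!r$values)
  clusters <- list()
  for (k in var_runs) {
    n_cl <- length(clusters)
    if (n_cl > 0 &&
        run_end[k] - clusters[[n_cl]][1] + 1 <= max_len) {
      clusters[[n_cl]][2] <- run_end[k]
    } else {
      clusters[[n_cl + 1]] <- c(run_start[k], run_end[k])
    }
  }
  ## conserved run length ending just before / starting just after a column
  cons_before <- function(pos) {
    i <- pos - 1
    n <- 0
    while (i >= 1 && conserved[i]) { n <- n + 1; i <- i - 1 }
    n
  }
  cons_after <- function(pos) {
    i <- pos + 1
    n <- 0
    while (i <= L && conserved[i]) { n <- n + 1; i <- i + 1 }
    n
  }
  cand <- list()
  for (cl in clusters) {
    s <- cl[1]; e <- cl[2]
    left_run <- cons_before(s)
    right_run <- cons_after(e)
    if (left_run < flank_len || right_run < flank_len) next
    len <- e - s + 1
    if (len > max_len) next
    if (len < min_len) {
      need <- min_len - len
      avail_l <- left_run - flank_len
      avail_r <- right_run - flank_len
      if (avail_l + avail_r < need) next
      pad_l <- min(avail_l, ceiling(need / 2))
      pad_r <- need - pad_l
      if (pad_r > avail_r) { pad_r <- avail_r; pad_l <- need - pad_r }
      s <- s - pad_l; e <- e + pad_r
      len <- min_len
    }
    region_div <- mean(div0[s:e])
    if (!(region_div > min_region_div)) next
    lf <- (s - flank_len):(s - 1)
    rf <- (e + 1):(e + flank_len)
    if (!is.null(max_poly_x)) {
      flank_seq <- paste(msa[1, c(lf, rf)], collapse = "")
      if (grepl(sprintf("([ACGT])\\1{%d,}", max_poly_x), flank_seq)) next
    }
    cand[[length(cand) + 1]] <- data.frame(
      start = s, end = e, length = len, divergence = region_div,
      left_flank_div = mean(div0[lf]), right_flank_div = mean(div0[rf]))
  }
  if (length(cand) == 0) return(empty)
  out <- do.call(rbind, cand)
  out <- out[order(-out$divergence, out$start), , drop = FALSE]
  ## greedy non-overlap pruning in rank order
  keep <- logical(nrow(out))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(out))) {
    if (!any(out$start[i] <= occ_end & out$end[i] >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, out$start[i])
      occ_end <- c(occ_end, out$end[i])
    }
  }
  out <- out[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Detect conserved islands and primer-pair candidates in a locus alignment
#'
#' An island is a maximal run of columns where at least `min_taxa` distinct
#' taxa have an unambiguous base. An ordered island pair is a candidate
#' amplicon when the separation between them, plus `intron_pad` bases for
#' each predicted intron falling between them, lies within
#' `[min_sep, max_sep]`.
#'
#' @param aln alignment matrix of binned reads against a reference locus
#'   (duplicate rownames are treated as the same taxon).
#' @param min_taxa minimum distinct taxa covering a column (default 2).
#' @param min_sep,max_sep admissible effective separation in columns
#'   (defaults 400 and 800).
#' @param intron_pad assumed average intron length added per predicted
#'   intron (default 100).
#' @param introns integer vector of predicted intron column positions
#'   (1-based; the optional annotation track).
#' @return list with data.frames `islands` (start, end, length, 1-based
#'   inclusive) and `candidates` (island coordinates, separation,
#'   n_introns, effective_sep).
#' @export
find_conserved_islands <- function(aln, min_taxa = 2, min_sep = 400,
                                   max_sep = 800, intron_pad = 100,
                                   introns = integer(0)) {
  present <- aln %in% DNA_BASES
  dim(present) <- dim(aln)
  taxa <- rownames(aln)
  if (is.null(taxa)) taxa <- as.character(seq_len(nrow(aln)))
  groups <- split(seq_len(nrow(aln)), taxa)
  coverage <- Reduce(`+`, lapply(groups, function(rows) {
    as.integer(colSums(present[rows, , drop = FALSE]) > 0)
  }))
  r <- rle(coverage >= min_taxa)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  isl <- which(r$values)
  islands <- data.frame(start = starts[isl], end = ends[isl],
                        length = r$lengths[isl])
  rownames(islands) <- NULL
  cand <- list()
  if (nrow(islands) >= 2) {
    for (i in seq_len(nrow(islands) - 1)) {
      for (j in (i + 1):nrow(islands)) {
        sep <- islands$start[j] - islands$end[i] - 1
        ni <- sum(introns > islands$end[i] & introns < islands$start[j])
        eff <- sep + intron_pad * ni
        if (eff >= min_sep && eff <= max_sep) {
          cand[[length(cand) + 1]] <- data.frame(
            island1_start = islands$start[i], island1_end = islands$end[i],
            island2_start = islands$start[j], island2_end = islands$end[j],
            separation = sep, n_introns = ni, effective_sep = eff)
        }
      }
    }
  }
  candidates <- if (length(cand) > 0) do.call(rbind, cand) else
    data.frame(island1_start = integer(0), island1_end = integer(0),
               island2_start = integer(0), island2_end = integer(0),
               separation = integer(0), n_introns = integer(0),
               effective_sep = integer(0))
  rownames(candidates) <- NULL
  list(islands = islands, candidates = candidates)
}

#' Drop under-occupied alignment columns
#'
#' Removes every column where fewer than `occupancy` of the rows carry a
#' real base (non-gap, non-N), the usual cleanup to minimise missing data
#' before concatenation. Row order is preserved; the kept column indices
#' are attached as attribute `kept_columns`. The operation is idempotent.
#'
#' @param msa alignment matrix.
#' @param occupancy minimum fraction of rows with a base (default 0.5).
#' @return cleaned alignment matrix.
#' @export
clean_alignment <- function(msa, occupancy = 0.5) {
  frac <- colSums(msa != "-" & msa != "N") / nrow(msa)
  keep <- which(frac >= occupancy)
  out <- msa[, keep, drop = FALSE]
  attr(out, "kept_columns") <- keep
  out
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' Taxa are the union over loci; a taxon absent from a locus gets a gap
#' block of that locus's width. A partition table (1-based inclusive column
#' spans, in input locus order) is returned for downstream partitioned
#' analysis.
#'
#' @param msas named list of alignment matrices (names = locus ids).
#' @return list with `supermatrix` (alignment matrix) and `partitions`
#'   (data.frame locus/start/end).
#' @export
concat_alignments <- function(msas) {
  stopifnot(length(msas) >= 1)
  if (is.null(names(msas))) names(msas) <- paste0("locus", seq_along(msas))
  taxa <- unique(unlist(lapply(msas, rownames)))
  widths <- vapply(msas, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  supermatrix <- matrix("-", nrow = length(taxa), ncol = sum(widths),
                        dimnames = list(taxa, NULL))
  for (k in seq_along(msas)) {
    m <- msas[[k]]
    supermatrix[rownames(m), starts[k]:ends[k]] <- m
  }
  list(supermatrix = supermatrix,
       partitions = data.frame(locus = names(msas), start = starts,
                               end = ends, row.names = NULL))
}

#' Write a region table as BED
#'
#' Converts the 1-based inclusive region table of
#' [scan_variable_regions()] to 0-based half-open BED.
#'
#' @param regions region data.frame with `start` and `end`.
#' @param path output BED file.
#' @param chrom sequence name for column 1 (default "alignment").
#' @export
write_regions_bed <- function(regions, path, chrom = "alignment") {
  bed <- data.frame(chrom = chrom, start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
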
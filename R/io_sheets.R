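## Readers/writers for FASTQ/FASTA streams, the three TSV run sheets
## (barcodes, target-specific primers, samples) and output tables.
##
## Sheet dialect (tab-separated, header row, case-insensitive sequences,
## stored upper-case):
##   barcodes: name  end{P5,P7}  sequence
##   primers:  target  genome{chloroplast,nuclear}  fwd  rev
##   samples:  sample  p5  p7  [project]

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s sheet not found: %s", what, path),
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s sheet %s lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and validate a barcode sheet
#'
#' Columns `name`, `end` (P5 or P7), `sequence`. Within each end, names and
#' sequences must be unique and sequences equal-length ACGT. The design rule
#' that same-end barcodes differ at more than 2 positions is checked and
#' reported as a warning (not an error) for user-supplied sets.
#'
#' @param path TSV file path.
#' @return data.frame with columns name/end/sequence (sequences upper-case).
#' @export
read_barcode_sheet <- function(path) {
  df <- read_tsv_checked(path, c("name", "end", "sequence"), "barcode")
  validate_barcodes(df)
}

validate_barcodes <- function(df) {
  df$end <- toupper(df$end)
  df$sequence <- toupper(df$sequence)
  if (!all(df$end %in% c("P5", "P7"))) {
    stop("barcode 'end' must be P5 or P7", call. = FALSE)
  }
  assert_dna(df$sequence, "barcode sheet")
  for (e in unique(df$end)) {
    sub <- df[df$end == e, ]
    if (anyDuplicated(sub$name)) {
      stop(sprintf("duplicate %s barcode name(s): %s", e,
                   paste(unique(sub$name[duplicated(sub$name)]),
                         collapse = ", ")), call. = FALSE)
    }
    if (anyDuplicated(sub$sequence)) {
      stop(sprintf("duplicate %s barcode sequence(s)", e), call. = FALSE)
    }
    if (length(unique(nchar(sub$sequence))) > 1) {
      stop(sprintf("%s barcodes are not all the same length", e),
           call. = FALSE)
    }
    if (nrow(sub) > 1) {
      d <- utils::combn(nrow(sub), 2)
      dist <- edit_distance(sub$sequence[d[1, ]], sub$sequence[d[2, ]])
      if (any(dist <= 2)) {
        warning(sprintf(
          "%d %s barcode pair(s) differ at <= 2 positions; separation > 2 is recommended",
          sum(dist <= 2), e), call. = FALSE)
      }
    }
  }
  df
}

#' Read and validate a target-specific primer sheet
#'
#' Columns `target`, `genome` (chloroplast or nuclear), `fwd`, `rev`. The
#' sequences are the target-specific parts only; conserved CS1/CS2 tails
#' must not be included (they are not present on the sequenced insert side
#' being matched).
#'
#' @param path TSV file path.
#' @return data.frame with upper-cased primer sequences.
#' @export
read_primer_sheet <- function(path) {
  df <- read_tsv_checked(path, c("target", "genome", "fwd", "rev"), "primer")
  validate_primers(df)
}

validate_primers <- function(df) {
  df$fwd <- toupper(df$fwd)
  df$rev <- toupper(df$rev)
  df$genome <- tolower(df$genome)
  if (anyDuplicated(df$target)) {
    stop(sprintf("duplicate target id(s): %s",
                 paste(unique(df$target[duplicated(df$target)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (!all(df$genome %in% c("chloroplast", "nuclear"))) {
    stop("primer 'genome' must be chloroplast or nuclear", call. = FALSE)
  }
  assert_dna(df$fwd, "primer sheet (fwd)")
  assert_dna(df$rev, "primer sheet (rev)")
  df
}

#' Read and validate a sample sheet
#'
#' Columns `sample`, `p5`, `p7` and optionally `project`. Each (p5, p7)
#' barcode-name pair must be unique: it is the demultiplexing key.
#'
#' @param path TSV file path.
#' @param barcodes validated barcode sheet, used to check that every
#'   referenced barcode name exists at the right end; NULL skips the check.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path, barcodes = NULL) {
  df <- read_tsv_checked(path, c("sample", "p5", "p7"), "sample")
  if (!"project" %in% names(df)) df$project <- NA_character_
  validate_samples(df, barcodes)
}

validate_samples <- function(df, barcodes = NULL) {
  key <- paste(df$p5, df$p7, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate barcode pair(s) in sample sheet: %s",
                 paste(unique(paste(dup$p5, dup$p7, sep = "+")),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    warning("duplicate sample id(s); their pools will be merged",
            call. = FALSE)
  }
  if (!is.null(barcodes)) {
    p5 <- barcodes$name[barcodes$end == "P5"]
    p7 <- barcodes$name[barcodes$end == "P7"]
    unknown <- c(setdiff(df$p5, p5), setdiff(df$p7, p7))
    if (length(unknown) > 0) {
      stop(sprintf("sample sheet references unknown barcode name(s): %s",
                   paste(unique(unknown), collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Load the three run sheets
#'
#' @param barcode_path,primer_path,sample_path TSV paths.
#' @return list with elements `barcodes`, `primers`, `samples` and
#'   `barcode_pairs`, the number of possible dual-barcode combinations
#'   (P5 count times P7 count).
#' @export
load_sheets <- function(barcode_path, primer_path, sample_path) {
  barcodes <- read_barcode_sheet(barcode_path)
  primers <- read_primer_sheet(primer_path)
  samples <- read_sample_sheet(sample_path, barcodes)
  structure(
    list(barcodes = barcodes, primers = primers, samples = samples,
         barcode_pairs = sum(barcodes$end == "P5") *
           sum(barcodes$end == "P7")),
    class = "amplikit_sheets")
}

#' @export
print.amplikit_sheets <- function(x, ...) {
  cat(sprintf(
    "amplikit run sheets: %d P5 + %d P7 barcodes (%d possible pairs), %d primer pairs, %d samples\n",
    sum(x$barcodes$end == "P5"), sum(x$barcodes$end == "P7"),
    x$barcode_pairs, nrow(x$primers), nrow(x$samples)))
  invisible(x)
}

## ---- FASTQ ------------------------------------------------------------

fastq_is_empty <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  length(readBin(con, "raw", n = 1L)) == 0L
}

read_one_fastq <- function(path) {
  if (fastq_is_empty(path)) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      stop(sprintf("malformed FASTQ in %s (near line %d): %s", path,
                   fastq_defect_line(path), conditionMessage(e)),
           call. = FALSE)
    })
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

## locate the first structurally bad line for the error message
fastq_defect_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i + 3L <= n) {
    if (!startsWith(lines[i], "@")) return(i)
    if (!startsWith(lines[i + 2L], "+")) return(i + 2L)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(i + 3L)
    i <- i + 4L
  }
  if (i <= n) return(i)
  n
}

strip_mate_suffix <- function(id) {
  sub("/[12]$", "", vapply(strsplit(id, "[ \t]"), `[[`, character(1), 1L))
}

header_barcode <- function(id) {
  field <- sub(".*:", "", id)
  field[!grepl("^[ACGTN+]+$", field)] <- ""
  field
}

#' Read a paired-end FASTQ run into a read-pair table
#'
#' Index (barcode) sequences come from separate index FASTQs when `i1_path`
#' and `i2_path` are given, otherwise from the read headers (the field after
#' the last colon, `BC1+BC2` or a single barcode per mate header).
#'
#' @param r1_path,r2_path mate FASTQ files (optionally gzipped).
#' @param i1_path,i2_path optional index FASTQ files.
#' @param barcode_source "auto" (default; index files when supplied, else
#'   headers), "index", or "header".
#' @return data.frame with columns id, r1_seq, r1_qual, r2_seq, r2_qual,
#'   r1_bc, r2_bc, in file order.
#' @export
read_fastq_pairs <- function(r1_path, r2_path, i1_path = NULL,
                             i2_path = NULL,
                             barcode_source = c("auto", "index", "header")) {
  barcode_source <- match.arg(barcode_source)
  r1 <- read_one_fastq(r1_path)
  r2 <- read_one_fastq(r2_path)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf(
      "read files out of step: %s has %d records, %s has %d (first missing record: %d)",
      r1_path, nrow(r1), r2_path, nrow(r2), min(nrow(r1), nrow(r2)) + 1L),
      call. = FALSE)
  }
  id1 <- strip_mate_suffix(r1$id)
  id2 <- strip_mate_suffix(r2$id)
  bad <- which(id1 != id2)
  if (length(bad) > 0) {
    stop(sprintf("mate ids disagree at record %d: '%s' vs '%s'",
                 bad[1], id1[bad[1]], id2[bad[1]]), call. = FALSE)
  }
  use_index <- (barcode_source == "index") ||
    (barcode_source == "auto" && !is.null(i1_path) && !is.null(i2_path))
  if (use_index) {
    if (is.null(i1_path) || is.null(i2_path)) {
      stop("barcode_source='index' requires i1_path and i2_path",
           call. = FALSE)
    }
    i1 <- read_one_fastq(i1_path)
    i2 <- read_one_fastq(i2_path)
    if (nrow(i1) != nrow(r1) || nrow(i2) != nrow(r1)) {
      stop("index files out of step with read files", call. = FALSE)
    }
    bc1 <- toupper(i1$seq)
    bc2 <- toupper(i2$seq)
  } else {
    f1 <- header_barcode(r1$id)
    with_plus <- grepl("+", f1, fixed = TRUE)
    bc1 <- ifelse(with_plus, sub("\\+.*", "", f1), f1)
    bc2 <- ifelse(with_plus, sub(".*\\+", "", f1), header_barcode(r2$id))
  }
  data.frame(id = id1, r1_seq = toupper(r1$seq), r1_qual = r1$qual,
             r2_seq = toupper(r2$seq), r2_qual = r2$qual,
             r1_bc = bc1, r2_bc = bc2, stringsAsFactors = FALSE)
}

## ---- output writers ---------------------------------------------------

#' Write sequences as FASTA
#'
#' @param records named character vector of sequences, or a data.frame with
#'   columns `id` and `sequence`. Input order is preserved.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.data.frame(records)) {
    records <- stats::setNames(records$sequence, records$id)
  }
  if (length(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

write_fastq <- function(ids, seqs, quals, path) {
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write a TSV table
#'
#' Plain tab-separated output with a header row, no quoting, rows in input
#' order.
#'
#' @param rows data.frame.
#' @param path output file.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
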
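## Shared sequence helpers and the closed-form multiplexing arithmetic.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0
  out[nz] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
  )
  out
}

reverse_strings <- function(x) .cpp_reverse_strings(x)

#' Levenshtein edit distance between sequence pairs
#'
#' Elementwise edit distance between two equal-length character vectors
#' (recycled if one has length 1).
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  .cpp_levenshtein(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

## strict ACGT check (used by sheet validation)
is_dna <- function(x) {
  !is.na(x) & nchar(x) > 0 & !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what) {
  bad <- which(!is_dna(toupper(x)))
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-ACGT or empty sequences at row(s) %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

## base set -> IUPAC code, built from the canonical Biostrings map
iupac_code_for <- local({
  map <- NULL
  function(bases) {
    if (is.null(map)) {
      m <- Biostrings::IUPAC_CODE_MAP
      key <- vapply(strsplit(unname(m), ""), function(b)
        paste(sort(b), collapse = ""), character(1))
      map <<- stats::setNames(names(m), key)
    }
    map[[paste(sort(unique(bases)), collapse = "")]]
  }
})

#' Multiplexing bookkeeping for dual-barcoded microfluidic amplicon runs
#'
#' Closed-form accounting for a run design: how many sample-by-target pools
#' one microfluidic array produces, how many unique dual-barcode pairs a
#' barcode set supports, how many samples can be multiplexed with a given
#' number of forward/reverse barcoded primers, the total amplicon count of a
#' run, how many arrays that run needs, and how many conventional 96-well
#' PCR plates a two-reaction tagging strategy would need for the same number
#' of amplicons.
#'
#' @param samples_per_array,targets_per_array array geometry (default 48x48).
#' @param n_p5,n_p7 number of distinct P5-side and P7-side barcodes.
#' @param n_fwd_barcoded,n_rev_barcoded number of forward/reverse barcoded
#'   primers actually synthesised.
#' @param n_samples,n_targets totals for the whole run.
#' @param plate_wells wells per conventional PCR plate (default 96).
#' @param reactions_per_amplicon PCR reactions per amplicon under the
#'   conventional two-reaction tagging strategy (default 2).
#' @return named list with elements `pools_per_array`, `barcode_pairs`,
#'   `max_multiplexed_samples`, `total_amplicons`, `arrays_required`,
#'   `plates_required_two_step`.
#' @examples
#' multiplex_bookkeeping(n_samples = 576, n_targets = 96)$total_amplicons
#' @export
multiplex_bookkeeping <- function(samples_per_array = 48,
                                  targets_per_array = 48,
                                  n_p5 = 24, n_p7 = 36,
                                  n_fwd_barcoded = 48, n_rev_barcoded = 24,
                                  n_samples = 576, n_targets = 96,
                                  plate_wells = 96,
                                  reactions_per_amplicon = 2) {
  pools <- samples_per_array * targets_per_array
  total <- n_samples * n_targets
  list(
    pools_per_array = pools,
    barcode_pairs = n_p5 * n_p7,
    max_multiplexed_samples = n_fwd_barcoded * n_rev_barcoded,
    total_amplicons = total,
    arrays_required = ceiling(total / pools),
    plates_required_two_step = ceiling(total * reactions_per_amplicon /
                                         plate_wells)
  )
}
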
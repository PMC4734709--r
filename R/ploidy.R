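## Bioinformatic karyotyping: aggregate per-pool allele counts into a
## sample-by-target matrix and minimum-ploidy calls.
##
## The call is a *minimum*: it is the smallest ploidy level consistent with
## the largest number of distinct alleles seen at any locus (1-2 alleles ->
## diploid, 3-4 -> tetraploid, >4 -> higher). Homozygosity, low divergence
## and autopolyploidy can all hide true ploidy, so the call can only ever be
## a lower bound.

ploidy_class <- function(max_alleles) {
  ifelse(is.na(max_alleles) | max_alleles == 0, NA_character_,
         ifelse(max_alleles <= 2, "diploid",
                ifelse(max_alleles <= 4, "tetraploid", "higher")))
}

#' Build the sample-by-target allele-count matrix
#'
#' @param allele_sets list of `allele_set` objects (see [call_alleles()]),
#'   or an allele-count data.frame as produced by [reduce_run()] in
#'   occurrence mode (columns sample/target/allele/status).
#' @return integer matrix, rows = samples, cols = targets; a discarded or
#'   missing (sample, target) is 0.
#' @export
build_allele_matrix <- function(allele_sets) {
  if (is.data.frame(allele_sets)) {
    df <- allele_sets
    n_alleles <- stats::aggregate(
      list(n = ifelse(df$status == "ok", 1L, 0L)),
      by = list(sample = df$sample, target = df$target), FUN = sum)
  } else {
    n_alleles <- data.frame(
      sample = vapply(allele_sets, `[[`, character(1), "sample_id"),
      target = vapply(allele_sets, `[[`, character(1), "target_id"),
      n = vapply(allele_sets, function(a)
        if (a$status == "ok") nrow(a$alleles) else 0L, integer(1)),
      stringsAsFactors = FALSE)
    if (anyDuplicated(paste(n_alleles$sample, n_alleles$target, sep = "\t"))) {
      stop("duplicate (sample, target) allele sets", call. = FALSE)
    }
  }
  samples <- sort(unique(n_alleles$sample))
  targets <- sort(unique(n_alleles$target))
  mat <- matrix(0L, nrow = length(samples), ncol = length(targets),
                dimnames = list(samples, targets))
  mat[cbind(match(n_alleles$sample, samples),
            match(n_alleles$target, targets))] <- as.integer(n_alleles$n)
  mat
}

#' Call minimum ploidy per sample and per species
#'
#' Per sample: the maximum allele count over its loci sets the minimum
#' ploidy (1-2 -> diploid, 3-4 -> tetraploid, >4 -> "higher", reported
#' rather than rejected since artifacts can exceed 4). Per species: the
#' maximum over its samples. The percentage of loci (per sample) or of
#' individuals (per species) with at least 3 alleles is reported alongside,
#' to flag weakly supported tetraploid calls; loci with no surviving allele
#' set (count 0) are excluded from the per-sample denominator.
#'
#' @param matrix allele-count matrix from [build_allele_matrix()].
#' @param species_map data.frame with columns `sample` and `species`; every
#'   matrix row must be mapped.
#' @return list of class `ploidy_calls` with data.frames `samples`
#'   (sample, species, max_alleles, pct_loci_ge3, min_ploidy) and `species`
#'   (species, n_samples, max_alleles, pct_individuals_ge3, min_ploidy).
#' @export
call_min_ploidy <- function(matrix, species_map) {
  stopifnot(is.matrix(matrix))
  if (!all(c("sample", "species") %in% names(species_map))) {
    stop("species_map needs columns 'sample' and 'species'", call. = FALSE)
  }
  unmapped <- setdiff(rownames(matrix), species_map$sample)
  if (length(unmapped) > 0) {
    stop(sprintf("sample(s) missing from species map: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  species <- species_map$species[match(rownames(matrix),
                                       species_map$sample)]
  max_alleles <- apply(matrix, 1, max)
  n_scored <- rowSums(matrix > 0)
  n_ge3 <- rowSums(matrix >= 3)
  pct_loci <- ifelse(n_scored > 0, 100 * n_ge3 / n_scored, NA_real_)
  per_sample <- data.frame(
    sample = rownames(matrix), species = species,
    max_alleles = as.integer(max_alleles),
    pct_loci_ge3 = pct_loci,
    min_ploidy = ploidy_class(max_alleles),
    stringsAsFactors = FALSE, row.names = NULL)

  sp <- split(seq_len(nrow(per_sample)), per_sample$species)
  per_species <- do.call(rbind, lapply(names(sp), function(s) {
    ii <- sp[[s]]
    mx <- max(per_sample$max_alleles[ii])
    data.frame(
      species = s, n_samples = length(ii), max_alleles = mx,
      pct_individuals_ge3 = 100 * mean(per_sample$max_alleles[ii] >= 3),
      min_ploidy = ploidy_class(mx), stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL
  structure(list(samples = per_sample, species = per_species),
            class = "ploidy_calls")
}

#' @export
print.ploidy_calls <- function(x, ...) {
  tab <- table(x$samples$min_ploidy, useNA = "ifany")
  cat(sprintf("ploidy calls for %d samples / %d species: %s\n",
              nrow(x$samples), nrow(x$species),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write the three karyotyping tables
#'
#' Per-cell allele counts, per-sample summary and per-species summary.
#'
#' @param matrix allele-count matrix.
#' @param calls a `ploidy_calls` object.
#' @param out_dir output directory.
#' @export
write_ploidy_tables <- function(matrix, calls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- data.frame(sample = rownames(matrix), matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_table(counts, file.path(out_dir, "allele_matrix.tsv"))
  write_table(calls$samples, file.path(out_dir, "ploidy_by_sample.tsv"))
  write_table(calls$species, file.path(out_dir, "ploidy_by_species.tsv"))
  invisible(out_dir)
}
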
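# Variant-site discovery from a multiple sequence alignment of the
# candidate-gene coding region. Direct Sanger genotyping of diploids
# yields one consensus sequence per bird in which IUPAC two-base
# ambiguity codes (R, Y, S, W, K, M) denote heterozygous positions; an
# unambiguous non-reference base is a homozygous alternate call.

#' Read an aligned FASTA file
#'
#' All sequences must have equal (aligned) length. Sequences are
#' upper-cased; `.` gap characters are converted to `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "npyassoc_io_error")
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(chartr(".", "-", as.character(set)))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(seqs))) > 1L)
    abort("aligned sequences must all have equal length",
          "npyassoc_alignment_error")
  seqs
}

#' Call biallelic variant sites from a multiple sequence alignment
#'
#' Scans alignment columns against the named reference sequence.
#' Positions are reported on the ungapped reference coordinate system:
#' columns where the reference carries a gap are skipped and do not
#' advance the coordinate. Per sample and column, an unambiguous base
#' equal to the reference is a ref-homozygote, a different unambiguous
#' base an alt-homozygote, and an IUPAC two-base ambiguity code a
#' heterozygote for its allele pair; gaps, `N` and three/four-base codes
#' are treated as missing. Columns where more than two alleles segregate
#' among the samples are excluded from the biallelic catalogue and
#' reported separately. If the reference base is absent from every
#' sample while two other alleles segregate, the major sample allele is
#' taken as ref and the site is flagged (`ref_unobserved`).
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (as from [read_alignment()]).
#' @param reference_id Name of the reference sequence within `aln`; the
#'   reference must contain no ambiguity codes.
#' @param locus_prefix Label prefix for discovered sites (default
#'   `"SNP"`, numbering sites in position order).
#' @return List with elements `sites` (locus-definition data frame with
#'   extra columns `label` and `ref_unobserved`), `genotypes` (a
#'   [genotype_table()] of the non-reference samples; breed label
#'   `"unknown"`), and `multiallelic` (data frame of excluded sites).
#' @export
call_variant_sites <- function(aln, reference_id, locus_prefix = "SNP") {
  if (length(unique(nchar(aln))) > 1L)
    abort("aligned sequences must all have equal length",
          "npyassoc_alignment_error")
  if (!reference_id %in% names(aln))
    abort(sprintf("reference id '%s' not found in alignment", reference_id),
          "npyassoc_lookup_error")
  ref_seq <- strsplit(aln[[reference_id]], "")[[1]]
  if (any(!ref_seq %in% c("A", "C", "G", "T", "-")))
    abort("reference sequence must contain no ambiguity codes",
          "npyassoc_alignment_error")
  sample_ids <- setdiff(names(aln), reference_id)
  mat <- do.call(rbind, strsplit(aln[sample_ids], ""))
  rownames(mat) <- sample_ids

  nucs <- c("A", "C", "G", "T")
  sites <- list(); multi <- list()
  geno_cols <- list()
  refpos <- 0L
  for (col in seq_along(ref_seq)) {
    ref <- ref_seq[col]
    if (ref == "-") next          # reference gap: coordinate does not advance
    refpos <- refpos + 1L
    chars <- mat[, col]
    # per-sample allele pairs; NA = missing
    pairs <- lapply(chars, function(ch) {
      if (ch %in% nucs) c(ch, ch)
      else if (ch %in% names(iupac_het)) strsplit(iupac_het[[ch]], "")[[1]]
      else NULL                   # gap / N / 3-4 base codes -> missing
    })
    observed <- sort(unique(unlist(pairs)))
    if (length(observed) == 0L || identical(observed, ref)) next
    if (all(observed %in% ref)) next
    if (length(observed) > 2L) {
      multi[[length(multi) + 1L]] <- data.frame(
        position = refpos, ref = ref,
        alleles = paste(observed, collapse = "/"),
        stringsAsFactors = FALSE)
      next
    }
    ref_unobserved <- !ref %in% observed && length(observed) == 2L
    if (ref_unobserved) {
      # polarity fallback: major sample allele becomes ref
      tab <- table(factor(unlist(pairs), levels = observed))
      site_ref <- names(tab)[which.max(tab)]
      site_alt <- setdiff(observed, site_ref)
    } else {
      site_ref <- ref
      site_alt <- setdiff(observed, ref)
      if (length(site_alt) == 0L) next
    }
    calls <- vapply(pairs, function(pr) {
      if (is.null(pr)) return(NA_character_)
      if (!all(pr %in% c(site_ref, site_alt))) return(NA_character_)
      paste(sort(pr), collapse = "")
    }, character(1))
    sites[[length(sites) + 1L]] <-
      cbind(locus_def(sprintf("pos%d", refpos), refpos, site_ref, site_alt),
            ref_unobserved = ref_unobserved)
    geno_cols[[length(geno_cols) + 1L]] <- calls
  }
  multiallelic <- if (length(multi)) do.call(rbind, multi) else
    data.frame(position = integer(0), ref = character(0),
               alleles = character(0), stringsAsFactors = FALSE)
  if (!length(sites)) {
    return(list(sites = data.frame(locus_id = character(0),
                                   position = integer(0), ref = character(0),
                                   alt = character(0), label = character(0),
                                   ref_unobserved = logical(0)),
                genotypes = NULL, multiallelic = multiallelic))
  }
  site_df <- do.call(rbind, sites)
  site_df$locus_id <- sprintf("%s%d", locus_prefix, seq_len(nrow(site_df)))
  site_df$label <- locus_label(site_df)
  samples <- data.frame(sample_id = sample_ids, breed = "unknown",
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(site_df)))
    samples[[site_df$locus_id[i]]] <- unname(geno_cols[[i]])
  gt <- genotype_table(samples,
                       site_df[, c("locus_id", "position", "ref", "alt")])
  list(sites = site_df[, c("locus_id", "position", "ref", "alt", "label",
                           "ref_unobserved")],
       genotypes = gt, multiallelic = multiallelic)
}

#' Write a discovered site catalogue as TSV
#'
#' @param sites `sites` element of a [call_variant_sites()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_site_catalogue <- function(sites, path) {
  write_tsv(sites, path)
  invisible(path)
}
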
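#' Define a biallelic SNP locus
#'
#' A locus is a position on the ungapped reference coding sequence together
#' with its reference and alternate alleles. Display names follow the
#' HGVS-like convention used for coding-region SNPs, `g.<pos> <ref>><alt>`
#' (e.g. `g.130 A>G`).
#'
#' @param locus_id Short label, e.g. `"SNP1"`.
#' @param position 1-based integer position on the reference coding sequence.
#' @param ref Reference allele, one of `A`, `C`, `G`, `T`.
#' @param alt Alternate allele, one of `A`, `C`, `G`, `T`; must differ
#'   from `ref`.
#' @return A one-row data frame with columns `locus_id`, `position`,
#'   `ref`, `alt`.
#' @export
#' @examples
#' locus_def("SNP1", 130, "A", "G")
locus_def <- function(locus_id, position, ref, alt) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, nzchar(locus_id))
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    abort("locus position must be a 1-based positive integer",
          "npyassoc_validation_error")
  nucs <- c("A", "C", "G", "T")
  if (!ref %in% nucs || !alt %in% nucs)
    abort(sprintf("locus %s: alleles must be unambiguous nucleotides (A/C/G/T)",
                  locus_id),
          "npyassoc_validation_error")
  if (ref == alt)
    abort(sprintf("locus %s: ref and alt allele must differ", locus_id),
          "npyassoc_validation_error")
  data.frame(locus_id = locus_id, position = position,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Display name of a locus
#'
#' @param locus A locus definition row (or data frame of them).
#' @return Character vector like `"g.130 A>G"`.
#' @export
locus_label <- function(locus) {
  sprintf("g.%d %s>%s", locus$position, locus$ref, locus$alt)
}

# IUPAC two-base ambiguity codes used for Sanger-style heterozygote calls
iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Normalize a genotype call
#'
#' Calls are unordered allele pairs stored as a lexicographically sorted
#' two-character string, so `"GA"` and `"AG"` denote the same call.
#' `"."`, `"NA"`, `""` and `NA` are treated as missing.
#'
#' @param call Character vector of two-character genotype strings.
#' @return Character vector of normalized calls (`NA` for missing).
#' @export
#' @examples
#' normalize_call(c("GA", "AG", "."))  # "AG" "AG" NA
normalize_call <- function(call) {
  call <- as.character(call)
  call[call %in% c(".", "NA", "")] <- NA_character_
  ok <- !is.na(call)
  if (any(nchar(call[ok]) != 2L))
    abort("genotype calls must be two-character allele pairs",
          "npyassoc_validation_error")
  norm <- function(x) {
    a <- sort(strsplit(x, "")[[1]])
    paste(a, collapse = "")
  }
  call[ok] <- vapply(call[ok], norm, character(1))
  call
}

#' Is a call heterozygous?
#'
#' Derivable without locus context: a call is heterozygous when its two
#' allele characters differ.
#'
#' @param call Normalized genotype call(s).
#' @return Logical vector (`NA` for missing calls).
#' @export
is_heterozygote <- function(call) {
  ifelse(is.na(call), NA,
         substr(call, 1, 1) != substr(call, 2, 2))
}

# genotype class of a call at a locus: "ref_hom", "het", "alt_hom" or NA
genotype_class <- function(call, ref, alt) {
  hom_ref <- paste0(ref, ref)
  hom_alt <- paste0(alt, alt)
  het <- paste(sort(c(ref, alt)), collapse = "")
  out <- rep(NA_character_, length(call))
  out[!is.na(call) & call == hom_ref] <- "ref_hom"
  out[!is.na(call) & call == het] <- "het"
  out[!is.na(call) & call == hom_alt] <- "alt_hom"
  bad <- !is.na(call) & is.na(out)
  if (any(bad))
    abort(sprintf("call(s) %s use alleles outside {%s,%s}",
                  paste(unique(call[bad]), collapse = ","), ref, alt),
          "npyassoc_validation_error")
  out
}
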
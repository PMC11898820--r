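# Built-in reference data: the published NPY candidate-gene study of
# Thai native (Pradu Hang Dum, Chee), black-bone and commercial laying
# hens. Genotype counts and trait summaries are transcribed from the
# published per-breed tables; they make every diversity statistic exactly
# recomputable and parameterize the default synthetic study.

#' Locus catalogue of the seven NPY coding-region SNPs
#'
#' @return Locus-definition data frame (`locus_id`, `position`, `ref`, `alt`)
#'   for SNP1 g.130 A>G through SNP7 g.647 G>T.
#' @export
npy_loci <- function() {
  rbind(
    locus_def("SNP1", 130L, "A", "G"),
    locus_def("SNP2", 301L, "C", "T"),
    locus_def("SNP3", 389L, "G", "A"),
    locus_def("SNP4", 404L, "G", "T"),
    locus_def("SNP5", 427L, "G", "A"),
    locus_def("SNP6", 596L, "G", "A"),
    locus_def("SNP7", 647L, "G", "T"))
}

#' Breed sample sizes of the NPY study
#'
#' @return Named integer vector: 59 Pradu Hang Dum (PH), 20 Chee (C),
#'   20 black-bone (BB), 18 commercial layers (LC); 117 hens in total.
#' @export
npy_breed_sizes <- function() {
  c(PH = 59L, C = 20L, BB = 20L, LC = 18L)
}

#' Published per-breed genotype counts at the seven NPY SNPs
#'
#' Counts of ref-homozygote, heterozygote and alt-homozygote hens per
#' breed per locus, as published. These counts reproduce the published
#' allele frequencies, PIC, expected heterozygosity and Hardy-Weinberg
#' chi-square values (with two known transcription quirks documented in
#' the package vignette).
#'
#' @return Data frame with columns `locus_id`, `breed`, `n_refref`,
#'   `n_refalt`, `n_altalt`.
#' @export
npy_genotype_counts <- function() {
  txt <- "
locus_id breed n_refref n_refalt n_altalt
SNP1 PH 41  8 10
SNP1 C  14  5  1
SNP1 BB 15  2  3
SNP1 LC 11  2  5
SNP2 PH 37  7 15
SNP2 C  10  7  3
SNP2 BB 13  1  6
SNP2 LC 14  1  3
SNP3 PH 27  9 23
SNP3 C   7  7  6
SNP3 BB  7  2 11
SNP3 LC  8  4  6
SNP4 PH 31  2 26
SNP4 C  14  3  3
SNP4 BB 13  2  5
SNP4 LC 10  4  4
SNP5 PH 25  5 29
SNP5 C   6  7  7
SNP5 BB  9  3  8
SNP5 LC  4  5  9
SNP6 PH 21 11 27
SNP6 C   2  8 10
SNP6 BB  1  4 15
SNP6 LC  9  4  5
SNP7 PH 34 14 11
SNP7 C  13  4  3
SNP7 BB 14  5  1
SNP7 LC 10  7  1
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Published per-breed trait means and standard deviations
#'
#' Mean and sample SD of the eight egg-production traits per breed, as
#' published. These parameterize the default phenotype simulator.
#'
#' @return Data frame with columns `trait`, `breed`, `mean`, `sd`.
#' @export
npy_trait_params <- function() {
  txt <- "
trait breed mean sd
AFEP PH 151.89  9.59
AFEP C  188.05 24.14
AFEP BB 170.60 12.41
AFEP LC 140.44  5.18
FEW  PH  33.29  6.07
FEW  C   35.08  3.86
FEW  BB  41.55  1.05
FEW  LC  43.77  7.05
EW_9M PH 44.81  3.10
EW_9M C  41.15  2.94
EW_9M BB 44.45  1.09
EW_9M LC 51.48  6.91
EW_12M PH 44.95 3.06
EW_12M C  43.30 3.16
EW_12M BB 48.55 1.05
EW_12M LC 53.50 6.91
NE_9M PH 159.61 35.49
NE_9M C   55.30 23.01
NE_9M BB  52.85 19.59
NE_9M LC 195.61 15.79
NE_12M PH 196.90 43.32
NE_12M C   73.70 30.70
NE_12M BB  87.55 28.78
NE_12M LC 254.44 14.08
EperM PH 16.40 3.61
EperM C   6.14 2.55
EperM BB  7.29 2.39
EperM LC 21.20 1.17
EMs PH 42.63 9.82
EMs C  17.95 5.76
EMs BB 22.06 6.03
EMs LC 60.67 8.76
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Expand per-breed genotype counts into a genotype table
#'
#' Reconstructs an individual-level [genotype_table()] whose per-breed,
#' per-locus genotype counts equal the given count table exactly. Hens are
#' assigned deterministic ids (`<breed>_<index>`); within a breed, calls
#' are laid out locus by locus in the block order ref-hom, het, alt-hom.
#' Useful to rebuild the published study's genotype structure, which is
#' fully determined by its counts for every per-locus statistic.
#'
#' @param counts Count data frame as from [npy_genotype_counts()].
#' @param loci Locus definitions as from [npy_loci()].
#' @return A [genotype_table()].
#' @export
counts_to_genotype_table <- function(counts = npy_genotype_counts(),
                                     loci = npy_loci()) {
  breeds <- unique(counts$breed)
  samples <- do.call(rbind, lapply(breeds, function(br) {
    sub <- counts[counts$breed == br, ]
    ns <- unique(sub$n_refref + sub$n_refalt + sub$n_altalt)
    if (length(ns) != 1L)
      abort(sprintf("breed %s: inconsistent totals across loci", br),
            "npyassoc_validation_error")
    df <- data.frame(sample_id = sprintf("%s_%02d", br, seq_len(ns)),
                     breed = br, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(loci))) {
      l <- loci[i, ]
      row <- sub[sub$locus_id == l$locus_id, ]
      if (nrow(row) != 1L)
        abort(sprintf("no counts for breed %s locus %s", br, l$locus_id),
              "npyassoc_validation_error")
      df[[l$locus_id]] <- rep(
        c(paste0(l$ref, l$ref),
          paste(sort(c(l$ref, l$alt)), collapse = ""),
          paste0(l$alt, l$alt)),
        times = c(row$n_refref, row$n_refalt, row$n_altalt))
    }
    df
  }))
  genotype_table(samples, loci)
}
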
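# Per-population, per-locus diversity statistics for codominant biallelic
# markers: genotype/allele frequencies by gene counting, expected
# heterozygosity, polymorphism information content, and the Hardy-Weinberg
# chi-square goodness-of-fit test.

#' Genotype counts at a locus within a population
#'
#' Counts non-missing calls only. `population = "All"` pools every breed.
#'
#' @param table A [genotype_table()].
#' @param locus_id Locus identifier present in the table.
#' @param population A breed label, or `"All"` to pool all breeds.
#' @return List with integer fields `n_refref`, `n_refalt`, `n_altalt`
#'   and their sum `n`.
#' @export
genotype_counts <- function(table, locus_id, population = "All") {
  stopifnot(inherits(table, "genotype_table"))
  l <- table$loci[table$loci$locus_id == locus_id, ]
  if (nrow(l) != 1L)
    abort(sprintf("locus %s not in table", locus_id), "npyassoc_validation_error")
  samples <- table$samples
  if (!identical(population, "All")) {
    samples <- samples[samples$breed == population, , drop = FALSE]
    if (!nrow(samples))
      abort(sprintf("no samples in population '%s'", population),
            "npyassoc_degenerate_error")
  }
  cls <- genotype_class(samples[[locus_id]], l$ref, l$alt)
  list(n_refref = sum(cls == "ref_hom", na.rm = TRUE),
       n_refalt = sum(cls == "het", na.rm = TRUE),
       n_altalt = sum(cls == "alt_hom", na.rm = TRUE),
       n = sum(!is.na(cls)))
}

#' Allele frequencies by gene counting
#'
#' Maximum-likelihood estimator for a codominant biallelic marker:
#' `p = (2 n_refref + n_refalt) / (2n)`, `q = 1 - p`.
#'
#' @param counts Genotype counts as from [genotype_counts()].
#' @return List with fields `p` (ref allele) and `q` (alt allele).
#' @export
#' @examples
#' allele_frequencies(list(n_refref = 41, n_refalt = 8, n_altalt = 10))
allele_frequencies <- function(counts) {
  n <- counts$n %||% (counts$n_refref + counts$n_refalt + counts$n_altalt)
  if (n < 1L)
    abort("cannot estimate allele frequencies from 0 samples",
          "npyassoc_degenerate_error")
  p <- (2 * counts$n_refref + counts$n_refalt) / (2 * n)
  list(p = p, q = 1 - p)
}

#' Expected heterozygosity
#'
#' `H_E = 1 - sum(p_i^2)`; for a biallelic locus this is `2pq`, maximal
#' (0.5) at `p = 0.5`. The uncorrected form is used throughout — no
#' `2n/(2n-1)` small-sample correction.
#'
#' @param freqs Either an allele-frequency list from
#'   [allele_frequencies()] or a numeric vector of allele frequencies
#'   summing to 1.
#' @return Expected heterozygosity in `[0, 1 - 1/k]`.
#' @export
expected_heterozygosity <- function(freqs) {
  p <- if (is.list(freqs)) c(freqs$p, freqs$q) else freqs
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  1 - sum(p^2)
}

#' Polymorphism information content
#'
#' Botstein's marker-informativeness measure,
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. For two alleles this
#' is `1 - (p^2 + q^2) - 2 p^2 q^2 = H_E - 2 p^2 q^2`, maximal (0.375)
#' at `p = 0.5`.
#'
#' @inheritParams expected_heterozygosity
#' @return PIC value; always `<= H_E`.
#' @export
pic <- function(freqs) {
  p <- if (is.list(freqs)) c(freqs$p, freqs$q) else freqs
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  cross <- 0
  k <- length(p)
  for (i in seq_len(k - 1))
    for (j in seq((i + 1), k))
      cross <- cross + 2 * p[i]^2 * p[j]^2
  1 - sum(p^2) - cross
}

#' Classify marker informativeness from PIC
#'
#' Conventional thresholds: `< 0.25` modestly informative, `< 0.50`
#' reasonably informative, `>= 0.50` highly informative.
#'
#' @param pic_value Numeric PIC value(s).
#' @return Character vector of labels.
#' @export
pic_class <- function(pic_value) {
  ifelse(pic_value < 0.25, "modest",
         ifelse(pic_value < 0.50, "reasonable", "high"))
}

#' Hardy-Weinberg chi-square test
#'
#' Goodness-of-fit of observed genotype counts to Hardy-Weinberg
#' proportions `(p^2, 2pq, q^2) * n`, with `p` from gene counting and no
#' continuity correction. Two degrees-of-freedom conventions are exposed:
#' `alleles_based` (df = 1: three classes minus one minus one estimated
#' allele frequency; the statistically standard choice and the default)
#' and `classes_minus_1` (df = 2, critical value 5.99 at alpha = 0.05;
#' replication mode for reports that treat the three genotype classes as
#' a plain three-category goodness-of-fit test).
#'
#' A monomorphic locus (only one allele observed) returns `chi2 = 0`,
#' `df = 0`, `p_value = 1`, `in_hwe = TRUE`, flagged `monomorphic`.
#'
#' @param counts Genotype counts as from [genotype_counts()].
#' @param df_convention `"alleles_based"` (df = 1) or `"classes_minus_1"`
#'   (df = 2).
#' @param alpha Significance level for the `in_hwe` flag (default 0.05).
#' @return List with fields `chi2`, `df`, `p_value`, `in_hwe`,
#'   `monomorphic`.
#' @export
#' @examples
#' hwe_chisq(list(n_refref = 41, n_refalt = 8, n_altalt = 10))
hwe_chisq <- function(counts,
                      df_convention = c("alleles_based", "classes_minus_1"),
                      alpha = 0.05) {
  df_convention <- match.arg(df_convention)
  n <- counts$n %||% (counts$n_refref + counts$n_refalt + counts$n_altalt)
  if (n < 1L)
    abort("cannot test HWE with 0 samples", "npyassoc_degenerate_error")
  fr <- allele_frequencies(counts)
  if (fr$p == 0 || fr$q == 0)
    return(list(chi2 = 0, df = 0L, p_value = 1, in_hwe = TRUE,
                monomorphic = TRUE))
  expected <- c(fr$p^2, 2 * fr$p * fr$q, fr$q^2) * n
  observed <- c(counts$n_refref, counts$n_refalt, counts$n_altalt)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- if (df_convention == "alleles_based") 1L else 2L
  p_value <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p_value,
       in_hwe = p_value >= alpha, monomorphic = FALSE)
}

#' Per-population, per-locus diversity table
#'
#' One row per locus x population combination — every breed plus the
#' pooled `"All"` — with genotype counts and frequencies, gene-counting
#' allele frequencies, PIC, expected heterozygosity and the
#' Hardy-Weinberg chi-square test. Row order is deterministic: loci in
#' table order, populations in the given order with `"All"` last.
#'
#' @param table A [genotype_table()].
#' @param populations Character vector of breed labels; defaults to the
#'   breeds present in the table, in order of first appearance.
#' @param df_convention Degrees-of-freedom convention for [hwe_chisq()].
#' @param alpha Significance level for the `in_hwe` flag.
#' @return Data frame with one row per locus x population.
#' @export
diversity_table <- function(table, populations = NULL,
                            df_convention = c("alleles_based",
                                              "classes_minus_1"),
                            alpha = 0.05) {
  stopifnot(inherits(table, "genotype_table"))
  df_convention <- match.arg(df_convention)
  if (is.null(populations))
    populations <- unique(table$samples$breed)
  pops <- c(populations, "All")
  rows <- list()
  for (i in seq_len(nrow(table$loci))) {
    l <- table$loci[i, ]
    for (pop in pops) {
      cnt <- genotype_counts(table, l$locus_id, pop)
      fr <- allele_frequencies(cnt)
      hwe <- hwe_chisq(cnt, df_convention, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = l$locus_id, locus = locus_label(l), population = pop,
        n = cnt$n,
        n_refref = cnt$n_refref, n_refalt = cnt$n_refalt,
        n_altalt = cnt$n_altalt,
        f_refref = cnt$n_refref / cnt$n,
        f_refalt = cnt$n_refalt / cnt$n,
        f_altalt = cnt$n_altalt / cnt$n,
        p = fr$p, q = fr$q,
        pic = pic(fr), he = expected_heterozygosity(fr),
        chi2 = hwe$chi2, df = hwe$df, p_value = hwe$p_value,
        in_hwe = hwe$in_hwe, monomorphic = hwe$monomorphic,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a diversity table as a report
#'
#' Formats [diversity_table()] output with the rounding conventions of
#' printed genetics reports (half away from zero, two decimals).
#'
#' @param div Output of [diversity_table()].
#' @param format `"tsv"` data frame or `"markdown"` character vector.
#' @return A data frame (`tsv`) or character vector of markdown lines.
#' @export
format_diversity_report <- function(div, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  out <- data.frame(
    locus = div$locus, population = div$population, n = div$n,
    geno_freq = sprintf("%.2f (%d) / %.2f (%d) / %.2f (%d)",
                        round_half_up(div$f_refref), div$n_refref,
                        round_half_up(div$f_refalt), div$n_refalt,
                        round_half_up(div$f_altalt), div$n_altalt),
    p = round_half_up(div$p), q = round_half_up(div$q),
    pic = round_half_up(div$pic), he = round_half_up(div$he),
    chi2 = round_half_up(div$chi2), df = div$df,
    p_value = signif(div$p_value, 3),
    in_hwe = ifelse(div$monomorphic, "monomorphic",
                    ifelse(div$in_hwe, "yes", "no")),
    informativeness = pic_class(div$pic),
    stringsAsFactors = FALSE)
  if (format == "tsv") return(out)
  header <- paste(names(out), collapse = " | ")
  rule <- paste(rep("---", ncol(out)), collapse = " | ")
  body <- apply(out, 1, paste, collapse = " | ")
  c(paste("|", header, "|"), paste("|", rule, "|"), paste("|", body, "|"))
}
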
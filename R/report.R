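# Workflow orchestration: discover -> diversity -> association, each
# step writing machine-readable (TSV) and human-readable (markdown)
# reports plus an effective-configuration echo, so a full replication
# run is one run_study() call on a simulated study.

# write the effective options + package version + seed into outdir
write_run_log <- function(outdir, step, options) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- c(list(step = step,
                package = "npyassoc",
                version = as.character(utils::packageVersion("npyassoc")),
                r_version = paste(R.version$major, R.version$minor,
                                  sep = ".")),
           options)
  yaml::write_yaml(log, file.path(outdir, paste0(step, "_config.yaml")))
  invisible(NULL)
}

# accept a genotype_table or a path to one
as_genotype_table <- function(genotypes) {
  if (inherits(genotypes, "genotype_table")) return(genotypes)
  read_genotype_table(genotypes)
}

as_trait_table <- function(traits) {
  if (is.data.frame(traits)) return(traits)
  read_trait_table(traits)
}

#' Run variant discovery on an alignment
#'
#' Reads an aligned FASTA, calls biallelic variant sites against the
#' named reference, and writes the genotype table and site catalogue.
#'
#' @param alignment Path to an aligned FASTA file, or a named character
#'   vector of aligned sequences.
#' @param reference_id Name of the reference sequence.
#' @param outdir Output directory.
#' @return Invisibly, the [call_variant_sites()] result.
#' @export
run_discovery <- function(alignment, reference_id, outdir) {
  aln <- if (is.character(alignment) && length(alignment) == 1L &&
               file.exists(alignment)) read_alignment(alignment) else alignment
  res <- call_variant_sites(aln, reference_id)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_site_catalogue(res$sites, file.path(outdir, "site_catalogue.tsv"))
  if (!is.null(res$genotypes))
    write_genotype_table(res$genotypes, file.path(outdir, "genotypes.tsv"))
  if (nrow(res$multiallelic))
    write_tsv(res$multiallelic, file.path(outdir, "multiallelic_sites.tsv"))
  write_run_log(outdir, "discover",
                list(reference_id = reference_id,
                     n_sites = nrow(res$sites),
                     n_multiallelic = nrow(res$multiallelic)))
  invisible(res)
}

#' Run the diversity analysis
#'
#' Computes the per-population, per-locus diversity table (genotype and
#' allele frequencies, PIC, expected heterozygosity, Hardy-Weinberg
#' chi-square) and writes TSV and markdown reports.
#'
#' @param genotypes A [genotype_table()] or path to one.
#' @param outdir Output directory.
#' @param populations Breed labels to report (default: all, in order of
#'   appearance); the pooled `"All"` row set is always appended.
#' @param hwe_df `1` (`alleles_based`, default) or `2`
#'   (`classes_minus_1`, replication mode).
#' @param alpha Significance level for the `in_hwe` flag.
#' @return Invisibly, the [diversity_table()] data frame.
#' @export
run_diversity <- function(genotypes, outdir, populations = NULL,
                          hwe_df = 1, alpha = 0.05) {
  gt <- as_genotype_table(genotypes)
  if (!nrow(gt$samples))
    abort("genotype table has no samples", "npyassoc_format_error")
  conv <- if (hwe_df == 2) "classes_minus_1" else "alleles_based"
  div <- diversity_table(gt, populations, conv, alpha)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(format_diversity_report(div, "tsv"),
            file.path(outdir, "diversity.tsv"))
  writeLines(format_diversity_report(div, "markdown"),
             file.path(outdir, "diversity.md"))
  write_run_log(outdir, "diversity",
                list(hwe_df = hwe_df, alpha = alpha,
                     populations = populations %||% "all observed"))
  invisible(div)
}

#' Run the association analysis
#'
#' Breed-level trait summary plus the per-locus, per-trait association
#' scan, written as TSV and markdown reports.
#'
#' @param genotypes A [genotype_table()] or path to one.
#' @param traits A trait table or path to one.
#' @param outdir Output directory.
#' @param alpha Significance level for letters (default 0.05).
#' @param adjust Pairwise adjustment: `"none"`, `"bonferroni"`,
#'   `"tukey"`.
#' @param outlier_filter Apply the within-breed `|z| > 3.5` screen first
#'   (default `FALSE`).
#' @return Invisibly, list with `scan` and `breed_summary` data frames.
#' @export
run_association <- function(genotypes, traits, outdir, alpha = 0.05,
                            adjust = "none", outlier_filter = FALSE) {
  gt <- as_genotype_table(genotypes)
  tt <- as_trait_table(traits)
  scan <- association_scan(gt, tt, alpha = alpha, adjust = adjust,
                           outlier_filter = outlier_filter)
  bs <- breed_summary(gt, tt, alpha = alpha, adjust = adjust)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(scan, file.path(outdir, "association_scan.tsv"))
  writeLines(format_scan_report(scan, "markdown"),
             file.path(outdir, "association_scan.md"))
  write_tsv(bs, file.path(outdir, "breed_summary.tsv"))
  writeLines(format_breed_report(bs, "markdown"),
             file.path(outdir, "breed_summary.md"))
  write_run_log(outdir, "associate",
                list(alpha = alpha, adjust = adjust,
                     outlier_filter = outlier_filter))
  invisible(list(scan = scan, breed_summary = bs))
}

#' Run the full replication workflow on a simulated study
#'
#' One call: simulate a study from a configuration, then run the
#' diversity and association analyses on it, writing every report under
#' `outdir` (`study/`, `diversity/`, `association/`).
#'
#' @param cfg A [sim_config()]; default [default_sim_config()] with the
#'   given seed.
#' @param outdir Output directory.
#' @param seed Seed for the default configuration (ignored when `cfg`
#'   is supplied).
#' @param hwe_df Degrees-of-freedom convention for the diversity step.
#' @param ... Further arguments passed to [run_association()].
#' @return Invisibly, list with `study`, `diversity`, `association`.
#' @export
run_study <- function(cfg = NULL, outdir, seed = 1L, hwe_df = 1, ...) {
  cfg <- cfg %||% default_sim_config(seed = seed)
  study <- generate_study(cfg, file.path(outdir, "study"))
  div <- run_diversity(study$genotypes, file.path(outdir, "diversity"),
                       hwe_df = hwe_df)
  assoc <- run_association(study$genotypes, study$traits,
                           file.path(outdir, "association"), ...)
  invisible(list(study = study, diversity = div, association = assoc))
}
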
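#' Construct a genotype table
#'
#' The central container of the package: an ordered set of biallelic locus
#' definitions plus one row per hen carrying its breed label and one
#' normalized genotype call per locus.
#'
#' @param samples Data frame with columns `sample_id`, `breed`, and one
#'   character column per locus (named by `locus_id`) holding two-character
#'   genotype calls; `"."`, `"NA"` or `NA` denote missing.
#' @param loci Data frame of locus definitions as built by [locus_def()]
#'   (columns `locus_id`, `position`, `ref`, `alt`), in display order.
#' @return An object of class `genotype_table`: a list with elements
#'   `loci` and `samples` (calls normalized).
#' @export
genotype_table <- function(samples, loci) {
  required <- c("locus_id", "position", "ref", "alt")
  if (!all(required %in% names(loci)))
    abort("loci must have columns locus_id, position, ref, alt",
          "npyassoc_format_error")
  if (anyDuplicated(loci$locus_id))
    abort("duplicate locus_id in locus definitions", "npyassoc_validation_error")
  if (!all(c("sample_id", "breed") %in% names(samples)))
    abort("samples must have columns sample_id and breed",
          "npyassoc_format_error")
  missing_loci <- setdiff(loci$locus_id, names(samples))
  if (length(missing_loci))
    abort(sprintf("samples table lacks locus column(s): %s",
                  paste(missing_loci, collapse = ", ")),
          "npyassoc_format_error")
  samples$sample_id <- as.character(samples$sample_id)
  samples$breed <- as.character(samples$breed)
  if (anyDuplicated(samples$sample_id))
    abort("sample_id must be unique within a table", "npyassoc_validation_error")
  if (any(!nzchar(samples$breed)) || anyNA(samples$breed))
    abort("breed labels must be non-empty", "npyassoc_validation_error")
  # normalize and validate every call against its locus alphabet
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    calls <- normalize_call(samples[[lid]])
    cls <- tryCatch(
      genotype_class(calls, loci$ref[i], loci$alt[i]),
      npyassoc_validation_error = function(e) {
        bad <- which(!is.na(calls) &
                       !calls %in% c(paste0(loci$ref[i], loci$ref[i]),
                                     paste(sort(c(loci$ref[i], loci$alt[i])),
                                           collapse = ""),
                                     paste0(loci$alt[i], loci$alt[i])))
        abort(sprintf(
          "sample %s: call '%s' at locus %s uses alleles outside {%s,%s}",
          samples$sample_id[bad[1]], calls[bad[1]], lid,
          loci$ref[i], loci$alt[i]),
          "npyassoc_validation_error")
      })
    samples[[lid]] <- calls
  }
  samples <- samples[, c("sample_id", "breed", loci$locus_id), drop = FALSE]
  rownames(samples) <- NULL
  rownames(loci) <- NULL
  structure(list(loci = loci[, required], samples = samples),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples, %d loci\n",
              nrow(x$samples), nrow(x$loci)))
  br <- table(x$samples$breed)
  cat("breeds:", paste(sprintf("%s=%d", names(br), br), collapse = ", "), "\n")
  cat("loci:", paste(sprintf("%s (%s)", x$loci$locus_id, locus_label(x$loci)),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Per-breed sample counts
#'
#' @param table A [genotype_table()].
#' @return Named integer vector of sample counts per breed.
#' @export
breed_counts <- function(table) {
  tab <- table(table$samples$breed)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a genotype table from delimited text
#'
#' Expects a header row naming `sample_id`, `breed` and one column per
#' locus. Locus definitions (position, ref, alt) are taken from
#' `#locus`-prefixed comment lines of the form
#' `#locus <id> <position> <ref> <alt>` (as written by
#' [write_genotype_table()]), or from the `loci` argument; plain `#`
#' comment lines are ignored. If neither source defines a locus, its two
#' alleles are inferred from the observed calls (major allele as ref,
#' position `NA`) with a warning.
#'
#' @param path Path to a delimited text file.
#' @param loci Optional locus-definition data frame overriding file metadata.
#' @param sep Field delimiter; tab by default, `","` selectable.
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, loci = NULL, sep = "\t") {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "npyassoc_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#locus\t|^#locus ", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    abort("empty genotype file (no header row)", "npyassoc_format_error")
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  if (!all(c("sample_id", "breed") %in% names(df))) {
    lacking <- setdiff(c("sample_id", "breed"), names(df))
    abort(sprintf("malformed header: missing column(s) %s",
                  paste(lacking, collapse = ", ")),
          "npyassoc_format_error")
  }
  locus_cols <- setdiff(names(df), c("sample_id", "breed"))
  if (is.null(loci) && length(meta)) {
    parts <- strsplit(sub("^#locus[\t ]+", "", meta), "[\t ]+")
    loci <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) != 4L)
        abort("malformed #locus metadata line", "npyassoc_format_error")
      locus_def(p[1], as.integer(p[2]), p[3], p[4])
    }))
  }
  if (is.null(loci)) {
    warning("no locus definitions supplied; inferring alleles from calls",
            call. = FALSE)
    loci <- do.call(rbind, lapply(locus_cols, function(lid) {
      calls <- normalize_call(df[[lid]])
      al <- sort(table(unlist(strsplit(calls[!is.na(calls)], ""))),
                 decreasing = TRUE)
      if (length(al) < 2L)
        abort(sprintf("cannot infer two alleles at locus %s", lid),
              "npyassoc_format_error")
      locus_def(lid, 1L, names(al)[1], names(al)[2])
    }))
    loci$position <- NA_integer_
  }
  unknown <- setdiff(loci$locus_id, locus_cols)
  if (length(unknown))
    abort(sprintf("header lacks locus column(s): %s",
                  paste(unknown, collapse = ", ")),
          "npyassoc_format_error")
  loci <- loci[match(intersect(locus_cols, loci$locus_id), loci$locus_id), ]
  genotype_table(df, loci)
}

#' Write a genotype table to delimited text
#'
#' Emits `#locus` metadata lines (so the file round-trips through
#' [read_genotype_table()] without external locus definitions) followed by
#' a header and one row per sample. Missing calls are written as `"."`.
#' Output is byte-stable for a fixed table: column order is sample id,
#' breed, then loci in definition order.
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @param sep Field delimiter (tab default).
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "genotype_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(table$loci)))
    writeLines(paste("#locus", table$loci$locus_id[i], table$loci$position[i],
                     table$loci$ref[i], table$loci$alt[i], sep = "\t"), con)
  utils::write.table(table$samples, con, sep = sep, quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Trait definitions for the eight egg-production traits
#'
#' The study's phenotype panel: age at first egg production (AFEP, day),
#' first egg weight (FEW, g), egg weight at 9 and 12 months (EW_9M,
#' EW_12M, g), number of eggs at 9 and 12 months (NE_9M, NE_12M, egg),
#' eggs per month (EperM, egg) and egg mass (EMs, g/hen/day).
#'
#' @return Data frame with columns `trait` and `units`.
#' @export
trait_definitions <- function() {
  data.frame(
    trait = c("AFEP", "FEW", "EW_9M", "EW_12M",
              "NE_9M", "NE_12M", "EperM", "EMs"),
    units = c("day", "g", "g", "g", "egg", "egg", "egg", "g/hen/day"),
    stringsAsFactors = FALSE)
}

#' Read a trait (phenotype) table
#'
#' One row per hen: `sample_id` plus one numeric column per trait.
#' All trait values must be finite and non-negative; missing values
#' (`"."`, `"NA"`, empty) are allowed and tracked as `NA`.
#'
#' @param path Path to a delimited text file; `#` comment lines ignored.
#' @param sep Field delimiter (tab default).
#' @return Data frame of class `trait_table`.
#' @export
read_trait_table <- function(path, sep = "\t") {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "npyassoc_io_error")
  df <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                          na.strings = c(".", "NA", ""), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    abort("malformed header: missing column sample_id", "npyassoc_format_error")
  df$sample_id <- as.character(df$sample_id)
  for (tr in setdiff(names(df), "sample_id")) {
    df[[tr]] <- as.numeric(df[[tr]])
    bad <- which(is.finite(df[[tr]]) & df[[tr]] < 0)
    if (length(bad))
      abort(sprintf("trait %s: negative value for sample %s",
                    tr, df$sample_id[bad[1]]),
            "npyassoc_validation_error")
  }
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a trait table
#'
#' Columns: `sample_id` then traits in alphabetical order (deterministic
#' diffs); missing values written as `"."`.
#'
#' @param traits A trait table (data frame with `sample_id` + trait columns).
#' @param path Output file path.
#' @param sep Field delimiter (tab default).
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(traits, path, sep = "\t") {
  cols <- c("sample_id", sort(setdiff(names(traits), "sample_id")))
  utils::write.table(traits[, cols, drop = FALSE], path, sep = sep,
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Export a genotype table as minimal VCF 4.2
#'
#' One record per locus (`CHROM` = `reference_name`, `POS` = the locus's
#' 1-based coding-sequence position, `REF`, `ALT`) with a per-sample `GT`
#' field: `0/0` ref-homozygote, `0/1` heterozygote, `1/1` alt-homozygote,
#' `./.` missing.
#'
#' @param table A [genotype_table()].
#' @param reference_name Contig/reference label for the CHROM column.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_vcf <- function(table, reference_name, path) {
  stopifnot(inherits(table, "genotype_table"))
  gt_code <- c(ref_hom = "0/0", het = "0/1", alt_hom = "1/1")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples$sample_id),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(table$loci))) {
    l <- table$loci[i, ]
    cls <- genotype_class(table$samples[[l$locus_id]], l$ref, l$alt)
    gts <- ifelse(is.na(cls), "./.", gt_code[cls])
    writeLines(paste(c(reference_name, l$position, l$locus_id, l$ref, l$alt,
                       ".", ".", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
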
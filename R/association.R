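# Fixed-effect linear modelling of trait ~ genotype (or trait ~ breed):
# the model y_ij = mu + g_i + e_ij fitted by ordinary least squares on
# the cell-means parameterization, with an overall F test, least-squares
# means, pairwise t comparisons on the pooled residual variance, and a
# compact letter display. With an optional covariate the model gains a
# common slope and LS means are evaluated at the covariate grand mean.

#' Fit a one-way fixed-effect model
#'
#' Ordinary least squares on the cell-means parameterization: one mean
#' per factor level, plus (optionally) a common covariate slope. The
#' F statistic compares the factor's between-group sum of squares to the
#' pooled residual mean square. With no covariate, LS means equal
#' arithmetic group means; with a covariate, LS means are the fitted
#' level means evaluated at the covariate's grand mean.
#'
#' @param y Numeric response vector.
#' @param group Factor (or vector coerced to factor) of level labels.
#' @param covariate Optional numeric covariate of the same length.
#' @param level_order Optional character vector fixing the level order of
#'   the output (defaults to factor level order).
#' @return Object of class `oneway_fit`: a list with `levels`, `n` (per
#'   level), `ls_means`, `se`, `cov_lsmeans` (covariance matrix of the
#'   LS means), `residual_variance`, `df_factor`, `df_error`, `f_stat`,
#'   `p_value`, `slope` (`NA` without covariate), `dropped` (empty levels
#'   removed).
#' @export
#' @examples
#' fit <- fit_oneway(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' fit$ls_means
fit_oneway <- function(y, group, covariate = NULL, level_order = NULL) {
  keep <- !is.na(y) & !is.na(group)
  if (!is.null(covariate)) keep <- keep & !is.na(covariate)
  y <- y[keep]
  group <- if (is.null(level_order)) factor(group[keep]) else
    factor(group[keep], levels = level_order)
  group <- droplevels(group)
  covariate <- covariate[keep]
  dropped <- character(0)
  if (!is.null(level_order)) {
    dropped <- setdiff(level_order, levels(group))
    if (length(dropped))
      warning(sprintf("dropping empty factor level(s): %s",
                      paste(dropped, collapse = ", ")), call. = FALSE)
  }
  k <- nlevels(group)
  if (k < 2L)
    abort("factor must have at least 2 observed levels",
          "npyassoc_design_error")
  n <- length(y)
  df_error <- n - k - as.integer(!is.null(covariate))
  if (df_error < 1L)
    abort("model has no residual degrees of freedom",
          "npyassoc_design_error")

  X <- stats::model.matrix(~ 0 + group)
  colnames(X) <- levels(group)
  if (!is.null(covariate)) {
    # centering the covariate makes cell-means coefficients the LS means
    # evaluated at the covariate grand mean
    X <- cbind(X, .cov = covariate - mean(covariate))
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_error
  xtx_inv <- chol2inv(chol(crossprod(X)))
  cov_beta <- sigma2 * xtx_inv

  # reduced model: grand mean (+ covariate) only
  X0 <- matrix(1, n, 1)
  if (!is.null(covariate)) X0 <- cbind(X0, covariate - mean(covariate))
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  df_factor <- k - 1L
  f_stat <- ((rss0 - rss) / df_factor) / sigma2
  f_stat <- max(f_stat, 0)
  p_value <- stats::pf(f_stat, df_factor, df_error, lower.tail = FALSE)

  idx <- seq_len(k)
  structure(list(
    levels = levels(group),
    n = as.integer(table(group)),
    ls_means = unname(beta[idx]),
    se = sqrt(diag(cov_beta)[idx]),
    cov_lsmeans = cov_beta[idx, idx, drop = FALSE],
    residual_variance = sigma2,
    df_factor = df_factor, df_error = df_error,
    f_stat = f_stat, p_value = p_value,
    slope = if (is.null(covariate)) NA_real_ else unname(beta[k + 1L]),
    dropped = dropped), class = "oneway_fit")
}

#' @export
print.oneway_fit <- function(x, ...) {
  cat(sprintf("one-way fixed-effect fit: %d levels, df = (%d, %d)\n",
              length(x$levels), x$df_factor, x$df_error))
  print(data.frame(level = x$levels, n = x$n,
                   ls_mean = round(x$ls_means, 3), se = round(x$se, 3)))
  cat(sprintf("F = %.3f, p = %.4g, residual variance = %.4g\n",
              x$f_stat, x$p_value, x$residual_variance))
  invisible(x)
}

#' Pairwise comparisons of least-squares means
#'
#' Two-sided t tests on every LS-mean difference, using the pooled
#' residual variance and the fit's error degrees of freedom. Unadjusted
#' by default (LSD-style, matching typical GLM letter reports);
#' Bonferroni and Tukey HSD adjustments selectable.
#'
#' @param fit An [fit_oneway()] result.
#' @param adjust `"none"` (default), `"bonferroni"` or `"tukey"`.
#' @return Symmetric matrix of two-sided p-values with unit diagonal,
#'   dimnames = factor levels.
#' @export
pairwise_ttests <- function(fit, adjust = c("none", "bonferroni", "tukey")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "oneway_fit"))
  k <- length(fit$levels)
  p <- matrix(1, k, k, dimnames = list(fit$levels, fit$levels))
  m <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      d <- fit$ls_means[i] - fit$ls_means[j]
      se <- sqrt(fit$cov_lsmeans[i, i] + fit$cov_lsmeans[j, j] -
                   2 * fit$cov_lsmeans[i, j])
      tval <- if (se > 0) d / se else if (d == 0) 0 else Inf
      pij <- switch(adjust,
        none = 2 * stats::pt(abs(tval), fit$df_error, lower.tail = FALSE),
        bonferroni = min(1, m * 2 * stats::pt(abs(tval), fit$df_error,
                                              lower.tail = FALSE)),
        tukey = stats::ptukey(sqrt(2) * abs(tval), k, fit$df_error,
                              lower.tail = FALSE))
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb assignment: levels are swept in descending-mean
#' order; each level joins every existing letter group with which it is
#' mutually non-significant; if none accepts it, every conflicting group
#' is split — its subset compatible with the new level founds a new
#' group together with it — and groups that are subsets of another are
#' absorbed. Two levels share a letter iff their pairwise p-value is
#' `>= alpha`. Deterministic for a fixed input.
#'
#' @param pairwise Symmetric matrix of pairwise p-values (dimnames =
#'   level names), as from [pairwise_ttests()].
#' @param means Named numeric vector of level means fixing the sweep
#'   order (descending); letters are assigned in this order, so the
#'   highest mean gets `"a"`.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings per level.
#' @export
#' @examples
#' p <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' compact_letter_display(p, c(A = 3, B = 2, C = 1))  # "a", "ab", "b"
compact_letter_display <- function(pairwise, means, alpha = 0.05) {
  lv <- names(means)[order(-means)]
  stopifnot(setequal(lv, rownames(pairwise)))
  ns <- function(a, b) pairwise[a, b] >= alpha   # not significantly different
  drop_subsets <- function(gs) {
    keep <- vapply(seq_along(gs), function(i) {
      !any(vapply(seq_along(gs), function(j) {
        i != j && all(gs[[i]] %in% gs[[j]]) &&
          (length(gs[[i]]) < length(gs[[j]]) || j < i)
      }, logical(1)))
    }, logical(1))
    gs[keep]
  }
  groups <- list(lv[1])
  for (level in lv[-1]) {
    placed <- FALSE
    before <- groups
    for (gi in seq_along(groups)) {
      if (all(vapply(groups[[gi]], ns, logical(1), b = level))) {
        groups[[gi]] <- c(groups[[gi]], level)
        placed <- TRUE
      }
    }
    if (!placed) {
      # split every conflicting group: its subset compatible with the new
      # level founds a new group with it, so no non-significant pair is
      # dropped by the insertion
      for (g in before) {
        compat <- g[vapply(g, ns, logical(1), b = level)]
        groups[[length(groups) + 1L]] <- c(compat, level)
      }
      groups <- drop_subsets(groups)
    }
  }
  groups <- drop_subsets(groups)
  # letter groups ordered by their best-ranked member
  first_rank <- vapply(groups, function(g) min(match(g, lv)), numeric(1))
  groups <- groups[order(first_rank)]
  out <- stats::setNames(rep("", length(lv)), lv)
  for (gi in seq_along(groups))
    out[groups[[gi]]] <- paste0(out[groups[[gi]]], letters[gi])
  out[names(means)]
}

#' Levene's test for homogeneity of variance (Brown-Forsythe variant)
#'
#' One-way ANOVA, via the package's own [fit_oneway()] engine, on the
#' absolute deviations of each observation from its group median
#' (median centering for robustness).
#'
#' @param y Numeric response vector.
#' @param group Grouping factor.
#' @return List with `statistic` (F), `df` (factor, error), `p_value`.
#' @export
levene_test <- function(y, group) {
  keep <- !is.na(y) & !is.na(group)
  y <- y[keep]
  group <- droplevels(factor(group[keep]))
  med <- tapply(y, group, stats::median)
  z <- abs(y - med[as.character(group)])
  fit <- fit_oneway(as.numeric(z), group)
  list(statistic = fit$f_stat, df = c(fit$df_factor, fit$df_error),
       p_value = fit$p_value)
}

#' Remove within-breed trait outliers
#'
#' Optional screening step: per breed and trait, values whose modified
#' z-score `0.6745 (x - median) / MAD` exceeds `threshold` in magnitude
#' are set to missing (the conventional 3.5 rule; median/MAD centering
#' keeps the screen usable in small breeds, where a mean/SD z-score is
#' bounded by `(n-1)/sqrt(n)` and can never reach 3.5). Off by default
#' in every analysis entry point; removals are reported via a message
#' and returned in the `removed` attribute.
#'
#' @param traits Trait table (data frame with `sample_id` + trait columns).
#' @param genotypes A [genotype_table()] supplying breed labels.
#' @param threshold z-score threshold (default 3.5).
#' @return The trait table with outliers set to `NA`; attribute
#'   `removed` lists sample/trait pairs.
#' @export
filter_outliers <- function(traits, genotypes, threshold = 3.5) {
  breed <- genotypes$samples$breed[match(traits$sample_id,
                                         genotypes$samples$sample_id)]
  removed <- list()
  for (tr in setdiff(names(traits), "sample_id")) {
    for (br in unique(breed[!is.na(breed)])) {
      idx <- which(breed == br & !is.na(traits[[tr]]))
      if (length(idx) < 3L) next
      v <- traits[[tr]][idx]
      mad <- stats::mad(v)                 # scaled to sigma for normals
      if (mad == 0) next
      z <- abs(v - stats::median(v)) / mad
      out <- idx[z > threshold]
      if (length(out)) {
        removed[[length(removed) + 1L]] <- data.frame(
          sample_id = traits$sample_id[out], breed = br, trait = tr,
          value = traits[[tr]][out], stringsAsFactors = FALSE)
        traits[[tr]][out] <- NA
      }
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(sample_id = character(0), breed = character(0),
               trait = character(0), value = numeric(0))
  if (nrow(removed))
    message(sprintf("outlier filter removed %d value(s)", nrow(removed)))
  attr(traits, "removed") <- removed
  traits
}

#' Genotype factor at a locus
#'
#' Builds the per-sample genotype factor used as the fixed effect in the
#' association model, with levels in ref-homozygote / heterozygote /
#' alt-homozygote order (missing calls are `NA`).
#'
#' @param genotypes A [genotype_table()].
#' @param locus_id Locus identifier.
#' @return A factor of genotype call strings, one element per sample.
#' @export
locus_factor <- function(genotypes, locus_id) {
  l <- genotypes$loci[genotypes$loci$locus_id == locus_id, ]
  lv <- c(paste0(l$ref, l$ref),
          paste(sort(c(l$ref, l$alt)), collapse = ""),
          paste0(l$alt, l$alt))
  factor(genotypes$samples[[locus_id]], levels = lv)
}

#' Per-locus, per-trait association scan
#'
#' For every locus x trait combination, fits the one-way genotype model
#' (pooled across breeds by default, mirroring a single LS-means column
#' per genotype; breed-as-factor and age-covariate modes are available
#' through `fit_oneway()` directly) and reports LS means, standard
#' errors, the overall F-test p-value and compact letters. Genotype
#' classes with fewer than `min_class_n` hens are retained in the fit
#' (if n >= 1) but excluded from pairwise letters. Loci with a single
#' observed genotype class are reported as non-testable.
#'
#' @param genotypes A [genotype_table()].
#' @param traits Trait table sharing `sample_id` with `genotypes`.
#' @param loci Locus ids to scan (default: all loci in the table).
#' @param trait_names Traits to scan (default: all trait columns).
#' @param alpha Significance level for letters (default 0.05).
#' @param adjust Pairwise adjustment passed to [pairwise_ttests()].
#' @param min_class_n Minimum class size for letter eligibility
#'   (default 2).
#' @param outlier_filter Apply [filter_outliers()] first (default FALSE).
#' @return Data frame with one row per locus x trait x genotype class:
#'   columns `locus_id`, `locus`, `trait`, `genotype`, `class`, `n`,
#'   `ls_mean`, `se`, `letter`, `f_stat`, `p_value`, `testable`, `note`.
#' @export
association_scan <- function(genotypes, traits, loci = NULL,
                             trait_names = NULL, alpha = 0.05,
                             adjust = "none", min_class_n = 2L,
                             outlier_filter = FALSE) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.null(loci)) loci <- genotypes$loci$locus_id
  if (is.null(trait_names))
    trait_names <- setdiff(names(traits), "sample_id")
  miss <- setdiff(trait_names, names(traits))
  if (length(miss))
    abort(sprintf("trait table lacks column(s): %s",
                  paste(miss, collapse = ", ")),
          "npyassoc_format_error")
  if (outlier_filter) traits <- filter_outliers(traits, genotypes)
  ord <- match(genotypes$samples$sample_id, traits$sample_id)
  rows <- list()
  for (lid in loci) {
    g <- locus_factor(genotypes, lid)
    lab <- locus_label(genotypes$loci[genotypes$loci$locus_id == lid, ])
    for (tr in trait_names) {
      y <- traits[[tr]][ord]
      obs <- table(droplevels(g[!is.na(y)]))
      if (length(obs) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = lid, locus = lab, trait = tr,
          genotype = names(obs) %||% NA_character_,
          class = NA_character_, n = as.integer(obs),
          ls_mean = NA_real_, se = NA_real_, letter = NA_character_,
          f_stat = NA_real_, p_value = NA_real_, testable = FALSE,
          note = "non-testable: single genotype class",
          stringsAsFactors = FALSE)
        next
      }
      fit <- suppressWarnings(fit_oneway(y, g))
      pw <- pairwise_ttests(fit, adjust = adjust)
      eligible <- fit$levels[fit$n >= min_class_n]
      lets <- stats::setNames(rep(NA_character_, length(fit$levels)),
                              fit$levels)
      if (length(eligible) >= 2L) {
        m <- stats::setNames(fit$ls_means, fit$levels)[eligible]
        lets[eligible] <- compact_letter_display(
          pw[eligible, eligible, drop = FALSE], m, alpha)
      }
      note <- if (length(eligible) < length(fit$levels))
        sprintf("class(es) with n<%d excluded from letters: %s",
                min_class_n,
                paste(setdiff(fit$levels, eligible), collapse = ","))
        else ""
      cls <- c("ref_hom", "het", "alt_hom")[match(fit$levels, levels(g))]
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = lid, locus = lab, trait = tr, genotype = fit$levels,
        class = cls, n = fit$n, ls_mean = fit$ls_means, se = fit$se,
        letter = unname(lets), f_stat = fit$f_stat,
        p_value = fit$p_value, testable = TRUE, note = note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-breed trait summary with significance letters
#'
#' For each trait: per-breed mean and sample SD (n - 1 denominator), the
#' overall F-test p-value across breeds, and compact letters from
#' pairwise LS-mean comparisons. Breeds with a single hen are reported
#' (mean only, SD missing) but excluded from pairwise letters.
#'
#' @param genotypes A [genotype_table()] supplying breed labels.
#' @param traits Trait table sharing `sample_id`.
#' @param trait_names Traits to summarize (default: all trait columns).
#' @param alpha Significance level for letters.
#' @param adjust Pairwise adjustment passed to [pairwise_ttests()].
#' @return Data frame with one row per trait x breed: `trait`, `breed`,
#'   `n`, `mean`, `sd`, `letter`, `p_value` (overall F test, repeated
#'   within trait).
#' @export
breed_summary <- function(genotypes, traits, trait_names = NULL,
                          alpha = 0.05, adjust = "none") {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.null(trait_names))
    trait_names <- setdiff(names(traits), "sample_id")
  breeds <- unique(genotypes$samples$breed)
  if (length(breeds) < 2L)
    abort("breed summary requires at least 2 breeds",
          "npyassoc_design_error")
  ord <- match(genotypes$samples$sample_id, traits$sample_id)
  breed <- factor(genotypes$samples$breed, levels = breeds)
  rows <- list()
  for (tr in trait_names) {
    y <- traits[[tr]][ord]
    fit <- suppressWarnings(fit_oneway(y, breed, level_order = breeds))
    pw <- pairwise_ttests(fit, adjust = adjust)
    eligible <- fit$levels[fit$n >= 2L]
    if (length(eligible) < length(fit$levels))
      warning(sprintf(
        "trait %s: breed(s) with n=1 excluded from letters: %s", tr,
        paste(setdiff(fit$levels, eligible), collapse = ",")),
        call. = FALSE)
    lets <- stats::setNames(rep(NA_character_, length(fit$levels)),
                            fit$levels)
    if (length(eligible) >= 2L) {
      m <- stats::setNames(fit$ls_means, fit$levels)[eligible]
      lets[eligible] <- compact_letter_display(
        pw[eligible, eligible, drop = FALSE], m, alpha)
    }
    sds <- tapply(y[!is.na(y)], droplevels(breed[!is.na(y)]), stats::sd)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, breed = fit$levels, n = fit$n,
      mean = fit$ls_means,
      sd = unname(sds[fit$levels]),
      letter = unname(lets), p_value = fit$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render an association scan as a wide report
#'
#' Reshapes [association_scan()] output into the familiar publication
#' layout: one block of rows per locus (one row per genotype class, LS
#' mean with its superscript letter) with one column per trait, plus a
#' p-value row per locus.
#'
#' @param scan Output of [association_scan()].
#' @param format `"tsv"` data frame or `"markdown"` character lines.
#' @return Data frame or character vector of markdown lines.
#' @export
format_scan_report <- function(scan, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  traits <- unique(scan$trait)
  rows <- list()
  for (lid in unique(scan$locus_id)) {
    sub <- scan[scan$locus_id == lid, ]
    for (g in unique(sub$genotype[!is.na(sub$genotype)])) {
      cells <- vapply(traits, function(tr) {
        r <- sub[sub$trait == tr & sub$genotype == g, ]
        if (!nrow(r) || !r$testable[1] || is.na(r$ls_mean[1])) return(".")
        paste0(sprintf("%.2f", round_half_up(r$ls_mean[1])),
               ifelse(is.na(r$letter[1]) | r$letter[1] == "", "",
                      paste0(" ", r$letter[1])))
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = sub$locus[1], row = g, t(cells), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
    pcells <- vapply(traits, function(tr) {
      r <- sub[sub$trait == tr, ]
      if (!nrow(r) || !any(r$testable)) return(".")
      sprintf("%.2f", round_half_up(r$p_value[r$testable][1]))
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      locus = sub$locus[1], row = "p-value", t(pcells), check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("locus", "genotype", traits)
  rownames(out) <- NULL
  if (format == "tsv") return(out)
  header <- paste(names(out), collapse = " | ")
  rule <- paste(rep("---", ncol(out)), collapse = " | ")
  body <- apply(out, 1, paste, collapse = " | ")
  c(paste("|", header, "|"), paste("|", rule, "|"), paste("|", body, "|"))
}

#' Render a breed summary as a wide report
#'
#' One row per trait, one `mean ± sd letter` column per breed, plus the
#' overall p-value.
#'
#' @param summary Output of [breed_summary()].
#' @param format `"tsv"` data frame or `"markdown"` character lines.
#' @return Data frame or character vector of markdown lines.
#' @export
format_breed_report <- function(summary, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  breeds <- unique(summary$breed)
  rows <- lapply(unique(summary$trait), function(tr) {
    sub <- summary[summary$trait == tr, ]
    cells <- vapply(breeds, function(br) {
      r <- sub[sub$breed == br, ]
      if (!nrow(r)) return(".")
      sprintf("%.2f ± %s%s", round_half_up(r$mean),
              ifelse(is.na(r$sd), "NA", sprintf("%.2f", round_half_up(r$sd))),
              ifelse(is.na(r$letter) | r$letter == "", "",
                     paste0(" ", r$letter)))
    }, character(1))
    data.frame(trait = tr, t(cells),
               p_value = sprintf("%.3g", sub$p_value[1]),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("trait", breeds, "p_value")
  rownames(out) <- NULL
  if (format == "tsv") return(out)
  header <- paste(names(out), collapse = " | ")
  rule <- paste(rep("---", ncol(out)), collapse = " | ")
  body <- apply(out, 1, paste, collapse = " | ")
  c(paste("|", header, "|"), paste("|", rule, "|"), paste("|", body, "|"))
}
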
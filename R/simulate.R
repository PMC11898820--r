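# Synthetic genotype-phenotype studies with the statistical structure
# the analysis assumes: per-breed genotype draws (Hardy-Weinberg
# proportions, optionally distorted by an inbreeding-style F, or copied
# verbatim from a published genotype-frequency table) and trait values
# generated from the fitted model's own generative mirror
# y = breed baseline + per-locus genotype value + Gaussian noise.

#' Build a simulation configuration
#'
#' @param breeds Data frame with columns `breed`, `n` (all `n >= 1`).
#' @param loci Locus definitions as from [locus_def()] / [npy_loci()].
#' @param genotype_model Per-breed, per-locus genotype law. Either
#'   frequency mode — columns `locus_id`, `breed`, `f_refref`,
#'   `f_refalt`, `f_altalt` (non-negative, summing to 1) — or p/F mode —
#'   columns `locus_id`, `breed`, `p` (ref-allele frequency in (0, 1))
#'   and `F` (inbreeding-style Hardy-Weinberg deviation; genotype
#'   probabilities `(p^2 + Fpq, 2pq(1 - F), q^2 + Fpq)` must be
#'   non-negative, i.e. `F >= -min(p, q)/max(p, q)`).
#' @param trait_params Data frame `trait`, `breed`, `mean`, `sd`:
#'   per-breed baseline mean and noise SD per trait.
#' @param effects Optional data frame `locus_id`, `trait`, `a`, `d`:
#'   additive allele effect `a` and dominance effect `d`, giving
#'   genotype values `-a` / `d` / `+a` for ref-hom / het / alt-hom.
#'   Default: no genotype effects (a null study).
#' @param seed Integer global seed; every draw derives a reproducible
#'   substream from it via [derive_seed()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(breeds, loci, genotype_model, trait_params,
                       effects = NULL, seed = 1L) {
  stopifnot(all(c("breed", "n") %in% names(breeds)),
            all(breeds$n >= 1L))
  freq_mode <- all(c("f_refref", "f_refalt", "f_altalt") %in%
                     names(genotype_model))
  if (!freq_mode && !all(c("p", "F") %in% names(genotype_model)))
    abort("genotype_model needs columns f_refref/f_refalt/f_altalt or p/F",
          "npyassoc_config_error")
  for (i in seq_len(nrow(genotype_model))) {
    gm <- genotype_model[i, ]
    probs <- genotype_probs(gm, freq_mode)
    if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-8)
      abort(sprintf(
        "locus %s breed %s: genotype probabilities invalid (%s)",
        gm$locus_id, gm$breed, paste(signif(probs, 4), collapse = ", ")),
        "npyassoc_config_error")
    if (!freq_mode && (gm$p <= 0 || gm$p >= 1))
      abort(sprintf("locus %s breed %s: p must lie in (0,1)",
                    gm$locus_id, gm$breed),
            "npyassoc_config_error")
  }
  if (is.null(effects))
    effects <- data.frame(locus_id = character(0), trait = character(0),
                          a = numeric(0), d = numeric(0),
                          stringsAsFactors = FALSE)
  structure(list(breeds = breeds, loci = loci,
                 genotype_model = genotype_model, freq_mode = freq_mode,
                 trait_params = trait_params, effects = effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# genotype class probabilities (ref-hom, het, alt-hom) for one model row
genotype_probs <- function(gm, freq_mode) {
  if (freq_mode) {
    c(gm$f_refref, gm$f_refalt, gm$f_altalt)
  } else {
    p <- gm$p; q <- 1 - p; F <- gm$F
    c(p^2 + F * p * q, 2 * p * q * (1 - F), q^2 + F * p * q)
  }
}

#' Default configuration: the four-breed NPY laying-hen study
#'
#' Reproduces the published study's dimensions and structure: 117 hens
#' in four breeds (PH 59, C 20, BB 20, LC 18), the seven NPY
#' coding-region SNPs with per-breed genotype frequencies equal to the
#' published counts (frequency mode, so Hardy-Weinberg deviations are
#' carried over), and the eight egg-production traits at the published
#' per-breed means and SDs. Genotype effects default to zero (null
#' study).
#'
#' @param seed Integer global seed.
#' @param effects Optional effects table (see [sim_config()]).
#' @param hwe_f If non-`NULL`, switch to p/F mode: a single inbreeding
#'   coefficient applied to every breed x locus, with `p` taken from the
#'   published counts by gene counting. `hwe_f = 0` gives exact
#'   Hardy-Weinberg proportions.
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, effects = NULL, hwe_f = NULL) {
  sizes <- npy_breed_sizes()
  breeds <- data.frame(breed = names(sizes), n = as.integer(sizes),
                       stringsAsFactors = FALSE)
  cnt <- npy_genotype_counts()
  n <- cnt$n_refref + cnt$n_refalt + cnt$n_altalt
  if (is.null(hwe_f)) {
    gm <- data.frame(locus_id = cnt$locus_id, breed = cnt$breed,
                     f_refref = cnt$n_refref / n,
                     f_refalt = cnt$n_refalt / n,
                     f_altalt = cnt$n_altalt / n,
                     stringsAsFactors = FALSE)
  } else {
    gm <- data.frame(locus_id = cnt$locus_id, breed = cnt$breed,
                     p = (2 * cnt$n_refref + cnt$n_refalt) / (2 * n),
                     F = hwe_f, stringsAsFactors = FALSE)
  }
  sim_config(breeds, npy_loci(), gm, npy_trait_params(),
             effects = effects, seed = seed)
}

#' Null-calibration configuration
#'
#' A variant of [default_sim_config()] under which the pooled one-way
#' genotype scan is exactly null: genotype structure (breeds, loci,
#' per-breed genotype frequencies) is unchanged, but trait baselines are
#' homogeneous across breeds (every breed uses the PH row of the
#' published trait summary) and genotype effects are zero. Because the
#' default study couples trait baselines and genotype frequencies to
#' breed, breed confounds the pooled genotype model there; with
#' homogeneous baselines trait and genotype are independent, so the
#' F test's type-I error can be measured against its nominal level.
#'
#' @param seed Integer global seed.
#' @param effects Optional effects table, e.g. for power studies on an
#'   otherwise-null background.
#' @return A [sim_config()].
#' @export
null_calibration_config <- function(seed = 1L, effects = NULL) {
  cfg <- default_sim_config(seed = seed, effects = effects)
  tp <- cfg$trait_params
  ph <- tp[tp$breed == "PH", c("trait", "mean", "sd")]
  cfg$trait_params <- do.call(rbind, lapply(unique(tp$breed), function(br)
    data.frame(trait = ph$trait, breed = br, mean = ph$mean, sd = ph$sd,
               stringsAsFactors = FALSE)))
  cfg
}

#' Simulate genotypes
#'
#' Per breed and locus, genotype classes are drawn independently from
#' the configured genotype law, on a substream derived from the global
#' seed and the (breed, locus) labels — so adding loci or breeds never
#' perturbs the draws of existing streams, and identical configurations
#' give identical tables.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_table()] with `sum(cfg$breeds$n)` samples.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- do.call(rbind, lapply(seq_len(nrow(cfg$breeds)), function(b) {
    br <- cfg$breeds$breed[b]; nb <- cfg$breeds$n[b]
    df <- data.frame(sample_id = sprintf("%s_%03d", br, seq_len(nb)),
                     breed = br, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cfg$loci))) {
      l <- cfg$loci[i, ]
      gm <- cfg$genotype_model[cfg$genotype_model$locus_id == l$locus_id &
                                 cfg$genotype_model$breed == br, ]
      if (nrow(gm) != 1L)
        abort(sprintf("no genotype model for breed %s locus %s",
                      br, l$locus_id), "npyassoc_config_error")
      probs <- pmax(genotype_probs(gm, cfg$freq_mode), 0)
      calls <- c(paste0(l$ref, l$ref),
                 paste(sort(c(l$ref, l$alt)), collapse = ""),
                 paste0(l$alt, l$alt))
      set.seed(derive_seed(cfg$seed, "geno", br, l$locus_id))
      df[[l$locus_id]] <- calls[sample.int(3L, nb, replace = TRUE,
                                           prob = probs)]
    }
    df
  }))
  genotype_table(samples, cfg$loci)
}

#' Simulate phenotypes
#'
#' Trait value = breed baseline mean + sum over loci of the genotype
#' value (`-a`, `d`, `+a` for ref-hom / het / alt-hom; missing genotype
#' contributes 0) + Gaussian noise with the breed-specific SD, truncated
#' at 0 (traits are counts, weights, ages). Noise streams are derived
#' per (breed, trait).
#'
#' @param genotypes A [genotype_table()] (typically from
#'   [simulate_genotypes()]).
#' @param cfg The same [sim_config()].
#' @return List with `traits` (trait table data frame) and `truth`
#'   (list: the config, plus per-sample latent genetic values per trait).
#' @export
simulate_phenotypes <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genotypes, "genotype_table"))
  unknown <- setdiff(unique(genotypes$samples$breed), cfg$breeds$breed)
  if (length(unknown))
    abort(sprintf("breed(s) %s not in simulation config",
                  paste(unknown, collapse = ", ")),
          "npyassoc_config_error")
  traits <- unique(cfg$trait_params$trait)
  out <- data.frame(sample_id = genotypes$samples$sample_id,
                    stringsAsFactors = FALSE)
  genetic <- out
  # per-sample genetic value per trait from the configured locus effects
  for (tr in traits) {
    gval <- numeric(nrow(out))
    eff <- cfg$effects[cfg$effects$trait == tr, , drop = FALSE]
    if (nrow(eff)) {
      for (i in seq_len(nrow(eff))) {
        cls <- genotype_class(
          genotypes$samples[[eff$locus_id[i]]],
          cfg$loci$ref[cfg$loci$locus_id == eff$locus_id[i]],
          cfg$loci$alt[cfg$loci$locus_id == eff$locus_id[i]])
        val <- c(ref_hom = -eff$a[i], het = eff$d[i], alt_hom = eff$a[i])
        gval <- gval + ifelse(is.na(cls), 0, val[cls])
      }
    }
    genetic[[tr]] <- gval
  }
  for (tr in traits) {
    v <- numeric(nrow(out))
    for (br in unique(genotypes$samples$breed)) {
      idx <- which(genotypes$samples$breed == br)
      tp <- cfg$trait_params[cfg$trait_params$trait == tr &
                               cfg$trait_params$breed == br, ]
      if (nrow(tp) != 1L)
        abort(sprintf("no trait parameters for breed %s trait %s", br, tr),
              "npyassoc_config_error")
      set.seed(derive_seed(cfg$seed, "trait", br, tr))
      v[idx] <- tp$mean + genetic[[tr]][idx] +
        stats::rnorm(length(idx), 0, tp$sd)
    }
    out[[tr]] <- pmax(v, 0)
  }
  class(out) <- c("trait_table", "data.frame")
  list(traits = out, truth = list(config = cfg, genetic_values = genetic))
}

#' Generate a complete study on disk
#'
#' Simulates genotypes and phenotypes and writes four files into
#' `outdir`: `genotypes.tsv`, `traits.tsv`, `truth.tsv` (per-sample
#' latent genetic values) and `config.yaml` (the effective configuration
#' echo). Outputs are byte-identical for identical configurations.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the simulated `genotypes`, `traits`,
#'   `truth` and the written `paths`.
#' @export
generate_study <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  paths <- list(
    genotypes = file.path(outdir, "genotypes.tsv"),
    traits = file.path(outdir, "traits.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    config = file.path(outdir, "config.yaml"))
  write_genotype_table(gt, paths$genotypes)
  write_trait_table(ph$traits, paths$traits)
  write_tsv(ph$truth$genetic_values, paths$truth)
  yaml::write_yaml(sim_config_as_list(cfg), paths$config)
  invisible(list(genotypes = gt, traits = ph$traits, truth = ph$truth,
                 paths = paths))
}

# plain-list view of a sim_config for the YAML configuration echo
sim_config_as_list <- function(cfg) {
  list(seed = cfg$seed,
       breeds = as.list(stats::setNames(cfg$breeds$n, cfg$breeds$breed)),
       loci = lapply(seq_len(nrow(cfg$loci)), function(i)
         as.list(cfg$loci[i, ])),
       genotype_model_mode = if (cfg$freq_mode) "frequencies" else "p_F",
       genotype_model = lapply(seq_len(nrow(cfg$genotype_model)), function(i)
         as.list(cfg$genotype_model[i, ])),
       trait_params = lapply(seq_len(nrow(cfg$trait_params)), function(i)
         as.list(cfg$trait_params[i, ])),
       effects = if (nrow(cfg$effects))
         lapply(seq_len(nrow(cfg$effects)), function(i)
           as.list(cfg$effects[i, ])) else list())
}
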
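test_that("identical configurations give identical studies on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(default_sim_config(seed = 7), d1)
  generate_study(default_sim_config(seed = 7), d2)
  for (f in c("genotypes.tsv", "traits.tsv", "truth.tsv", "config.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  d3 <- withr::local_tempdir()
  generate_study(default_sim_config(seed = 8), d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.tsv")),
                         readLines(file.path(d3, "genotypes.tsv"))))
})

test_that("the default study reproduces the published dimensions", {
  cfg <- default_sim_config(seed = 1)
  gt <- simulate_genotypes(cfg)
  expect_identical(nrow(gt$samples), 117L)
  expect_identical(nrow(gt$loci), 7L)
  expect_identical(breed_counts(gt),
                   c(BB = 20L, C = 20L, LC = 18L, PH = 59L))
  ph <- simulate_phenotypes(gt, cfg)
  expect_identical(setdiff(names(ph$traits), "sample_id"),
                   trait_definitions()$trait)
  expect_true(all(ph$traits[, -1] >= 0))
  # pipeline closure: downstream stages run without error
  expect_silent(div <- diversity_table(gt))
  expect_identical(nrow(div), 35L)
  scan <- association_scan(gt, ph$traits)
  expect_identical(length(unique(paste(scan$locus_id, scan$trait))), 56L)
})

test_that("genotype draws follow the configured law", {
  # F = 1: no heterozygotes can be produced
  cfg1 <- sim_config(
    breeds = data.frame(breed = "X", n = 400L),
    loci = npy_loci()[1, ],
    genotype_model = data.frame(locus_id = "SNP1", breed = "X",
                                p = 0.4, F = 1),
    trait_params = data.frame(trait = "AFEP", breed = "X",
                              mean = 150, sd = 10),
    seed = 5)
  gt1 <- simulate_genotypes(cfg1)
  expect_false(any(is_heterozygote(gt1$samples$SNP1)))

  # F = 0, p = 0.5, n = 10000: heterozygote fraction near 1/2
  cfg0 <- sim_config(
    breeds = data.frame(breed = "X", n = 10000L),
    loci = npy_loci()[1, ],
    genotype_model = data.frame(locus_id = "SNP1", breed = "X",
                                p = 0.5, F = 0),
    trait_params = data.frame(trait = "AFEP", breed = "X",
                              mean = 150, sd = 10),
    seed = 6)
  gt0 <- simulate_genotypes(cfg0)
  het <- mean(is_heterozygote(gt0$samples$SNP1))
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
  # empirical allele frequency near p
  cnt <- genotype_counts(gt0, "SNP1", "All")
  expect_lt(abs(allele_frequencies(cnt)$p - 0.5),
            3 * sqrt(0.25 / (2 * 10000)))
})

test_that("draws match a same-stream multinomial oracle", {
  cfg <- default_sim_config(seed = 13)
  gt <- simulate_genotypes(cfg)
  l <- cfg$loci[cfg$loci$locus_id == "SNP1", ]
  gm <- cfg$genotype_model[cfg$genotype_model$locus_id == "SNP1" &
                            cfg$genotype_model$breed == "PH", ]
  calls <- c("AA", "AG", "GG")
  probs <- c(gm$f_refref, gm$f_refalt, gm$f_altalt)
  set.seed(derive_seed(13, "geno", "PH", "SNP1"))
  expected <- calls[sample.int(3L, 59L, replace = TRUE, prob = probs)]
  expect_identical(gt$samples$SNP1[gt$samples$breed == "PH"], expected)
})

test_that("substreams isolate loci from one another", {
  cfg_full <- default_sim_config(seed = 17)
  cfg_sub <- cfg_full
  cfg_sub$loci <- cfg_full$loci[1:3, ]
  gt_full <- simulate_genotypes(cfg_full)
  gt_sub <- simulate_genotypes(cfg_sub)
  for (lid in cfg_sub$loci$locus_id)
    expect_identical(gt_sub$samples[[lid]], gt_full$samples[[lid]])
})

test_that("phenotypes follow the generative model exactly at zero noise", {
  cfg <- default_sim_config(seed = 19)
  cfg$trait_params$sd <- 0
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  tp <- cfg$trait_params
  for (tr in c("AFEP", "EMs")) {
    expected <- tp$mean[tp$trait == tr][
      match(gt$samples$breed, tp$breed[tp$trait == tr])]
    expect_equal(ph$traits[[tr]], expected)
  }
  expect_true(all(ph$truth$genetic_values[, -1] == 0))
})

test_that("an additive locus effect is recovered by the fitted model", {
  cfg <- sim_config(
    breeds = data.frame(breed = "X", n = 300L),
    loci = npy_loci()[3, ],                # SNP3, balanced frequencies
    genotype_model = data.frame(locus_id = "SNP3", breed = "X",
                                p = 0.5, F = 0),
    trait_params = data.frame(trait = "EW_9M", breed = "X",
                              mean = 45, sd = 5),
    effects = data.frame(locus_id = "SNP3", trait = "EW_9M",
                         a = 5, d = 0),
    seed = 23)
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  fit <- fit_oneway(ph$traits$EW_9M, locus_factor(gt, "SNP3"))
  hom_diff <- fit$ls_means[fit$levels == "AA"] -
    fit$ls_means[fit$levels == "GG"]
  se <- sqrt(fit$se[fit$levels == "AA"]^2 + fit$se[fit$levels == "GG"]^2)
  expect_lt(abs(hom_diff - 10), 3 * se)
  # truth file records the per-sample genetic values
  cls <- ph$truth$genetic_values$EW_9M
  expect_setequal(unique(cls), c(-5, 0, 5))
})

test_that("invalid configurations are rejected", {
  base <- list(
    breeds = data.frame(breed = "X", n = 10L),
    loci = npy_loci()[1, ],
    trait_params = data.frame(trait = "AFEP", breed = "X",
                              mean = 150, sd = 10))
  # (p, F) giving a negative genotype probability
  expect_error(
    sim_config(base$breeds, base$loci,
               data.frame(locus_id = "SNP1", breed = "X", p = 0.9, F = -0.5),
               base$trait_params),
    class = "npyassoc_config_error")
  # frequencies that do not sum to 1
  expect_error(
    sim_config(base$breeds, base$loci,
               data.frame(locus_id = "SNP1", breed = "X", f_refref = 0.5,
                          f_refalt = 0.4, f_altalt = 0.4),
               base$trait_params),
    class = "npyassoc_config_error")
  # unknown breed at phenotype time
  cfg <- sim_config(base$breeds, base$loci,
                    data.frame(locus_id = "SNP1", breed = "X",
                               p = 0.5, F = 0),
                    base$trait_params)
  gt <- simulate_genotypes(cfg)
  gt$samples$breed <- "Y"
  expect_error(simulate_phenotypes(gt, cfg),
               class = "npyassoc_config_error")
})

test_that("the inbreeding-style F is recovered from large samples", {
  cfg <- sim_config(
    breeds = data.frame(breed = "X", n = 20000L),
    loci = npy_loci()[1, ],
    genotype_model = data.frame(locus_id = "SNP1", breed = "X",
                                p = 0.6, F = 0.3),
    trait_params = data.frame(trait = "AFEP", breed = "X",
                              mean = 150, sd = 10),
    seed = 29)
  gt <- simulate_genotypes(cfg)
  cnt <- genotype_counts(gt, "SNP1", "All")
  fr <- allele_frequencies(cnt)
  f_hat <- 1 - (cnt$n_refalt / cnt$n) / (2 * fr$p * fr$q)
  expect_lt(abs(f_hat - 0.3), 0.03)
})
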
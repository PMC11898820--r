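test_that("the one-way engine matches brute-force least squares", {
  for (seed in 1:60) {
    d <- random_design(seed)
    fit <- fit_oneway(d$y, d$group, d$covariate)
    oracle <- oracle_oneway(d$y, d$group, d$covariate)
    expect_equal(fit$ls_means, oracle$ls_means, tolerance = 1e-10)
    expect_equal(fit$f_stat, oracle$f_stat, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)
    expect_equal(fit$residual_variance, oracle$sigma2, tolerance = 1e-10)
    expect_identical(fit$df_error, as.integer(oracle$df_error))
  }
})

test_that("without a covariate LS means are arithmetic group means", {
  set.seed(3)
  y <- rnorm(40)
  g <- sample(c("a", "b", "c"), 40, replace = TRUE)
  fit <- fit_oneway(y, g)
  expect_equal(fit$ls_means,
               as.numeric(tapply(y, g, mean)[fit$levels]),
               tolerance = 1e-12)
})

test_that("F is invariant to shifts and positive rescaling of y", {
  set.seed(4)
  y <- rnorm(30, 5)
  g <- rep(c("a", "b", "c"), each = 10)
  f0 <- fit_oneway(y, g)$f_stat
  expect_equal(fit_oneway(y + 100, g)$f_stat, f0, tolerance = 1e-9)
  expect_equal(fit_oneway(y * 7.5, g)$f_stat, f0, tolerance = 1e-9)
})

test_that("balanced two-group F equals the squared pooled t statistic", {
  set.seed(5)
  y <- rnorm(24)
  g <- rep(c("a", "b"), each = 12)
  fit <- fit_oneway(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(fit$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical group means give F = 0 and a shared letter", {
  y <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- fit_oneway(y, g)
  expect_equal(fit$f_stat, 0)
  pw <- pairwise_ttests(fit)
  lets <- compact_letter_display(pw, setNames(fit$ls_means, fit$levels))
  expect_identical(unname(lets), c("a", "a", "a"))
})

test_that("degenerate designs raise design errors", {
  expect_error(fit_oneway(c(1, 2, 3), c("a", "a", "a")),
               class = "npyassoc_design_error")
  expect_error(fit_oneway(c(1, 2), c("a", "b")),
               class = "npyassoc_design_error")   # zero residual df
  expect_warning(
    fit_oneway(c(1, 2, 3, 4), c("a", "a", "b", "b"),
               level_order = c("a", "b", "c")),
    "empty factor level")
})

test_that("pairwise tests are symmetric with exact-null p = 1", {
  y <- c(1, 2, 3, 1, 2, 3, 5, 6, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- fit_oneway(y, g)
  pw <- pairwise_ttests(fit)
  expect_identical(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(1, 3))
  expect_equal(pw["a", "b"], 1)           # identical groups, difference 0
  expect_lt(pw["a", "c"], pw["a", "b"])
})

test_that("a group shifted by 5 SE separates from the others", {
  hits <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 10
    se <- sqrt(2 / n)                      # SE of a difference at sigma = 1
    y <- c(rnorm(n), rnorm(n), rnorm(n, mean = 5 * se))
    g <- rep(c("a", "b", "c"), each = n)
    fit <- fit_oneway(y, g)
    pw <- pairwise_ttests(fit)
    if (pw["c", "a"] < 0.05 && pw["c", "b"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.9)
})

test_that("adjustment methods order p-values as expected", {
  set.seed(8)
  y <- rnorm(30, rep(c(0, 0.5, 1.5), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  fit <- fit_oneway(y, g)
  p_none <- pairwise_ttests(fit, "none")
  p_bonf <- pairwise_ttests(fit, "bonferroni")
  p_tuk <- pairwise_ttests(fit, "tukey")
  off <- upper.tri(p_none)
  expect_true(all(p_bonf[off] >= p_none[off]))
  expect_true(all(p_tuk[off] >= p_none[off]))
  expect_true(all(p_bonf[off] <= 1))
})

test_that("letter displays encode the pairwise structure", {
  # all pairs significant: four distinct letters in descending-mean order
  p_all <- matrix(0.001, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(p_all) <- 1
  means <- c(a = 188.05, b = 170.60, c = 151.89, d = 140.44)
  expect_identical(unname(compact_letter_display(p_all, means)),
                   c("a", "b", "c", "d"))

  # chain case A != C, A ~ B, B ~ C -> "a", "ab", "b"
  p_chain <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3,
                    dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- c(A = 3, B = 2, C = 1)
  expect_identical(unname(compact_letter_display(p_chain, m)),
                   c("a", "ab", "b"))

  # property check over random pairwise structures
  for (seed in 1:40) {
    set.seed(seed)
    k <- sample(3:5, 1)
    pm <- matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k]))
    pm[upper.tri(pm)] <- runif(k * (k - 1) / 2)
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    mns <- setNames(sort(rnorm(k), decreasing = TRUE), letters[1:k])
    lets <- compact_letter_display(pm, mns)
    expect_true(letters_encode(lets, pm))
  }
})

test_that("Levene's test matches car's Brown-Forsythe implementation", {
  for (seed in 1:10) {
    set.seed(seed)
    y <- rnorm(60, sd = rep(c(1, 1, 3), each = 20))
    g <- factor(rep(c("a", "b", "c"), each = 20))
    mine <- levene_test(y, g)
    ref <- car::leveneTest(y, g, center = stats::median)
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # mirrored dispersion: statistic exactly 0
  y <- c(1, 2, 3, 11, 12, 13)
  expect_equal(levene_test(y, rep(c("a", "b"), each = 3))$statistic, 0)
})

test_that("Levene's test is calibrated and has power against scale shifts", {
  rej <- 0
  for (rep in 1:400) {
    set.seed(3000 + rep)
    y <- rnorm(200)
    g <- rep(c("a", "b"), each = 100)
    if (levene_test(y, g)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.08)

  hits <- 0
  for (rep in 1:100) {
    set.seed(4000 + rep)
    y <- c(rnorm(50), rnorm(50, sd = 5))
    g <- rep(c("a", "b"), each = 50)
    if (levene_test(y, g)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("the association scan covers every locus x trait cell", {
  cfg <- default_sim_config(seed = 21)
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  scan <- association_scan(gt, ph$traits)
  expect_identical(length(unique(paste(scan$locus_id, scan$trait))), 56L)
  expect_true(all(scan$testable))
  # every testable cell has three genotype rows with letters
  s1 <- scan[scan$locus_id == "SNP1" & scan$trait == "AFEP", ]
  expect_identical(nrow(s1), 3L)
  expect_false(any(is.na(s1$letter)))
  expect_error(association_scan(gt, ph$traits, trait_names = "nope"),
               class = "npyassoc_format_error")
})

test_that("sparse genotype classes are kept in the fit, not the letters", {
  set.seed(9)
  gt <- genotype_table(
    data.frame(sample_id = sprintf("h%02d", 1:21), breed = "PH",
               SNP1 = c(rep("AA", 10), rep("AG", 10), "GG"),
               stringsAsFactors = FALSE),
    locus_def("SNP1", 130, "A", "G"))
  traits <- data.frame(sample_id = gt$samples$sample_id,
                       AFEP = rnorm(21, 150, 5))
  scan <- association_scan(gt, traits)
  gg <- scan[scan$genotype == "GG", ]
  expect_true(is.na(gg$letter))
  expect_false(is.na(gg$ls_mean))
  expect_match(gg$note, "excluded from letters")
  # single observed class -> non-testable
  mono <- genotype_table(
    data.frame(sample_id = c("h1", "h2", "h3"), breed = "PH", SNP1 = "AA",
               stringsAsFactors = FALSE),
    locus_def("SNP1", 130, "A", "G"))
  tmono <- data.frame(sample_id = mono$samples$sample_id, AFEP = c(1, 2, 3))
  sc <- association_scan(mono, tmono)
  expect_false(any(sc$testable))
  expect_match(sc$note[1], "non-testable")
})

test_that("breed summaries report means, SDs and letters per trait", {
  cfg <- default_sim_config(seed = 31)
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  bs <- breed_summary(gt, ph$traits)
  expect_identical(nrow(bs), 32L)          # 8 traits x 4 breeds
  expect_true(all(bs$sd > 0))
  # breed SD uses the n-1 denominator
  afep_ph <- ph$traits$AFEP[gt$samples$breed == "PH"]
  expect_equal(bs$sd[bs$trait == "AFEP" & bs$breed == "PH"],
               sd(afep_ph), tolerance = 1e-12)

  single <- gt
  single$samples <- single$samples[single$samples$breed == "PH", ]
  expect_error(breed_summary(single, ph$traits),
               class = "npyassoc_design_error")
})

test_that("a one-hen breed keeps its mean but loses SD and letter", {
  set.seed(10)
  gt <- genotype_table(
    data.frame(sample_id = sprintf("h%02d", 1:13),
               breed = c(rep("PH", 6), rep("C", 6), "BB"),
               SNP1 = "AA", stringsAsFactors = FALSE),
    locus_def("SNP1", 130, "A", "G"))
  traits <- data.frame(sample_id = gt$samples$sample_id,
                       AFEP = rnorm(13, 150, 5))
  expect_warning(bs <- breed_summary(gt, traits), "n=1")
  bb <- bs[bs$breed == "BB", ]
  expect_false(is.na(bb$mean))
  expect_true(is.na(bb$sd))
  expect_true(is.na(bb$letter))
})

test_that("the outlier filter removes only extreme within-breed values", {
  set.seed(11)
  gt <- genotype_table(
    data.frame(sample_id = sprintf("h%02d", 1:20),
               breed = rep(c("PH", "C"), each = 10),
               SNP1 = "AA", stringsAsFactors = FALSE),
    locus_def("SNP1", 130, "A", "G"))
  traits <- data.frame(sample_id = gt$samples$sample_id,
                       AFEP = c(rnorm(9, 150, 2), 400, rnorm(10, 180, 2)))
  expect_message(out <- filter_outliers(traits, gt), "removed 1")
  expect_true(is.na(out$AFEP[10]))
  expect_identical(attr(out, "removed")$sample_id, "h10")
  expect_identical(sum(is.na(out$AFEP)), 1L)
})

test_that("wide reports carry one column per trait and p-value rows", {
  cfg <- default_sim_config(seed = 41)
  gt <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(gt, cfg)
  scan <- association_scan(gt, ph$traits)
  wide <- format_scan_report(scan)
  expect_identical(ncol(wide), 10L)        # locus, genotype, 8 traits
  expect_identical(sum(wide$genotype == "p-value"), 7L)
  bs <- breed_summary(gt, ph$traits)
  wb <- format_breed_report(bs)
  expect_identical(dim(wb), c(8L, 6L))     # 8 traits; 4 breeds + 2
  expect_true(all(grepl("±", wb$PH)))
})
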
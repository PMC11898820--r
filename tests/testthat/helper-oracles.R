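# Independent oracles and fixture builders shared across tests. The
# oracles deliberately use different code paths from the package:
# explicit normal equations with matrix inversion for least squares,
# first-principles arithmetic for the chi-square, and exhaustive
# checking for letter displays.

# brute-force one-way least squares: uncentered design, explicit
# inversion of the normal equations
oracle_oneway <- function(y, group, covariate = NULL) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  X <- sapply(levels(group), function(l) as.numeric(group == l))
  if (!is.null(covariate)) X <- cbind(X, covariate)
  XtX <- t(X) %*% X
  beta <- solve(XtX) %*% t(X) %*% y
  resid <- y - X %*% beta
  df_error <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df_error
  ls_means <- beta[seq_len(k)]
  if (!is.null(covariate)) ls_means <- ls_means + beta[k + 1] * mean(covariate)
  # F for the group factor: reduced model with common intercept
  X0 <- matrix(1, length(y), 1)
  if (!is.null(covariate)) X0 <- cbind(X0, covariate)
  beta0 <- solve(t(X0) %*% X0) %*% t(X0) %*% y
  rss0 <- sum((y - X0 %*% beta0)^2)
  f <- ((rss0 - sum(resid^2)) / (k - 1)) / sigma2
  list(ls_means = as.numeric(ls_means), f_stat = f,
       p_value = stats::pf(f, k - 1, df_error, lower.tail = FALSE),
       sigma2 = sigma2, df_error = df_error)
}

# first-principles Hardy-Weinberg chi-square from three genotype counts
oracle_hwe_chi2 <- function(a, h, b) {
  n <- a + h + b
  p <- (2 * a + h) / (2 * n)
  q <- 1 - p
  e <- c(p * p * n, 2 * p * q * n, q * q * n)
  o <- c(a, h, b)
  sum((o - e)^2 / e)
}

# random small one-way design: 2-4 groups, 6-60 samples, balanced or
# unbalanced, optionally with a covariate
random_design <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  balanced <- runif(1) < 0.5
  sizes <- if (balanced) rep(sample(3:15, 1), k) else sample(2:15, k,
                                                            replace = TRUE)
  n <- sum(sizes)
  group <- rep(letters[seq_len(k)], times = sizes)
  y <- stats::rnorm(n, mean = rep(stats::rnorm(k, 10, 3), times = sizes))
  covariate <- if (runif(1) < 0.5) stats::rnorm(n) else NULL
  list(y = y, group = group, covariate = covariate)
}

# does a letter assignment encode a pairwise p matrix correctly?
# every non-significant pair must share >= 1 letter, every significant
# pair none
letters_encode <- function(lets, pmat, alpha = 0.05) {
  lv <- names(lets)
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (i >= j) next
      share <- length(intersect(strsplit(lets[i], "")[[1]],
                                strsplit(lets[j], "")[[1]])) > 0
      if (pmat[lv[i], lv[j]] >= alpha && !share) return(FALSE)
      if (pmat[lv[i], lv[j]] < alpha && share) return(FALSE)
    }
  }
  TRUE
}

# three-sample toy genotype table over two loci
toy_genotype_table <- function() {
  loci <- rbind(locus_def("SNP1", 130, "A", "G"),
                locus_def("SNP2", 301, "C", "T"))
  samples <- data.frame(
    sample_id = c("h1", "h2", "h3"),
    breed = c("PH", "PH", "C"),
    SNP1 = c("AA", "GA", "GG"),    # "GA" must normalize to "AG"
    SNP2 = c("CC", "CT", "."),
    stringsAsFactors = FALSE)
  genotype_table(samples, loci)
}

# published per-breed diversity statistics (allele frequencies, PIC,
# expected heterozygosity, HWE chi-square) for the NPY study, keyed by
# locus and population; used to check exact recomputation from counts
published_diversity <- function() {
  txt <- "
locus_id population p q pic he chi2
SNP1 PH 0.76 0.24 0.30 0.36 23.08
SNP1 C  0.82 0.175 0.25 0.29 0.36
SNP1 BB 0.80 0.20 0.27 0.32 9.45
SNP1 LC 0.67 0.33 0.35 0.44 10.13
SNP1 All 0.76 0.24 0.29 0.36 41.55
SNP2 PH 0.69 0.31 0.34 0.43 30.96
SNP2 C  0.68 0.32 0.34 0.44 0.82
SNP2 BB 0.68 0.32 0.34 0.44 15.70
SNP2 LC 0.81 0.19 0.26 0.31 12.18
SNP2 All 0.70 0.30 0.33 0.42 53.13
SNP3 PH 0.53 0.47 0.37 0.50 28.38
SNP3 C  0.52 0.48 0.37 0.50 1.78
SNP3 BB 0.40 0.60 0.36 0.48 12.53
SNP3 LC 0.56 0.44 0.37 0.49 5.45
SNP3 All 0.51 0.49 0.37 0.50 45.51
SNP4 PH 0.54 0.46 0.37 0.50 30.35
SNP4 C  0.78 0.23 0.29 0.35 6.50
SNP4 BB 0.70 0.30 0.33 0.42 11.61
SNP4 LC 0.67 0.33 0.35 0.44 4.50
SNP4 All 0.63 0.37 0.36 0.47 74.64
SNP5 PH 0.47 0.53 0.37 0.50 40.62
SNP5 C  0.47 0.53 0.37 0.50 1.78
SNP5 BB 0.52 0.48 0.37 0.50 9.78
SNP5 LC 0.36 0.64 0.35 0.46 2.85
SNP5 All 0.46 0.54 0.50 0.50 50.36
SNP6 PH 0.45 0.55 0.37 0.49 22.92
SNP6 C  0.30 0.70 0.33 0.42 0.05
SNP6 BB 0.15 0.85 0.22 0.26 0.93
SNP6 LC 0.61 0.39 0.36 0.48 5.10
SNP6 All 0.40 0.60 0.36 0.48 31.42
SNP7 PH 0.69 0.31 0.33 0.42 11.44
SNP7 C  0.75 0.25 0.30 0.38 4.36
SNP7 BB 0.82 0.18 0.25 0.29 0.36
SNP7 LC 0.75 0.25 0.30 0.38 0.02
SNP7 All 0.74 0.26 0.31 0.39 13.66
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}
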
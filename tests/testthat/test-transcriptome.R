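# Gene filtering, normalization, the per-gene sex x genotype model with its
# thresholds, fold-change and module-correlation layers, and the chimeric
# reference builder.

test_that("gene filtering removes genes with zeros in more than 75% of samples", {
  n <- 72
  counts <- rbind(
    over = c(rep(0, 55), rep(3, n - 55)),   # 55/72 = 76.4% zero -> removed
    at = c(rep(0, 54), rep(3, n - 54)),     # exactly 75% -> kept
    none = rep(2, n)
  )
  keep <- filter_genes(counts)
  expect_false(keep[["over"]])
  expect_true(keep[["at"]])
  expect_true(keep[["none"]])
})

test_that("upper-quantile normalization removes per-sample scale", {
  set.seed(1)
  a <- matrix(rexp(200, 0.1), 100, 2, dimnames = list(paste0("g", 1:100), NULL))
  a[, 2] <- a[, 1]
  out <- uq_normalize_log(a)
  expect_equal(out[, 1], out[, 2])
  b <- cbind(a[, 1], 2 * a[, 1])
  out_b <- uq_normalize_log(b)
  expect_equal(out_b[, 1], out_b[, 2])
  const <- matrix(4, 10, 3)
  expect_equal(uq_normalize_log(const), log2(const + 1))
  expect_error(uq_normalize_log(cbind(a[, 1], 0)), "all-zero")
  # order stability: permuting samples permutes the output identically
  m <- matrix(rexp(500, 0.1), 50, 10)
  perm <- sample(10)
  expect_equal(uq_normalize_log(m)[, perm], uq_normalize_log(m[, perm]))
})

test_that("per-gene OLS matches lm and the normal-equations oracle", {
  # 4-sample toy design: exact interpolation, zero residual
  design4 <- data.frame(sex = c("M", "F", "M", "F"),
                        genotype = c("WT", "WT", "TG", "TG"))
  y <- matrix(c(1, 2, 4, 8), 1, 4, dimnames = list("g1", NULL))
  res <- fit_glm_per_gene(y, design4)
  X <- cbind(1, c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 0, 0, 1))
  want <- oracle_ols(as.numeric(y), X)
  expect_equal(unlist(res[1, c("beta0", "beta1", "beta2", "beta12")]),
               want, tolerance = 1e-12, ignore_attr = TRUE)
  # random data: agree with stats::lm per gene
  set.seed(5)
  d <- gen_study_design(3)
  sel <- d$age_months == 6
  Y <- matrix(rnorm(5 * sum(sel)), 5, sum(sel),
              dimnames = list(paste0("g", 1:5), NULL))
  res2 <- fit_glm_per_gene(Y, d[sel, ])
  for (g in 1:5) {
    fit <- lm(Y[g, ] ~ sex + geno + sex:geno,
              data = data.frame(sex = as.integer(d$sex[sel] == "F"),
                                geno = as.integer(d$genotype[sel] == "TG")))
    co <- summary(fit)$coefficients
    expect_equal(unlist(res2[g, c("beta0", "beta1", "beta2", "beta12")]),
                 co[, 1], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unlist(res2[g, c("p_sex", "p_genotype", "p_interaction")]),
                 co[2:4, 4], tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res2$r_squared[g], summary(fit)$r.squared, tolerance = 1e-10)
  }
  # noiseless genotype effect is recovered exactly
  dn <- gen_study_design(2)
  seln <- dn$age_months == 4
  En <- matrix(5 + as.integer(dn$genotype[seln] == "TG"), 1, sum(seln),
               dimnames = list("g", NULL))
  resn <- fit_glm_per_gene(En, dn[seln, ])
  expect_equal(resn$beta2, 1)
  expect_equal(resn$beta1, 0)
  expect_equal(resn$beta12, 0)
  expect_error(fit_glm_per_gene(Y, transform(d[sel, ], genotype = "TG")),
               "invalid design")
})

test_that("the genotype term keeps its nominal type-I error under the null", {
  d <- gen_study_design(6)
  sel <- d$age_months == 12
  sim <- gen_expression(d, 2000, sigma = 1, seed = 77)
  res <- fit_glm_per_gene(sim$log_expr[, sel], d[sel, ])
  rate <- mean(res$p_genotype < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("coefficient estimates are unbiased over replicate simulations", {
  d <- gen_study_design(6)
  true <- c(beta1 = 0.4, beta2 = 0.8, beta12 = 1.5)
  errs <- matrix(NA_real_, 500, 3, dimnames = list(NULL, names(true)))
  for (r in 1:500) {
    eff <- data.frame(gene = 1, beta1 = true[1], beta2 = true[2],
                      beta12 = true[3])
    sim <- gen_expression(d, 1, effects = eff, sigma = 0.5, seed = 3000 + r)
    sel <- d$age_months == 4
    res <- fit_glm_per_gene(sim$log_expr[, sel, drop = FALSE], d[sel, ])
    errs[r, ] <- c(res$beta1, res$beta2, res$beta12) - true
  }
  expect_true(all(abs(colMeans(errs)) <= 0.05))
})

test_that("candidate selection applies strict thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    q_model = c(0.25, 0.10, 0.10, 0.24),
                    r_squared = c(0.50, 0.31, 0.30, 0.80),
                    p_sex = 1, p_genotype = c(1, 0.01, 1, 0.2),
                    p_interaction = 1)
  sel <- selection_thresholds(res)
  expect_setequal(sel$candidates, c("b", "d"))  # a: q at bound; c: R2 at bound
  expect_equal(sel$genotype, "b")
  expect_length(sel$sex, 0)
})

test_that("the BH adjustment matches a step-up oracle", {
  set.seed(11)
  for (n in c(1, 10, 137, 1000)) {
    p <- runif(n)^sample(c(1, 3), 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # q >= p for every gene within one family
  d <- gen_study_design(2)
  sim <- gen_expression(d, 50, sigma = 1, seed = 5)
  res <- fit_glm_per_gene(sim$log_expr, d)
  expect_true(all(res$q_model >= res$p_model - 1e-12))
})

test_that("mouse fold changes recover the genotype effects", {
  d <- gen_study_design(6)
  le <- matrix(1, 4, nrow(d), dimnames = list(paste0("g", 1:4), d$subject_id))
  expect_true(all(mouse_lfc(le, d, sex = "F", age_months = 4) == 0))
  le2 <- le
  le2[, d$genotype == "TG"] <- 2
  expect_true(all(mouse_lfc(le2, d, sex = "M", age_months = 12) == 1))
  set.seed(9)
  eff <- data.frame(gene = 1:200, beta1 = 0, beta2 = rnorm(200, 0, 1),
                    beta12 = 0)
  sim <- gen_expression(d, 200, effects = eff, sigma = 0.3, seed = 31)
  lfc <- mouse_lfc(sim$log_expr, d, sex = "F", age_months = 6)
  expect_gt(cor(lfc, sim$truth$beta2), 0.95)
  expect_error(mouse_lfc(le, d[d$genotype == "TG", ], sex = "F"), "stratum")
})

test_that("module correlations flag and blank by adjusted p", {
  set.seed(3)
  m <- stats::setNames(rnorm(100), paste0("g", 1:100))
  mods <- list(same = m, opposite = -m,
               noise = stats::setNames(rnorm(100), names(m)))
  out <- correlate_modules(m, mods)
  expect_equal(out$r[out$module == "same"], 1)
  expect_equal(out$r[out$module == "opposite"], -1)
  expect_true(is.na(out$display[out$module == "noise"]))
  expect_false(is.na(out$display[out$module == "same"]))
  expect_true(all(out$p_adj >= out$p - 1e-12))
  tiny <- list(small = stats::setNames(rnorm(2), paste0("g", 1:2)))
  expect_warning(out2 <- correlate_modules(m, tiny), "fewer than 3")
  expect_equal(nrow(out2), 0)
  # null distribution of r at n = 100: |r| 95th percentile near 0.197
  set.seed(8)
  null_mods <- lapply(1:1000, function(i)
    stats::setNames(rnorm(100), names(m)))
  names(null_mods) <- paste0("m", 1:1000)
  out3 <- correlate_modules(m, null_mods)
  expect_lt(abs(mean(out3$r)), 0.02)
  expect_equal(unname(quantile(abs(out3$r), 0.95)), 0.197, tolerance = 0.1)
})

test_that("sample PCA reports sensible variance fractions", {
  set.seed(6)
  u <- rnorm(50); v <- rnorm(8)
  rank1 <- outer(u, v)
  pc <- pca_samples(rank1)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-8)
  dup <- cbind(rank1, rank1[, 1])
  pc2 <- pca_samples(dup)
  expect_equal(pc2$scores[1, ], pc2$scores[9, ])
  # isotropic noise with p >> n: all retained components carry comparable
  # variance (Marchenko-Pastur edge ratio stays modest at n/p = 0.005)
  # (centering over 10 samples leaves 9 informative components)
  iso <- matrix(rnorm(2000 * 10), 2000, 10)
  ev <- pca_samples(iso)$explained_variance[1:9]
  expect_lt(max(ev) / min(ev), 2)
})

test_that("the chimeric reference appends labeled transgene chromosomes", {
  genome <- c(chr1 = "ACGTACGTAC", chr2 = "GGGGCCCCGG")
  tg <- data.frame(name = c("hAPP", "hPSEN1"),
                   sequence = c("ACGTAAAATT", "TTTTACGTAA"),
                   chromosome = c("21", "22"))
  ref <- build_chimeric_reference(genome, tg)
  expect_length(ref$sequences, 4)
  expect_setequal(names(ref$sequences), c("chr1", "chr2", "21", "22"))
  ann <- ref$annotation
  expect_equal(length(ann), 4)  # gene + exon per transgene
  expect_true(all(BiocGenerics::start(ann) == 1))
  expect_true(all(BiocGenerics::end(ann) == 10))  # full-span annotation
  # round trip through FASTA/GTF preserves sequences byte-identically
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  write_chimeric_reference(ref, fa, gtf)
  back <- read_chimeric_reference(fa, gtf)
  expect_identical(as.character(back$sequences), as.character(ref$sequences))
  expect_equal(length(back$annotation), 4)
  expect_error(build_chimeric_reference(genome,
    transform(tg, chromosome = c("chr1", "22"))), "collide|unique")
  expect_error(build_chimeric_reference(genome,
    transform(tg, sequence = c("ACGU", "ACGT"))), "A,C,G,T,N")
})
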
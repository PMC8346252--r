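# Expression preprocessing, per-gene sex x genotype linear model, and
# correlation of mouse log-fold-changes against human co-expression module
# signatures.
#
# The per-gene model on log2 expression is
#   E = b0 + b1*Sex + b2*Genotype + b12*Sex.Genotype + eps
# with 0/1 coding and the WT male as reference, fitted by ordinary least
# squares separately within each age group. Candidate transcripts are those
# with model q-value < 0.25 and R^2 > 0.3 (both strict); within candidates,
# per-term significance is read at p < 0.05.

#' Filter genes by zero-count prevalence
#'
#' A gene is removed iff it has zero counts in more than 75% of samples
#' (strictly greater; a gene at exactly the threshold is kept).
#'
#' @param counts gene x sample count matrix.
#' @param max_zero_fraction removal threshold (default 0.75).
#' @return Logical vector of genes kept (named by rownames).
#' @export
filter_genes <- function(counts, max_zero_fraction = 0.75) {
  zero_frac <- rowMeans(counts == 0)
  keep <- zero_frac <= max_zero_fraction
  names(keep) <- rownames(counts)
  keep
}

#' Upper-quantile normalization and log2 transform
#'
#' Each sample is divided by its 75th percentile of nonzero TPM, rescaled by
#' the global mean of those quantiles so the output stays on the TPM scale,
#' then transformed as log2(x + 1).
#'
#' @param tpm gene x sample TPM matrix, non-negative.
#' @return A gene x sample matrix of log2 normalized expression.
#' @export
uq_normalize_log <- function(tpm) {
  uq <- apply(tpm, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop_invalid("invalid sample: all-zero TPM column")
    quantile(nz, 0.75, names = FALSE)
  })
  scaled <- sweep(tpm, 2, uq, "/") * mean(uq)
  log2(scaled + 1)
}

design_matrix_sex_genotype <- function(design) {
  sex <- as.integer(design$sex == "F")
  geno <- as.integer(design$genotype == "TG")
  cbind(intercept = 1, sex = sex, genotype = geno, interaction = sex * geno)
}

#' Fit the per-gene sex x genotype linear model
#'
#' Ordinary least squares per gene with 0/1 coding (female = 1, TG = 1; the
#' WT male is the reference). Per-term two-sided p-values come from the t
#' distribution; the model-level F-test p-value is Benjamini-Hochberg
#' adjusted across genes to give the model q-value.
#'
#' @param log_expr gene x sample matrix of log2 expression.
#' @param design data.frame with one row per sample (columns `sex` in
#'   `{"F","M"}` and `genotype` in `{"TG","WT"}`), rows aligned to the
#'   columns of `log_expr`.
#' @return A data.frame with one row per gene: coefficients `beta0`, `beta1`
#'   (sex), `beta2` (genotype), `beta12` (interaction), their p-values
#'   `p_sex`, `p_genotype`, `p_interaction`, `sigma2`, `r_squared`,
#'   `p_model`, `q_model`.
#' @export
fit_glm_per_gene <- function(log_expr, design) {
  if (ncol(log_expr) != nrow(design))
    stop_invalid("design rows must match expression columns")
  if (length(unique(design$sex)) < 2 || length(unique(design$genotype)) < 2)
    stop_invalid("invalid design: need both sexes and both genotypes")
  X <- design_matrix_sex_genotype(design)
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-10) stop_invalid("invalid design: rank deficient")
  XtX_inv <- solve(XtX)
  n <- nrow(X); p <- ncol(X)
  Y <- log_expr                             # genes x samples
  B <- Y %*% X %*% XtX_inv                  # genes x 4
  fitted <- B %*% t(X)
  resid <- Y - fitted
  rss <- rowSums(resid^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(outer(sigma2, diag(XtX_inv)))
  tval <- B / se
  pval <- 2 * pt(-abs(tval), df)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  f_model <- ((tss - rss) / (p - 1)) / (rss / df)
  p_model <- pf(f_model, p - 1, df, lower.tail = FALSE)
  p_model[!is.finite(f_model)] <- 1
  out <- data.frame(
    gene = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    beta0 = B[, 1], beta1 = B[, 2], beta2 = B[, 3], beta12 = B[, 4],
    p_sex = pval[, 2], p_genotype = pval[, 3], p_interaction = pval[, 4],
    sigma2 = sigma2, r_squared = pmin(pmax(r2, 0), 1),
    p_model = p_model, q_model = p.adjust(p_model, "BH")
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the candidate-gene selection thresholds
#'
#' Candidates must satisfy `q_model < q_max` and `r_squared > r2_min`, both
#' strict. Within candidates, per-term significant gene lists are read at
#' `p < alpha`.
#'
#' @param results a \code{\link{fit_glm_per_gene}} table.
#' @param q_max,r2_min,alpha thresholds (defaults 0.25, 0.3, 0.05).
#' @return A list: `candidates` (gene names), plus `sex`, `genotype`,
#'   `interaction` significant-gene lists within the candidates.
#' @export
selection_thresholds <- function(results, q_max = 0.25, r2_min = 0.3,
                                 alpha = 0.05) {
  cand <- results$q_model < q_max & results$r_squared > r2_min
  sub <- results[cand, , drop = FALSE]
  list(candidates = sub$gene,
       sex = sub$gene[sub$p_sex < alpha],
       genotype = sub$gene[sub$p_genotype < alpha],
       interaction = sub$gene[sub$p_interaction < alpha])
}

#' Mouse log2 fold change within a sex/age stratum
#'
#' Per gene, mean log2 expression of TG samples minus mean of WT samples in
#' the requested stratum.
#'
#' @param log_expr gene x sample log2 expression matrix.
#' @param design per-sample data.frame (`genotype`, `sex`, `age_months`).
#' @param sex,age_months stratum selectors; `NULL` keeps all levels.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
mouse_lfc <- function(log_expr, design, sex = NULL, age_months = NULL) {
  sel <- rep(TRUE, nrow(design))
  if (!is.null(sex)) sel <- sel & design$sex == sex
  if (!is.null(age_months)) sel <- sel & design$age_months == age_months
  tg <- sel & design$genotype == "TG"
  wt <- sel & design$genotype == "WT"
  if (!any(tg) || !any(wt))
    stop_invalid("stratum must contain both TG and WT samples")
  rowMeans(log_expr[, tg, drop = FALSE]) - rowMeans(log_expr[, wt, drop = FALSE])
}

#' Correlate mouse fold changes with human module signatures
#'
#' Pearson correlation between the mouse log2 fold-change vector and each
#' human module's per-gene log2 fold changes, on the shared-gene
#' intersection. Two-sided p-values from `cor.test` are Benjamini-Hochberg
#' adjusted across all supplied cells; the display value is blanked (`NA`)
#' where the adjusted p exceeds 0.05. Modules sharing fewer than 3 genes are
#' skipped with a warning.
#'
#' @param mouse named numeric vector of mouse log2 fold changes (names are
#'   gene identifiers, harmonized with the human tables).
#' @param human_modules named list of named numeric vectors (one per human
#'   module).
#' @param alpha blanking threshold on adjusted p (default 0.05).
#' @return A data.frame: `module`, `n_genes`, `r`, `p`, `p_adj`, `display`
#'   (`r` where significant, `NA` otherwise).
#' @export
correlate_modules <- function(mouse, human_modules, alpha = 0.05) {
  rows <- lapply(names(human_modules), function(m) {
    hv <- human_modules[[m]]
    shared <- intersect(names(mouse), names(hv))
    if (length(shared) < 3) {
      warning("module '", m, "' skipped: fewer than 3 shared genes")
      return(NULL)
    }
    ct <- cor.test(hv[shared], mouse[shared], method = "pearson")
    data.frame(module = m, n_genes = length(shared),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(module = character(0), n_genes = integer(0),
                      r = numeric(0), p = numeric(0), p_adj = numeric(0),
                      display = numeric(0)))
  out$p_adj <- p.adjust(out$p, "BH")
  out$display <- ifelse(out$p_adj > alpha, NA_real_, out$r)
  rownames(out) <- NULL
  out
}

#' Sample-level principal component analysis
#'
#' Centered (unscaled) PCA over samples of a gene x sample expression
#' matrix, for inspecting genotype/sex/age structure.
#'
#' @param log_expr gene x sample matrix.
#' @return A list: `scores` (sample x component), `explained_variance`
#'   fractions.
#' @export
pca_samples <- function(log_expr) {
  pc <- prcomp(t(log_expr), center = TRUE, scale. = FALSE)
  list(scores = pc$x, explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
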
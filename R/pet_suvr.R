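# PET regional-uptake analysis: bilateral averaging, cerebellum-normalized
# SUVR, PCA consensus-region selection, and two-way genotype x age ANOVA.

#' Average left/right lateralized regions into bilateral volumes
#'
#' Regions named `<stem>_left` / `<stem>_right` are averaged arithmetically
#' within each subject; any other (midline/unpaired) region passes through
#' unchanged.
#'
#' @param uptake long data.frame with columns `subject`, `region`, `value`
#'   and any metadata columns (`genotype`, `sex`, `age`), one row per
#'   subject x region.
#' @return A data.frame of the same shape with bilateral region names.
#' @export
average_bilateral <- function(uptake) {
  stopifnot(all(c("subject", "region", "value") %in% names(uptake)))
  stem <- sub("_(left|right)$", "", uptake$region)
  meta_cols <- setdiff(names(uptake), c("region", "value"))
  agg <- stats::aggregate(uptake$value,
                          by = c(list(region = stem),
                                 lapply(meta_cols, function(cl) uptake[[cl]])),
                          FUN = mean)
  names(agg) <- c("region", meta_cols, "value")
  agg[order(agg$subject, agg$region), c(meta_cols, "region", "value")]
}

#' Cerebellum-normalized standardized uptake value ratios
#'
#' For each subject, every regional uptake is divided by that subject's
#' reference-region (cerebellum) uptake, cancelling injected dose and global
#' calibration. The reference region itself maps to exactly 1.
#'
#' @param uptake long data.frame (`subject`, `region`, `value`, metadata).
#' @param reference reference region name (default `"cerebellum"`).
#' @return A list with `suvr` (subject x region matrix) and `design` (one
#'   metadata row per subject).
#' @export
compute_suvr <- function(uptake, reference = "cerebellum") {
  stopifnot(all(c("subject", "region", "value") %in% names(uptake)))
  subjects <- unique(uptake$subject)
  regions <- unique(uptake$region)
  if (!reference %in% regions)
    stop_invalid("reference region '", reference, "' absent from uptake table")
  mat <- matrix(NA_real_, length(subjects), length(regions),
                dimnames = list(subjects, regions))
  mat[cbind(match(uptake$subject, subjects), match(uptake$region, regions))] <-
    uptake$value
  C <- mat[, reference]
  bad <- which(!is.finite(C) | C <= 0)
  if (length(bad))
    stop_invalid("non-positive cerebellum uptake for subject(s): ",
                 paste(subjects[bad], collapse = ", "))
  suvr <- sweep(mat, 1, C, "/")
  meta_cols <- setdiff(names(uptake), c("region", "value"))
  design <- unique(uptake[meta_cols])
  design <- design[match(subjects, design$subject), , drop = FALSE]
  rownames(design) <- NULL
  list(suvr = suvr, design = design)
}

#' Select consensus regions by principal component analysis
#'
#' Correlation-mode PCA (columns centered and unit-scaled) of the subject x
#' region SUVR matrix. The minimal set of leading components whose cumulative
#' explained variance reaches `variance_target` is retained (never fewer than
#' one); for each retained component the regions whose absolute loading is at
#' least half that component's maximum absolute loading are selected, and the
#' union over components is returned. Zero-variance columns (e.g. the
#' reference region, identically 1) are excluded before PCA.
#'
#' @param suvr subject x region numeric matrix.
#' @param variance_target cumulative explained-variance target (default 0.8).
#' @param loading_fraction fraction of the per-component max |loading| a
#'   region must reach to be selected (default 0.5).
#' @return A list: `selected_regions`, `n_components`,
#'   `explained_variance` (all components), `cumulative_variance`,
#'   `loadings` (retained components).
#' @export
select_consensus_regions <- function(suvr, variance_target = 0.8,
                                     loading_fraction = 0.5) {
  check_scalar_number(variance_target, "variance_target", lower = 0, upper = 1)
  if (nrow(suvr) < 2 || ncol(suvr) < 2)
    stop_invalid("need at least 2 subjects and 2 regions")
  sds <- apply(suvr, 2, sd)
  keep <- sds > 1e-12
  if (!any(keep)) stop_invalid("SUVR matrix has no variance")
  x <- suvr[, keep, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(ev)
  k <- max(1L, which(cum >= variance_target)[1])
  if (is.na(k)) k <- length(ev)
  sel <- character(0)
  for (j in seq_len(k)) {
    load <- abs(pc$rotation[, j])
    sel <- union(sel, names(load)[load >= loading_fraction * max(load)])
  }
  list(selected_regions = sort(sel), n_components = k,
       explained_variance = ev, cumulative_variance = cum[k],
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

#' Two-way genotype x age ANOVA per region
#'
#' Fixed-effects two-factor ANOVA with interaction fitted to each region's
#' SUVR values; on balanced designs the classical sum-of-squares
#' decomposition applies. Regions with a constant response are flagged not
#' significant with `NA` statistics.
#'
#' @param suvr subject x region SUVR matrix.
#' @param design data.frame with one row per subject (matching `suvr` rows)
#'   and columns `genotype`, `age`.
#' @param alpha significance level for the flags (default 0.05, uncorrected;
#'   set `adjust = "BH"` to flag on BH-adjusted p instead).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data.frame with one row per region x term (`genotype`, `age`,
#'   `genotype:age`): `F`, `p`, `p_adj`, `significant`.
#' @export
anova_genotype_age <- function(suvr, design, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  g <- factor(design$genotype)
  a <- factor(design$age)
  if (nlevels(g) < 2 || nlevels(a) < 2)
    stop_invalid("each factor needs at least 2 levels")
  terms <- c("genotype", "age", "genotype:age")
  rows <- lapply(colnames(suvr), function(r) {
    y <- suvr[, r]
    if (sd(y) < 1e-12) {
      return(data.frame(region = r, term = terms, F = NA_real_, p = NA_real_))
    }
    fit <- aov(y ~ g * a)
    tab <- summary(fit)[[1]]
    data.frame(region = r, term = terms,
               F = tab[1:3, "F value"], p = tab[1:3, "Pr(>F)"])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
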
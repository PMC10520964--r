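# Post-quantification expression analysis for the temperature-gradient
# design: CPM transforms, contig-to-gene grouping by shared best hit,
# empirical control selection, unwanted-variation factors, outlier
# detection, NB differential expression against the 5 degree control, and
# hypergeometric term enrichment.

# ---- I/O ------------------------------------------------------------------

#' Read a gene-level count matrix
#'
#' @param path TSV with gene ids in the first column and one column of
#'   integer counts per sample.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_counts(m)
  m
}

check_counts <- function(counts) {
  if (any(counts < 0)) stop_glue("count matrix has negative entries")
  if (any(colSums(counts) == 0)) {
    stop_glue("sample(s) with zero library size: ",
              paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a sample design table
#'
#' @param path CSV with columns `sample_id`, `temperature_C`, `exposure`,
#'   `replicate`, and optionally `batch`.
#' @return Data frame of the design.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "temperature_C", "exposure", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_glue("design missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a 12-column BLAST/diamond tabular hit file
#'
#' Columns follow outfmt 6: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' e-value, bitscore.
#'
#' @param path Path to the tabular file (no header).
#' @return Data frame of hit records.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop_glue("expected 12 columns, got ", ncol(df))
  names(df) <- cols
  df
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV with columns `gene_id` and `term_id`, one pair per row.
#' @return Data frame with `gene_id`, `term_id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("gene_id", "term_id")
  }
  df
}

# ---- transforms -----------------------------------------------------------

#' Counts-per-million transform
#'
#' Scales each sample to counts per million of its library size. With
#' `log = TRUE` returns `log2(cpm + prior_count)`; with
#' `row_normalize = TRUE` subtracts each gene's row mean (the display
#' transform used for expression heat maps).
#'
#' @param counts Genes x samples count matrix.
#' @param log Return log2-transformed values.
#' @param prior_count Offset added before the log (default 1).
#' @param row_normalize Subtract row means after the (log) transform.
#' @return Numeric matrix of the same dimensions.
#' @export
cpm_transform <- function(counts, log = FALSE, prior_count = 1,
                          row_normalize = FALSE) {
  check_counts(counts)
  lib <- colSums(counts)
  out <- sweep(counts, 2, lib, "/") * 1e6
  if (log) out <- log2(out + prior_count)
  if (row_normalize) out <- out - rowMeans(out)
  out
}

# ---- contig -> gene grouping ---------------------------------------------

#' Group contigs into genes by shared best hit
#'
#' For each contig the best hit is the record with the highest bitscore
#' (ties broken by lower e-value, then by lexicographically smallest subject
#' id, making the grouping independent of record order). Contigs sharing
#' the same best-hit subject are assigned to one gene named by that subject;
#' contigs with no hit become singleton genes named by the contig itself.
#'
#' @param hits Data frame of hit records as from [read_hits()].
#' @param contigs Character vector of all contig ids (including those with
#'   no hits).
#' @return Data frame with columns `contig` and `gene`; every contig appears
#'   exactly once.
#' @export
group_genes_by_best_hit <- function(hits, contigs) {
  contigs <- as.character(contigs)
  gene <- stats::setNames(contigs, contigs)
  if (nrow(hits)) {
    hits <- hits[hits$qseqid %in% contigs, , drop = FALSE]
    ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
    best <- hits[ord, , drop = FALSE]
    best <- best[!duplicated(best$qseqid), , drop = FALSE]
    gene[best$qseqid] <- best$sseqid
  }
  data.frame(contig = contigs, gene = unname(gene[contigs]),
             stringsAsFactors = FALSE)
}

#' Collapse a contig-level count matrix to gene level
#'
#' @param counts Contigs x samples count matrix.
#' @param grouping Data frame from [group_genes_by_best_hit()].
#' @return Genes x samples matrix with counts summed within genes.
#' @export
collapse_counts <- function(counts, grouping) {
  idx <- match(rownames(counts), grouping$contig)
  if (anyNA(idx)) stop_glue("counts contain contigs absent from grouping")
  rowsum(counts, group = grouping$gene[idx])
}

# ---- NB machinery ---------------------------------------------------------

# Expression filter: keep genes with cpm above `min_cpm` in at least as many
# samples as the smallest group.
filter_expressed <- function(counts, groups, min_cpm = 1) {
  cpm <- cpm_transform(counts)
  min_n <- min(table(groups))
  rowSums(cpm > min_cpm) >= min_n
}

# Method-of-moments NB dispersion per gene, pooled over groups on
# library-size-normalized counts, then shrunk 50/50 toward the common
# (median) dispersion across genes. When nuisance covariates W are
# supplied, their per-gene log-scale contribution (estimated jointly with
# the group means) is divided out first, so unwanted variation does not
# masquerade as biological dispersion.
mom_dispersion <- function(counts, groups, W = NULL) {
  lib <- colSums(counts)
  y <- sweep(counts, 2, lib, "/") * exp(mean(log(lib)))
  groups <- factor(groups)
  if (!is.null(W) && ncol(W) > 0) {
    l <- log2(y + 0.5)
    Xg <- stats::model.matrix(~ 0 + groups)
    XW <- cbind(Xg, W)
    B <- solve(crossprod(XW), crossprod(XW, t(l)))
    gamma <- B[seq(ncol(Xg) + 1, ncol(XW)), , drop = FALSE]
    y <- y / 2^t(W %*% gamma)
  }
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- apply(y[, idx, drop = FALSE], 1, stats::var)
    w <- length(idx) - 1
    num <- num + w * (v - m)
    den <- den + w * m^2
  }
  phi <- pmax(num / pmax(den, 1e-8), 0)
  phi[!is.finite(phi)] <- 0
  common <- stats::median(phi)
  0.5 * phi + 0.5 * common
}

# Per-gene NB log-linear likelihood-ratio test of `X_full` against nested
# `X_null`, with log library size offsets and fixed per-gene dispersion.
nb_lrt <- function(counts, X_full, X_null, dispersion) {
  lib <- colSums(counts)
  off <- log(lib)
  df <- ncol(X_full) - ncol(X_null)
  n_genes <- nrow(counts)
  stat <- numeric(n_genes)
  pval <- numeric(n_genes)
  coefs <- matrix(NA_real_, n_genes, ncol(X_full),
                  dimnames = list(rownames(counts), colnames(X_full)))
  ctl <- stats::glm.control(maxit = 100)
  for (i in seq_len(n_genes)) {
    y <- counts[i, ]
    phi <- dispersion[i]
    fam <- if (phi < 1e-8) stats::poisson()
    else MASS::negative.binomial(theta = 1 / phi)
    dev <- tryCatch({
      fit_full <- suppressWarnings(
        stats::glm.fit(X_full, y, family = fam, offset = off, control = ctl))
      fit_null <- suppressWarnings(
        stats::glm.fit(X_null, y, family = fam, offset = off, control = ctl))
      coefs[i, ] <- fit_full$coefficients
      fit_null$deviance - fit_full$deviance
    }, error = function(e) NA_real_)
    if (is.na(dev)) {
      stat[i] <- 0
      pval[i] <- 1
    } else {
      stat[i] <- max(dev, 0)
      pval[i] <- stats::pchisq(max(dev, 0), df = df, lower.tail = FALSE)
    }
  }
  list(stat = stat, p_value = pval, df = df, coefficients = coefs)
}

subset_design <- function(counts, design, exposure = "both",
                          exclude_samples = character(0)) {
  stopifnot(identical(colnames(counts), design$sample_id) ||
              all(design$sample_id %in% colnames(counts)))
  counts <- counts[, design$sample_id, drop = FALSE]
  keep <- !(design$sample_id %in% exclude_samples)
  if (exposure != "both") {
    ctrl <- min(design$temperature_C)
    keep_exposure <- design$exposure == exposure
    # The control temperature anchors every comparison: when the design has
    # no control samples under the requested exposure, retain all controls.
    if (!any(keep_exposure & design$temperature_C == ctrl)) {
      keep_exposure <- keep_exposure | design$temperature_C == ctrl
    }
    keep <- keep & keep_exposure
  }
  list(counts = counts[, keep, drop = FALSE],
       design = design[keep, , drop = FALSE])
}

# ---- empirical controls & unwanted variation ------------------------------

#' Select empirical control genes
#'
#' Runs a first-pass all-groups omnibus differential-expression test (every
#' temperature x exposure cell its own group) on expression-filtered genes
#' and returns the `n_controls` genes with the smallest omnibus statistic --
#' the genes varying least across the whole design, suitable as negative
#' controls for unwanted-variation estimation.
#'
#' @param counts Genes x samples count matrix.
#' @param design Design data frame (see [read_design()]).
#' @param n_controls Number of control genes to return (default 1000).
#' @param min_cpm Expression filter threshold (default 1).
#' @return Character vector of control gene ids.
#' @export
select_empirical_controls <- function(counts, design, n_controls = 1000,
                                      min_cpm = 1) {
  check_counts(counts)
  counts <- counts[, design$sample_id, drop = FALSE]
  groups <- interaction(design$temperature_C, design$exposure, drop = TRUE)
  keep <- filter_expressed(counts, groups, min_cpm)
  counts <- counts[keep, , drop = FALSE]
  if (n_controls > nrow(counts)) {
    warning("requested ", n_controls, " controls but only ", nrow(counts),
            " expressed genes; returning all")
    n_controls <- nrow(counts)
  }
  X_full <- stats::model.matrix(~groups)
  X_null <- stats::model.matrix(~1, data = data.frame(g = groups))
  disp <- mom_dispersion(counts, groups)
  res <- nb_lrt(counts, X_full, X_null, disp)
  rownames(counts)[order(res$stat)][seq_len(n_controls)]
}

#' Estimate unwanted-variation factors from control genes
#'
#' Factor-analytic removal of unwanted variation: the samples x controls
#' matrix of gene-centered log2-cpm is decomposed by SVD and the first `k`
#' left singular vectors are returned as nuisance covariates for the
#' differential-expression model. Columns of `W` have unit norm.
#'
#' @param counts Genes x samples count matrix.
#' @param controls Character vector of control gene ids (rows of `counts`).
#' @param k Number of factors (0 for none; must be < number of samples).
#' @return A list with `W` (samples x k matrix), `k`, and `controls`.
#' @export
estimate_unwanted_factors <- function(counts, controls, k = 1) {
  check_counts(counts)
  n <- ncol(counts)
  if (k > n - 1) stop_glue("k must be at most samples - 1 = ", n - 1)
  if (k == 0) {
    W <- matrix(numeric(0), nrow = n, ncol = 0,
                dimnames = list(colnames(counts), NULL))
    return(list(W = W, k = 0L, controls = character(0)))
  }
  if (!length(controls)) stop_glue("need control genes when k > 0")
  missing <- setdiff(controls, rownames(counts))
  if (length(missing)) {
    stop_glue("control genes absent from counts: ",
              paste(utils::head(missing, 3), collapse = ", "))
  }
  lc <- cpm_transform(counts[controls, , drop = FALSE], log = TRUE)
  m <- t(lc)                      # samples x controls
  m <- sweep(m, 2, colMeans(m))   # center each control gene
  sv <- svd(m, nu = k, nv = 0)
  W <- sv$u[, seq_len(k), drop = FALSE]
  dimnames(W) <- list(colnames(counts), paste0("W", seq_len(k)))
  list(W = W, k = as.integer(k), controls = controls)
}

# ---- outlier samples ------------------------------------------------------

#' Flag outlier samples by PCA distance within their group
#'
#' Projects samples onto the first two principal components of log2-cpm and
#' measures, for each sample, its distance to the nearest other sample of
#' its temperature x exposure group. (The nearest group-mate stands in for
#' the group centre: a gross outlier is far from every replicate, while its
#' group-mates remain close to each other, so the outlier does not
#' implicate them the way a shifted centroid would.) A sample is flagged
#' when its distance lies more than `c_mad` median-absolute-deviations
#' above the median of all within-group distances. Deterministic
#' replacement for by-eye MDS/PCA screening; the default cut-off is
#' calibrated so homogeneous experiments of this size are flag-free about
#' 95% of the time, while a sample with a gross compositional shift sits
#' tens of MADs out. Samples alone in their group cannot be assessed and
#' are never flagged.
#'
#' @param counts Genes x samples count matrix (>= 3 samples).
#' @param design Design data frame.
#' @param c_mad Robust z cut-off on the within-group distance.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(counts, design, c_mad = 6) {
  check_counts(counts)
  if (ncol(counts) < 3) stop_glue("need at least 3 samples")
  counts <- counts[, design$sample_id, drop = FALSE]
  lc <- cpm_transform(counts, log = TRUE)
  pc <- stats::prcomp(t(lc), center = TRUE, scale. = FALSE)
  nc <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  groups <- interaction(design$temperature_C, design$exposure, drop = TRUE)
  d <- rep(NA_real_, nrow(scores))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    dist_g <- as.matrix(stats::dist(scores[idx, , drop = FALSE]))
    diag(dist_g) <- Inf
    d[idx] <- apply(dist_g, 1, min)
  }
  ok <- !is.na(d)
  cut <- stats::median(d[ok]) + c_mad * stats::mad(d[ok])
  design$sample_id[ok & d > cut]
}

# ---- differential expression ---------------------------------------------

#' Call differentially expressed genes against the control temperature
#'
#' Fits, per gene, a negative-binomial log-linear model with a temperature
#' factor (plus exposure when both exposures are analyzed jointly, plus any
#' unwanted-variation covariates in `W`), with log library-size offsets.
#' Dispersion is estimated by method of moments and shrunk 50/50 toward the
#' common dispersion. An omnibus likelihood-ratio test of all temperature
#' terms against the nested no-temperature model gives each gene's p-value
#' (an ANOVA-like comparison of every temperature with the control);
#' Benjamini-Hochberg adjustment yields FDRs, and genes with
#' `fdr < fdr_threshold` are flagged significant. The temperature-response
#' direction is the sign of the least-squares slope of mean log2-cpm against
#' temperature (see [classify_temperature_pattern()]).
#'
#' @param counts Genes x samples count matrix.
#' @param design Design data frame (see [read_design()]).
#' @param W Unwanted-variation covariates: matrix from
#'   [estimate_unwanted_factors()]`$W`, or `NULL`.
#' @param exposure `"ST"`, `"LT"`, or `"both"`; control-temperature samples
#'   are retained in every subset.
#' @param fdr_threshold Significance threshold on the FDR (default 0.01).
#' @param min_cpm Expression filter threshold (default 1).
#' @param exclude_samples Sample ids to drop before analysis (e.g., outliers
#'   or a temperature group with excessive intra-replicate diversity).
#' @return Data frame, one row per tested gene: per-temperature log2 fold
#'   change versus the control temperature, omnibus statistic, `p_value`,
#'   `fdr`, `direction` (`"up"`, `"down"`, `"flat"`), and `significant`.
#'   Filtered-out genes are listed in attribute `"filtered_genes"`.
#' @export
call_degs <- function(counts, design, W = NULL, exposure = "both",
                      fdr_threshold = 0.01, min_cpm = 1,
                      exclude_samples = character(0)) {
  check_counts(counts)
  sub <- subset_design(counts, design, exposure, exclude_samples)
  counts <- sub$counts
  design <- sub$design
  ctrl_temp <- min(design$temperature_C)
  temps <- sort(unique(design$temperature_C))
  if (length(temps) < 2) stop_glue("need at least 2 temperature groups")
  tf <- factor(design$temperature_C, levels = temps)
  if (min(table(tf)) < 2) stop_glue("each temperature group needs >= 2 samples")
  if (!is.null(W)) {
    W <- W[design$sample_id, , drop = FALSE]
    if (anyNA(W)) stop_glue("W rows do not cover the analyzed samples")
  }

  cells <- interaction(design$temperature_C, design$exposure, drop = TRUE)
  keep <- filter_expressed(counts, cells, min_cpm)
  filtered <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]

  has_exposure <- exposure == "both" && length(unique(design$exposure)) > 1
  base <- if (has_exposure) {
    stats::model.matrix(~factor(design$exposure))
  } else {
    stats::model.matrix(~1, data = design)
  }
  X_null <- base
  X_full <- cbind(base, stats::model.matrix(~tf)[, -1, drop = FALSE])
  colnames(X_full) <- c(colnames(base),
                        paste0("temp", temps[-1]))
  if (!is.null(W) && ncol(W) > 0) {
    X_null <- cbind(X_null, W)
    X_full <- cbind(X_full, W)
  }

  disp <- mom_dispersion(counts, cells, W = W)
  res <- nb_lrt(counts, X_full, X_null, disp)
  fdr <- stats::p.adjust(res$p_value, method = "BH")

  # Per-temperature mean log2-cpm (for the direction label).
  lc <- cpm_transform(counts, log = TRUE)
  mean_lc <- vapply(temps, function(tt) {
    rowMeans(lc[, design$temperature_C == tt, drop = FALSE])
  }, numeric(nrow(counts)))
  direction <- apply(mean_lc, 1, classify_temperature_pattern, temps = temps)

  lfc <- res$coefficients[, paste0("temp", temps[-1]), drop = FALSE] / log(2)
  colnames(lfc) <- paste0("log2fc_", temps[-1], "C")

  out <- data.frame(
    gene = rownames(counts),
    lfc,
    stat = res$stat,
    df = res$df,
    p_value = res$p_value,
    fdr = fdr,
    direction = direction,
    significant = fdr < fdr_threshold,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "filtered_genes") <- filtered
  attr(out, "control_temperature_C") <- ctrl_temp
  out
}

#' Classify the temperature-response direction of a gene
#'
#' Least-squares slope of mean log2-cpm against numeric temperature:
#' positive slope is `"up"` (expression rises with temperature), negative
#' `"down"`, zero `"flat"`.
#'
#' @param means Mean log2-cpm per temperature group (same order as `temps`).
#' @param temps Numeric temperatures.
#' @return `"up"`, `"down"`, or `"flat"`.
#' @export
classify_temperature_pattern <- function(means, temps) {
  slope <- stats::cov(temps, means) / stats::var(temps)
  if (abs(slope) < 1e-12) "flat" else if (slope > 0) "up" else "down"
}

# ---- enrichment -----------------------------------------------------------

#' Hypergeometric term enrichment with an observed/expected threshold
#'
#' For each term annotated to at least one universe gene, tests whether the
#' DEG set overlaps the term more than expected by sampling without
#' replacement: with `N` universe genes, `K` of them annotated, and a DEG
#' set of size `n` overlapping the term in `k` genes, the p-value is the
#' hypergeometric upper tail P(X >= k), the expectation is `n * K / N`, and
#' the enrichment ratio is `k / expected`. P-values are BH-adjusted across
#' the tested terms; a term is significant when `fdr < fdr_threshold` and
#' the observed/expected ratio exceeds `min_oe`.
#'
#' @param deg_set Character vector of significant genes (subset of
#'   `universe`).
#' @param universe Character vector of all expressed genes.
#' @param annotation Data frame with columns `gene_id`, `term_id`.
#' @param fdr_threshold FDR cut-off (default 0.05).
#' @param min_oe Observed/expected cut-off (default 3).
#' @return Data frame, one row per tested term: `term_id`, `N`, `K`, `n`,
#'   `k`, `expected`, `o_over_e`, `p_value`, `fdr`, `significant`.
#' @export
hypergeometric_enrichment <- function(deg_set, universe, annotation,
                                      fdr_threshold = 0.05, min_oe = 3) {
  universe <- unique(as.character(universe))
  deg_set <- unique(as.character(deg_set))
  extra <- setdiff(deg_set, universe)
  if (length(extra)) {
    stop_glue("deg_set genes outside the universe: ",
              paste(utils::head(extra, 3), collapse = ", "))
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  N <- length(universe)
  n <- length(deg_set)
  terms <- unique(ann$term_id)
  rows <- lapply(terms, function(tm) {
    genes_tm <- ann$gene_id[ann$term_id == tm]
    K <- length(genes_tm)
    if (K == 0) return(NULL)
    k <- length(intersect(genes_tm, deg_set))
    expected <- n * K / N
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(
      term_id = tm, N = N, K = K, n = n, k = k,
      expected = expected,
      o_over_e = if (expected > 0) k / expected else NA_real_,
      p_value = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), expected = numeric(0),
                      o_over_e = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$fdr < fdr_threshold & out$o_over_e > min_oe
  out[order(out$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the output is
#' in the same order as the input. Inputs must lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, elementwise >= the input and <= 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_glue("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
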
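test_that("cpm columns scale to per-million and row-normalize to zero", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(as.numeric(cpm_transform(m)), c(250000, 750000))

  sim <- generate_expression_experiment(
    small_expression_config(n_genes = 50), seed = 2)
  cpm <- cpm_transform(sim$counts)
  expect_equal(unname(colSums(cpm)), rep(1e6, ncol(cpm)))

  flat <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  rn <- cpm_transform(flat, log = TRUE, row_normalize = TRUE)
  expect_equal(as.numeric(rn), rep(0, 12))

  bad <- matrix(c(1, 0, 0, 0), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(cpm_transform(bad), "zero library size")
})

test_that("best-hit grouping follows bitscore with e-value/id tie-breaks", {
  hits <- data.frame(
    qseqid = c("A", "B", "C"), sseqid = c("P1", "P1", "P2"),
    pident = 90, length = 100, mismatch = 1, gapopen = 0,
    qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = c(1e-30, 1e-20, 1e-10), bitscore = c(100, 90, 80),
    stringsAsFactors = FALSE
  )
  g <- group_genes_by_best_hit(hits, c("A", "B", "C", "D"))
  expect_equal(g$gene, c("P1", "P1", "P2", "D"))

  # equal bitscore: lower e-value wins
  tie <- data.frame(
    qseqid = "A", sseqid = c("P2", "P1"), pident = 90, length = 100,
    mismatch = 1, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
    send = 100, evalue = c(1e-20, 1e-30), bitscore = c(100, 100),
    stringsAsFactors = FALSE
  )
  expect_equal(group_genes_by_best_hit(tie, "A")$gene, "P1")
  # equal bitscore and e-value: lexicographically smallest subject
  tie$evalue <- 1e-20
  expect_equal(group_genes_by_best_hit(tie, "A")$gene, "P1")
})

test_that("grouping is a partition invariant to record order", {
  map <- c(c1 = "P1", c2 = "P1", c3 = "P2", c4 = NA, c5 = "P2", c6 = "P3")
  ht <- generate_hit_table(map, n_decoys = 3, seed = 8)
  g1 <- group_genes_by_best_hit(ht, names(map))
  expect_equal(nrow(g1), length(map))
  expect_equal(sort(g1$contig), sort(names(map)))
  for (s in 1:5) {
    set.seed(s)
    g2 <- group_genes_by_best_hit(ht[sample(nrow(ht)), ], names(map))
    expect_equal(g2, g1)
  }
  # collapse sums counts within genes
  cts <- matrix(1:18, nrow = 6, dimnames = list(names(map), paste0("s", 1:3)))
  coll <- collapse_counts(cts, g1)
  expect_equal(nrow(coll), length(unique(g1$gene)))
  expect_equal(colSums(coll), colSums(cts))
})

test_that("control selection returns the least-varying genes", {
  sim <- generate_expression_experiment(
    small_expression_config(n_genes = 300, fraction_de = 0.2,
                            lfc_per_step = 1.5), seed = 15)
  ctrl <- select_empirical_controls(sim$counts, sim$design, n_controls = 80)
  expect_length(ctrl, 80)
  truth <- sim$truth$genes
  purity <- mean(!truth$is_de[match(ctrl, truth$gene)])
  expect_gte(purity, 0.8)
  expect_warning(
    all_g <- select_empirical_controls(sim$counts, sim$design,
                                       n_controls = 1e5),
    "returning all")
  expect_true(length(all_g) <= 300)
})

test_that("unwanted factors have the contracted shape and recover batch", {
  sim <- generate_expression_experiment(
    small_expression_config(n_genes = 400, fraction_de = 0,
                            lfc_per_step = 0, batch_sd = 1), seed = 16)
  ctrl <- rownames(sim$counts)[1:100]
  uv <- estimate_unwanted_factors(sim$counts, ctrl, k = 2)
  expect_equal(dim(uv$W), c(ncol(sim$counts), 2))
  expect_equal(unname(apply(uv$W, 2, function(v) sum(v^2))), c(1, 1),
               tolerance = 1e-8)
  b <- as.numeric(sim$truth$samples$batch == "B")
  expect_gt(abs(cor(uv$W[, 1], b)), 0.9)

  uv0 <- estimate_unwanted_factors(sim$counts, character(0), k = 0)
  expect_equal(ncol(uv0$W), 0)
  expect_error(estimate_unwanted_factors(sim$counts, ctrl,
                                         k = ncol(sim$counts)),
               "samples - 1")
})

test_that("k = 0 adjustment leaves the DEG fit unchanged", {
  sim <- generate_expression_experiment(
    small_expression_config(n_genes = 150), seed = 19)
  uv0 <- estimate_unwanted_factors(sim$counts, character(0), k = 0)
  d1 <- call_degs(sim$counts, sim$design, W = uv0$W, exposure = "ST")
  d2 <- call_degs(sim$counts, sim$design, exposure = "ST")
  expect_equal(d1, d2)
})

test_that("outlier screening flags a shifted sample and spares clean ones", {
  sim <- generate_expression_experiment(
    small_expression_config(n_genes = 500, fraction_de = 0, lfc_per_step = 0,
                            n_outliers = 1), seed = 23)
  truth <- sim$truth$samples$sample_id[sim$truth$samples$is_outlier]
  expect_true(truth %in% detect_outlier_samples(sim$counts, sim$design))

  m <- matrix(rep(c(5L, 10L, 20L, 3L), 3), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  des <- data.frame(sample_id = paste0("s", 1:3), temperature_C = 5,
                    exposure = "ST", replicate = 1:3)
  expect_length(detect_outlier_samples(m, des), 0)
})

test_that("homogeneous experiments are flag-free in at least 95/100 runs", {
  clean <- 0
  for (s in 1:100) {
    sim <- generate_expression_experiment(
      expression_config(n_genes = 300, fraction_de = 0, lfc_per_step = 0),
      seed = 1000 + s)
    if (!length(detect_outlier_samples(sim$counts, sim$design))) {
      clean <- clean + 1
    }
  }
  expect_gte(clean, 95)
})

test_that("a constant gene is never significant", {
  cts <- matrix(rep(c(50L, 30L, 20L), times = 12), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:12)))
  des <- data.frame(sample_id = paste0("s", 1:12),
                    temperature_C = rep(c(5, 10, 15, 20), each = 3),
                    exposure = "ST", replicate = rep(1:3, 4))
  deg <- call_degs(cts, des, exposure = "ST")
  expect_equal(deg$p_value, rep(1, 3))
  expect_false(any(deg$significant))
})

test_that("temperature patterns classify by slope sign", {
  temps <- c(5, 10, 15, 20)
  expect_equal(classify_temperature_pattern(c(1, 2, 3, 4), temps), "up")
  expect_equal(classify_temperature_pattern(c(4, 3, 2, 1), temps), "down")
  expect_equal(classify_temperature_pattern(c(2, 2, 2, 2), temps), "flat")
})

test_that("hypergeometric p equals exhaustive enumeration for N <= 12", {
  for (N in 4:12) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        k_max <- min(n, K)
        for (k in 0:k_max) {
          if (k < max(0, n - (N - K))) next
          genes <- sprintf("g%02d", 1:N)
          ann <- data.frame(gene_id = genes[1:K], term_id = "T1")
          deg <- c(genes[seq_len(k)],
                   if (n - k > 0) genes[K + seq_len(n - k)])
          if (length(deg) != n) next
          row <- hypergeometric_enrichment(deg, genes, ann)
          expect_equal(row$p_value, hyper_enum(N, K, n, k),
                       tolerance = 1e-12)
          expect_equal(row$k, k)
        }
      }
    }
  }
})

test_that("the worked enrichment example gives p = 1/42 and O/E = 2", {
  genes <- sprintf("g%02d", 1:20)
  ann <- generate_annotation(genes, n_terms = 4,
                             term_spec = list(N = 10, K = 5, n = 4, k = 4),
                             seed = 3)
  en <- hypergeometric_enrichment(attr(ann, "deg_set"),
                                  attr(ann, "universe"), ann)
  row <- en[en$term_id == "T_planted", ]
  expect_equal(row$p_value, 1 / 42)
  expect_equal(row$o_over_e, 2)
  expect_false(row$significant)  # O/E = 2 fails the > 3 rule

  # zero overlap: O/E = 0 and p = 1
  ann0 <- data.frame(gene_id = genes[11:15], term_id = "T0")
  en0 <- hypergeometric_enrichment(genes[1:4], genes, ann0)
  expect_equal(en0$o_over_e, 0)
  expect_equal(en0$p_value, 1)
})

test_that("enrichment significance needs both FDR < 0.05 and O/E > 3", {
  genes <- sprintf("g%03d", 1:200)
  ann <- data.frame(gene_id = genes[1:10], term_id = "T_strong")
  deg <- genes[1:10]  # all ten annotated genes in a 10-gene DEG set
  en <- hypergeometric_enrichment(deg, genes, ann)
  expect_gt(en$o_over_e, 3)
  expect_lt(en$fdr, 0.05)
  expect_true(en$significant)
  # an overlap equal to its expectation (O/E = 1) is never significant
  even <- hypergeometric_enrichment(
    c(genes[1], genes[101:109]), genes,
    data.frame(gene_id = genes[1:20], term_id = "T_even"))
  expect_equal(even$o_over_e, 1)
  expect_false(even$significant)
})

test_that("BH adjustment matches hand application and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(q[order(p)], sort(q))  # order-preserving with input
})
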
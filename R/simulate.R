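# Synthetic-data generators with planted ground truth. The life-history
# generator emulates the rearing design (generations P/F1/F2 at 5 and 15
# degrees, individually followed females); the expression generator emulates
# the temperature-gradient RNA-seq design (4 temperatures x 2 exposures x 3
# replicate pools) with planted monotone DEGs, batch factors, and injected
# outlier samples.

#' Configuration for the life-history cohort generator
#'
#' Group parameters are on the natural scale (days, eggs, probabilities);
#' durations are drawn lognormal with the given mean/sd, clutch sizes are
#' 1 + Poisson with an order-dependent mean (so clutch size can grow over
#' the life span), and each egg hatches independently with the group's
#' hatch probability. Defaults echo the rearing study's anchors: at 5
#' degrees females first oviposit around day 34 and eggs hatch in about 22
#' days, lay roughly fortnightly, and live much longer than at 15 degrees.
#'
#' @param groups Data frame with one row per generation x temperature group:
#'   `generation`, `temperature_C`, `n`, `lifespan_mean`, `lifespan_sd`,
#'   `age_first_mean`, `age_first_sd`, `interval_mean`, `interval_sd`,
#'   `clutch_mean`, `clutch_slope`, `hatch_prob`, `hatch_time_mean`,
#'   `hatch_time_sd`.
#' @param n_no_egg Planted females that never lay (fitness zero).
#' @param n_no_hatch Planted females whose eggs never hatch (fitness zero).
#' @param zero_group Generation and temperature the planted zero-fitness
#'   females belong to (default F2 at 15 degrees, as in the rearing study).
#' @return A list of class `lifehistory_config`.
#' @export
lifehistory_config <- function(groups = NULL, n_no_egg = 0, n_no_hatch = 0,
                               zero_group = list(generation = "F2",
                                                 temperature_C = 15)) {
  if (is.null(groups)) {
    groups <- data.frame(
      generation = c("F1", "F2", "F1", "F2"),
      temperature_C = c(5, 5, 15, 15),
      n = c(20, 20, 20, 20),
      lifespan_mean = c(240, 200, 80, 60),
      lifespan_sd = c(110, 95, 28, 22),
      age_first_mean = c(34, 36, 20, 22),
      age_first_sd = c(7, 7, 4, 4),
      interval_mean = c(14, 16, 9, 10),
      interval_sd = c(4, 4, 3, 3),
      clutch_mean = c(2.5, 2.4, 2.2, 2.0),
      clutch_slope = c(0.12, 0.12, 0.10, 0.10),
      hatch_prob = c(0.55, 0.45, 0.75, 0.60),
      hatch_time_mean = c(22, 21, 12, 11),
      hatch_time_sd = c(4, 4, 3, 3),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(groups$n >= 0), all(groups$hatch_prob >= 0),
            all(groups$hatch_prob <= 1), n_no_egg >= 0, n_no_hatch >= 0)
  structure(list(groups = groups, n_no_egg = n_no_egg,
                 n_no_hatch = n_no_hatch, zero_group = zero_group),
            class = "lifehistory_config")
}

#' Generate a synthetic life-history cohort with known truth
#'
#' Every generated female satisfies the record invariants (strictly
#' increasing oviposition days, last oviposition before death,
#' hatched <= laid). Ordinary females are guaranteed at least one hatched
#' egg, so exactly the planted no-egg and no-hatch females fall under the
#' fitness zero rule. Deterministic given `(config, seed)`.
#'
#' @param config A [lifehistory_config()].
#' @param seed Integer seed.
#' @return A list with `cohort` (list of [female_record()]) and `truth`
#'   (per-female group parameters and planted-zero labels, plus the group
#'   parameter table).
#' @export
generate_lifehistory_cohort <- function(config = lifehistory_config(),
                                        seed = 1) {
  stopifnot(inherits(config, "lifehistory_config"))
  with_seed(seed, {
    females <- list()
    truth_rows <- list()
    counter <- 0L

    make_female <- function(gp, kind) {
      counter <<- counter + 1L
      id <- sprintf("%s_%g_%03d", gp$generation, gp$temperature_C, counter)
      lifespan <- max(3, round(rlnorm_ms(1, gp$lifespan_mean, gp$lifespan_sd)))
      clutches <- list()
      if (kind != "no_egg") {
        day <- max(1, min(round(rlnorm_ms(1, gp$age_first_mean,
                                          gp$age_first_sd)), lifespan - 1))
        j <- 0L
        while (day <= lifespan) {
          j <- j + 1L
          mu <- max(0.1, gp$clutch_mean - 1 + gp$clutch_slope * (j - 1))
          eggs <- 1L + stats::rpois(1, mu)
          if (kind == "no_hatch") {
            hatched <- 0L
          } else if (j == 1L) {
            # Condition ordinary females on >= 1 hatched egg so the zero
            # rule applies to exactly the planted females.
            hatched <- 1L + stats::rbinom(1, eggs - 1L, gp$hatch_prob)
          } else {
            hatched <- stats::rbinom(1, eggs, gp$hatch_prob)
          }
          times <- if (hatched > 0) {
            pmax(1, round(rlnorm_ms(hatched, gp$hatch_time_mean,
                                    gp$hatch_time_sd)))
          } else {
            numeric(0)
          }
          clutches[[j]] <- clutch_record(j, day, eggs, hatched, times)
          day <- day + max(1, round(rlnorm_ms(1, gp$interval_mean,
                                              gp$interval_sd)))
        }
      }
      n_molts <- length(clutches) + 1L + stats::rpois(1, 1)
      f <- female_record(id, gp$generation, gp$temperature_C, lifespan,
                         n_molts, clutches)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        female_id = id, generation = gp$generation,
        temperature_C = gp$temperature_C, planted = kind,
        stringsAsFactors = FALSE
      )
      f
    }

    for (r in seq_len(nrow(config$groups))) {
      gp <- as.list(config$groups[r, ])
      for (i in seq_len(gp$n)) {
        females[[length(females) + 1L]] <- make_female(gp, "normal")
      }
    }
    zg <- config$zero_group
    zrow <- which(config$groups$generation == zg$generation &
                    config$groups$temperature_C == zg$temperature_C)
    if (!length(zrow) && (config$n_no_egg + config$n_no_hatch) > 0) {
      stop_glue("zero_group not present in the group table")
    }
    if (length(zrow)) {
      gp <- as.list(config$groups[zrow[1], ])
      for (i in seq_len(config$n_no_egg)) {
        females[[length(females) + 1L]] <- make_female(gp, "no_egg")
      }
      for (i in seq_len(config$n_no_hatch)) {
        females[[length(females) + 1L]] <- make_female(gp, "no_hatch")
      }
    }
    list(
      cohort = structure(females, class = c("tardigrade_cohort", "list")),
      truth = list(
        females = do.call(rbind, truth_rows),
        groups = config$groups
      )
    )
  })
}

#' Configuration for the expression experiment generator
#'
#' The default design mirrors the temperature-gradient protocol: control
#' temperature 5 degrees plus 10, 15 and 20 degrees, short- and long-term
#' exposure, three replicate pools per cell. Planted DEGs change their
#' expected log2 mean by `lfc_per_step` per 5-degree step (half up, half
#' down, monotone in temperature); all other genes share one mean across
#' groups. Counts are negative binomial with the configured dispersion.
#'
#' @param n_genes Number of genes (default 2000).
#' @param fraction_de Fraction of genes planted as DEGs (default 0.1).
#' @param lfc_per_step Log2 fold change per 5-degree step for planted DEGs
#'   (default 1, i.e., 8-fold from 5 to 20 degrees).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.1).
#' @param lib_size_range Library-size range, drawn uniformly (default 1e6
#'   to 2e6).
#' @param temperatures Numeric temperatures; the minimum is the control.
#' @param exposures Exposure labels (default ST and LT).
#' @param n_reps Replicates per temperature x exposure cell (default 3).
#' @param batch_sd SD (log2 scale) of per-gene batch effects; 0 disables
#'   batches.
#' @param n_outliers Number of injected outlier samples.
#' @param outlier_fold Fold shift applied to the shifted genes of an
#'   outlier sample (default 10).
#' @param outlier_gene_fraction Fraction of genes shifted in an outlier
#'   sample (default 0.5; a shift of every gene would be absorbed by
#'   library-size normalization).
#' @return A list of class `expression_config`.
#' @export
expression_config <- function(n_genes = 2000, fraction_de = 0.1,
                              lfc_per_step = 1, dispersion = 0.1,
                              lib_size_range = c(1e6, 2e6),
                              temperatures = c(5, 10, 15, 20),
                              exposures = c("ST", "LT"), n_reps = 3,
                              batch_sd = 0, n_outliers = 0,
                              outlier_fold = 10,
                              outlier_gene_fraction = 0.5) {
  stopifnot(fraction_de >= 0, fraction_de <= 1, dispersion > 0,
            n_genes > 0, n_reps > 0)
  structure(
    list(n_genes = n_genes, fraction_de = fraction_de,
         lfc_per_step = lfc_per_step, dispersion = dispersion,
         lib_size_range = lib_size_range, temperatures = temperatures,
         exposures = exposures, n_reps = n_reps, batch_sd = batch_sd,
         n_outliers = n_outliers, outlier_fold = outlier_fold,
         outlier_gene_fraction = outlier_gene_fraction),
    class = "expression_config"
  )
}

#' Generate a synthetic expression experiment with known truth
#'
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples), `design` (sample table
#'   with batch labels), and `truth` (`genes`: is_de, direction, per-step
#'   log2 fold change; `samples`: batch, is_outlier).
#' @export
generate_expression_experiment <- function(config = expression_config(),
                                           seed = 1) {
  stopifnot(inherits(config, "expression_config"))
  with_seed(seed, {
    temps <- sort(config$temperatures)
    design <- expand.grid(
      replicate = seq_len(config$n_reps),
      exposure = config$exposures,
      temperature_C = temps,
      stringsAsFactors = FALSE
    )
    design$sample_id <- sprintf("T%g_%s_R%d", design$temperature_C,
                                design$exposure, design$replicate)
    design <- design[, c("sample_id", "temperature_C", "exposure",
                         "replicate")]
    n_s <- nrow(design)
    n_g <- config$n_genes
    genes <- sprintf("g%04d", seq_len(n_g))

    # Batch: replicate pools processed in two runs (final replicate in the
    # second run) when batch effects are enabled.
    design$batch <- if (config$batch_sd > 0) {
      ifelse(design$replicate == max(design$replicate), "B", "A")
    } else {
      "A"
    }

    n_de <- round(config$fraction_de * n_g)
    if (config$lfc_per_step == 0) n_de <- 0L
    is_de <- rep(FALSE, n_g)
    if (n_de > 0) is_de[sample.int(n_g, n_de)] <- TRUE
    dir_sign <- integer(n_g)
    dir_sign[is_de] <- sample(c(-1L, 1L), sum(is_de), replace = TRUE)

    base_log2 <- stats::rnorm(n_g, mean = 5, sd = 2)
    prop <- 2^base_log2
    prop <- prop / sum(prop)

    step <- match(design$temperature_C, temps) - 1L
    batch_lfc <- if (config$batch_sd > 0) {
      stats::rnorm(n_g, 0, config$batch_sd)
    } else {
      numeric(n_g)
    }
    lib <- round(stats::runif(n_s, config$lib_size_range[1],
                              config$lib_size_range[2]))

    counts <- matrix(0, n_g, n_s, dimnames = list(genes, design$sample_id))
    for (s in seq_len(n_s)) {
      lfc_s <- dir_sign * config$lfc_per_step * step[s] +
        if (design$batch[s] == "B") batch_lfc else 0
      mu <- lib[s] * prop * 2^lfc_s
      counts[, s] <- stats::rnbinom(n_g, mu = mu,
                                    size = 1 / config$dispersion)
    }

    design$is_outlier <- FALSE
    if (config$n_outliers > 0) {
      out_idx <- sample.int(n_s, config$n_outliers)
      design$is_outlier[out_idx] <- TRUE
      n_shift <- round(config$outlier_gene_fraction * n_g)
      for (s in out_idx) {
        shifted <- sample.int(n_g, n_shift)
        counts[shifted, s] <- counts[shifted, s] * config$outlier_fold
      }
    }

    truth_genes <- data.frame(
      gene = genes, is_de = is_de,
      direction = ifelse(!is_de, "flat", ifelse(dir_sign > 0, "up", "down")),
      lfc_per_step = dir_sign * config$lfc_per_step,
      stringsAsFactors = FALSE
    )
    truth_samples <- design[, c("sample_id", "batch", "is_outlier")]
    design$is_outlier <- NULL
    list(counts = counts, design = design,
         truth = list(genes = truth_genes, samples = truth_samples))
  })
}

#' Generate a synthetic BLAST-style hit table for the grouping step
#'
#' Each contig with a protein assignment gets one true hit plus `n_decoys`
#' decoy hits with strictly lower bitscores, so the best-hit rule recovers
#' the true contig-to-protein map exactly. Contigs mapped to `NA` get no
#' hits and should come out as singleton genes.
#'
#' @param contig_map Named character vector: names are contig ids, values
#'   the true protein id (or `NA` for no hit).
#' @param n_decoys Decoy hits per contig (default 2).
#' @param seed Integer seed.
#' @return Data frame of 12-column hit records in the layout of
#'   [read_hits()], in shuffled row order.
#' @export
generate_hit_table <- function(contig_map, n_decoys = 2, seed = 1) {
  with_seed(seed, {
    rows <- list()
    decoy_pool <- paste0("decoy", seq_len(max(10, 3 * n_decoys)))
    for (contig in names(contig_map)) {
      protein <- contig_map[[contig]]
      if (is.na(protein)) next
      true_bs <- round(stats::runif(1, 250, 400), 1)
      add <- function(subject, bs) {
        rows[[length(rows) + 1L]] <<- data.frame(
          qseqid = contig, sseqid = subject,
          pident = round(stats::runif(1, 60, 100), 1),
          length = sample(100:900, 1), mismatch = sample(0:40, 1),
          gapopen = sample(0:5, 1), qstart = 1, qend = sample(200:900, 1),
          sstart = 1, send = sample(100:400, 1),
          evalue = 10^(-bs / 10), bitscore = bs,
          stringsAsFactors = FALSE
        )
      }
      add(protein, true_bs)
      if (n_decoys > 0) {
        decoys <- sample(setdiff(decoy_pool, protein), n_decoys)
        for (d in decoys) add(d, round(true_bs - stats::runif(1, 10, 100), 1))
      }
    }
    if (!length(rows)) {
      out <- utils::read.delim(text = "", header = FALSE)
    } else {
      out <- do.call(rbind, rows)
      out <- out[sample.int(nrow(out)), , drop = FALSE]
      rownames(out) <- NULL
    }
    out
  })
}

#' Generate an annotation table with a term of specified overlap
#'
#' Constructs a gene-to-term annotation whose first term has exactly the
#' hypergeometric configuration `(N, K, n, k)`: a universe of `N` genes of
#' which `K` carry the term, and a DEG set of `n` genes of which `k` carry
#' it. The resulting enrichment row is checkable against exact enumeration.
#' Additional background terms are annotated at random.
#'
#' @param genes Character vector of at least `N` gene ids.
#' @param n_terms Total number of terms including the constructed one.
#' @param term_spec List with `N`, `K`, `n`, `k` (and optional `term_id`).
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, `term_id`; attributes `"universe"`
#'   (the `N` universe genes) and `"deg_set"` (the `n` DEG genes).
#' @export
generate_annotation <- function(genes, n_terms = 5,
                                term_spec = list(N = 10, K = 5, n = 4, k = 4),
                                seed = 1) {
  N <- term_spec$N; K <- term_spec$K
  n <- term_spec$n; k <- term_spec$k
  if (is.null(K) || K < 1) stop_glue("term_spec$K must be >= 1")
  if (N > length(genes)) stop_glue("need at least N = ", N, " genes")
  if (n > N || K > N) stop_glue("infeasible term_spec: n and K must be <= N")
  if (k > min(n, K)) stop_glue("infeasible term_spec: k > min(n, K)")
  if (K - k > N - n) stop_glue("infeasible term_spec: K - k > N - n")
  with_seed(seed, {
    universe <- genes[seq_len(N)]
    deg_set <- universe[seq_len(n)]
    term_id <- term_spec$term_id %||% "T_planted"
    annotated <- c(deg_set[seq_len(k)],
                   if (K - k > 0) sample(setdiff(universe, deg_set), K - k))
    rows <- data.frame(gene_id = annotated, term_id = term_id,
                       stringsAsFactors = FALSE)
    for (i in seq_len(max(0, n_terms - 1))) {
      size <- sample(2:max(3, min(8, N)), 1)
      rows <- rbind(rows, data.frame(
        gene_id = sample(universe, min(size, N)),
        term_id = sprintf("T_bg%02d", i), stringsAsFactors = FALSE
      ))
    }
    rows <- unique(rows)
    attr(rows, "universe") <- universe
    attr(rows, "deg_set") <- deg_set
    rows
  })
}
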
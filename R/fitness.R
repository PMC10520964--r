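# Composite fitness score: the mean of four traits normalized to [0, 1]
# over the scored pool. Traits rewarded when high (fecundity, total hatched
# eggs) use plain min-max normalization; traits rewarded when low (mean
# hatching time, age at first oviposition) use the inverted form. Females
# that never laid, or none of whose eggs hatched, score zero outright.

#' Compute min-max normalization bounds for a trait
#'
#' Bounds are the minimum and maximum of the trait over all females in the
#' scored pool for which the trait is defined; females with an undefined
#' trait (NA) do not contribute.
#'
#' @param traits Trait table from [derive_traits()].
#' @param trait_name Name of a numeric column of `traits`.
#' @return A list with `trait`, `min`, `max` (class `normalization_bounds`).
#' @export
compute_bounds <- function(traits, trait_name) {
  if (!trait_name %in% names(traits)) {
    stop_glue("unknown trait: ", trait_name)
  }
  x <- traits[[trait_name]]
  x <- x[!is.na(x)]
  if (!length(x)) stop_glue("no defined values for trait '", trait_name, "'")
  structure(list(trait = trait_name, min = min(x), max = max(x)),
            class = "normalization_bounds")
}

#' Min-max normalize a value to [0, 1]
#'
#' Computes `(x - min) / (max - min)`, so the pool minimum maps to 0 and the
#' maximum to 1. When the bounds are degenerate (`max == min`) the trait
#' carries no information and every value maps to the neutral 0.5.
#'
#' @param x Value(s) to normalize; must lie within the bounds.
#' @param bounds Bounds from [compute_bounds()] or a list with `min`, `max`.
#' @return Normalized value(s) in [0, 1].
#' @export
minmax_normalize <- function(x, bounds) {
  check_in_bounds(x, bounds)
  if (bounds$max == bounds$min) return(rep(0.5, length(x)))
  (x - bounds$min) / (bounds$max - bounds$min)
}

#' Inverted min-max normalization
#'
#' Computes `1 - (x - min) / (max - min)`, so the pool minimum maps to 1 and
#' the maximum to 0; used for traits where smaller is fitter (hatching time,
#' age at first oviposition). Degenerate bounds map to 0.5.
#'
#' @inheritParams minmax_normalize
#' @return Normalized value(s) in [0, 1].
#' @export
inverted_minmax_normalize <- function(x, bounds) {
  check_in_bounds(x, bounds)
  if (bounds$max == bounds$min) return(rep(0.5, length(x)))
  1 - (x - bounds$min) / (bounds$max - bounds$min)
}

check_in_bounds <- function(x, bounds) {
  if (bounds$min > bounds$max) stop_glue("invalid bounds: min > max")
  bad <- x[!is.na(x) & (x < bounds$min | x > bounds$max)]
  if (length(bad)) {
    stop_glue("value ", bad[1], " outside bounds [", bounds$min, ", ",
              bounds$max, "] for trait '", bounds$trait %||% "?", "'")
  }
  invisible(TRUE)
}

#' Score a single female against a set of bounds
#'
#' Applies the zero rule first: a female that laid no eggs, or whose laid
#' eggs never hatched, is assigned a fitness score of exactly zero. Otherwise
#' the score is the mean of the four normalized components: fecundity and
#' total hatched eggs (min-max), mean hatching time and age at first
#' oviposition (inverted min-max). Components undefined for the female are
#' left out of the mean.
#'
#' @param trait_row One-row data frame from [derive_traits()].
#' @param bounds Named list of bounds for `fecundity`, `total_hatched_eggs`,
#'   `mean_hatching_time_days`, `age_at_first_oviposition_days`.
#' @return One-row data frame with the four components, the score, and a
#'   `zero_rule_applied` flag.
#' @export
score_female <- function(trait_row, bounds) {
  norm_or_na <- function(value, b, inverted) {
    if (is.na(value)) return(NA_real_)
    if (inverted) inverted_minmax_normalize(value, b)
    else minmax_normalize(value, b)
  }
  c_fec <- norm_or_na(trait_row$fecundity, bounds$fecundity, FALSE)
  c_hat <- norm_or_na(trait_row$total_hatched_eggs,
                      bounds$total_hatched_eggs, FALSE)
  c_time <- norm_or_na(trait_row$mean_hatching_time_days,
                       bounds$mean_hatching_time_days, TRUE)
  c_age <- norm_or_na(trait_row$age_at_first_oviposition_days,
                      bounds$age_at_first_oviposition_days, TRUE)
  zero_rule <- trait_row$fecundity == 0 || trait_row$total_hatched_eggs == 0
  comps <- c(c_fec, c_hat, c_time, c_age)
  score <- if (zero_rule) 0 else mean(comps[!is.na(comps)])
  data.frame(
    female_id = trait_row$female_id,
    generation = trait_row$generation,
    rearing_temperature_C = trait_row$rearing_temperature_C,
    c_fecundity = c_fec, c_hatched = c_hat,
    c_hatch_time = c_time, c_age_first = c_age,
    score = score, zero_rule_applied = zero_rule,
    stringsAsFactors = FALSE
  )
}

#' Score a cohort of females
#'
#' Normalization bounds are computed once over the scored pool (by default
#' all females supplied, pooling generations and rearing temperatures so the
#' scores share one scale) and each female is scored against them. With
#' `pool = "per-temperature"` bounds are computed within each rearing
#' temperature instead.
#'
#' @param traits Trait table from [derive_traits()]; callers wanting the
#'   filial generations only should subset before scoring.
#' @param pool `"all"` (default) or `"per-temperature"`.
#' @return Data frame with one row per female: the four components, the
#'   score, and the zero-rule flag.
#' @export
score_cohort <- function(traits, pool = c("all", "per-temperature")) {
  pool <- match.arg(pool)
  if (nrow(traits) < 2) stop_glue("need at least 2 females to score")
  score_pool <- function(tr) {
    bounds <- list(
      fecundity = compute_bounds(tr, "fecundity"),
      total_hatched_eggs = compute_bounds(tr, "total_hatched_eggs"),
      mean_hatching_time_days =
        safe_bounds(tr, "mean_hatching_time_days"),
      age_at_first_oviposition_days =
        safe_bounds(tr, "age_at_first_oviposition_days")
    )
    do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      score_female(tr[i, , drop = FALSE], bounds)
    }))
  }
  if (pool == "all") {
    out <- score_pool(traits)
  } else {
    parts <- split(traits, traits$rearing_temperature_C)
    out <- do.call(rbind, lapply(parts, score_pool))
  }
  rownames(out) <- NULL
  out[match(traits$female_id, out$female_id), , drop = FALSE]
}

# Bounds that tolerate a trait with no defined values (possible when every
# scored female falls under the zero rule): such a component is NA for
# everyone and never enters a mean.
safe_bounds <- function(traits, trait_name) {
  tryCatch(compute_bounds(traits, trait_name),
           error = function(e) structure(
             list(trait = trait_name, min = NA_real_, max = NA_real_),
             class = "normalization_bounds"))
}
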
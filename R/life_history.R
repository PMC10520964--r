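# Data model for individually reared females: each female carries her
# rearing metadata plus an ordered list of clutches (egg-laying events).

#' Construct a clutch record
#'
#' A clutch is a single oviposition event: the day it happened (days since the
#' female's birth), the number of eggs laid, how many of those hatched, and
#' the hatching time (days from oviposition) of each hatched egg.
#'
#' @param clutch_index Ordinal position of the clutch in the female's life
#'   (1 = first oviposition).
#' @param oviposition_day Day of laying, counted from the female's birth
#'   (day 0); must be positive.
#' @param eggs_laid Number of eggs in the clutch.
#' @param eggs_hatched Number of those eggs that hatched.
#' @param hatching_times Numeric vector of days from oviposition to hatching,
#'   one entry per hatched egg.
#' @return An object of class `clutch_record`.
#' @export
clutch_record <- function(clutch_index, oviposition_day, eggs_laid,
                          eggs_hatched, hatching_times = numeric(0)) {
  rec <- structure(
    list(
      clutch_index = as.integer(clutch_index),
      oviposition_day = as.numeric(oviposition_day),
      eggs_laid = as.integer(eggs_laid),
      eggs_hatched = as.integer(eggs_hatched),
      hatching_times = as.numeric(hatching_times)
    ),
    class = "clutch_record"
  )
  msg <- validate_clutch(rec)
  if (length(msg)) stop_glue("invalid clutch: ", paste(msg, collapse = "; "))
  rec
}

validate_clutch <- function(clutch) {
  v <- character(0)
  if (is.na(clutch$clutch_index) || clutch$clutch_index < 1) {
    v <- c(v, "clutch_index must be >= 1")
  }
  if (is.na(clutch$oviposition_day) || clutch$oviposition_day <= 0) {
    v <- c(v, "oviposition_day must be > 0")
  }
  if (is.na(clutch$eggs_laid) || clutch$eggs_laid < 0) {
    v <- c(v, "eggs_laid must be >= 0")
  }
  if (is.na(clutch$eggs_hatched) || clutch$eggs_hatched < 0) {
    v <- c(v, "eggs_hatched must be >= 0")
  }
  if (!is.na(clutch$eggs_hatched) && !is.na(clutch$eggs_laid) &&
      clutch$eggs_hatched > clutch$eggs_laid) {
    v <- c(v, "eggs_hatched exceeds eggs_laid")
  }
  if (length(clutch$hatching_times) != clutch$eggs_hatched) {
    v <- c(v, "hatching_times length must equal eggs_hatched")
  }
  if (any(clutch$hatching_times <= 0)) {
    v <- c(v, "hatching_times must all be > 0")
  }
  v
}

#' Construct a female life-history record
#'
#' @param female_id Unique identifier.
#' @param generation One of `"P"`, `"F1"`, `"F2"`.
#' @param rearing_temperature_C Rearing temperature in degrees Celsius
#'   (the study design uses 5 and 15).
#' @param lifespan_days Active life span in days (> 0).
#' @param n_molts Number of molts over the life span.
#' @param clutches List of [clutch_record()] objects, in oviposition order.
#' @return An object of class `female_record`.
#' @export
female_record <- function(female_id, generation, rearing_temperature_C,
                          lifespan_days, n_molts, clutches = list()) {
  rec <- structure(
    list(
      female_id = as.character(female_id),
      generation = as.character(generation),
      rearing_temperature_C = as.numeric(rearing_temperature_C),
      lifespan_days = as.numeric(lifespan_days),
      n_molts = as.integer(n_molts),
      clutches = clutches
    ),
    class = "female_record"
  )
  msg <- validate_female(rec)
  if (length(msg)) {
    stop_glue("invalid female '", rec$female_id, "': ",
              paste(msg, collapse = "; "))
  }
  rec
}

validate_female <- function(female) {
  v <- character(0)
  if (!female$generation %in% c("P", "F1", "F2")) {
    v <- c(v, "generation must be one of P, F1, F2")
  }
  if (is.na(female$lifespan_days) || female$lifespan_days <= 0) {
    v <- c(v, "lifespan_days must be > 0")
  }
  if (is.na(female$n_molts) || female$n_molts < 0) {
    v <- c(v, "n_molts must be >= 0")
  }
  for (cl in female$clutches) {
    cv <- validate_clutch(cl)
    if (length(cv)) {
      v <- c(v, paste0("clutch ", cl$clutch_index, ": ",
                       paste(cv, collapse = "; ")))
    }
  }
  days <- vapply(female$clutches, function(cl) cl$oviposition_day, numeric(1))
  if (length(days) > 1 && any(diff(days) <= 0)) {
    v <- c(v, "oviposition days must be strictly increasing")
  }
  if (length(days) && max(days) > female$lifespan_days) {
    v <- c(v, "oviposition after death day")
  }
  v
}

#' Validate a cohort
#'
#' Checks every female against the record invariants (non-negative counts,
#' hatched <= laid, strictly increasing oviposition days, no oviposition
#' after death) plus cohort-level uniqueness of female ids.
#'
#' @param cohort List of [female_record()] objects.
#' @return A data frame with columns `female_id` and `violation`; zero rows
#'   when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  ids <- vapply(cohort, function(f) f$female_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    out[[length(out) + 1L]] <- data.frame(
      female_id = d, violation = "duplicate female_id",
      stringsAsFactors = FALSE
    )
  }
  for (f in cohort) {
    for (msg in validate_female(f)) {
      out[[length(out) + 1L]] <- data.frame(
        female_id = f$female_id, violation = msg, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(female_id = character(0), violation = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read a cohort from a long-format CSV file
#'
#' The file has one row per clutch, with the female-level columns repeated;
#' females that never laid appear as a single row with empty clutch fields.
#' Required columns: `female_id`, `generation`, `rearing_temperature_C`,
#' `lifespan_days`, `n_molts`, `clutch_index`, `oviposition_day`,
#' `eggs_laid`, `eggs_hatched`, `hatching_times` (semicolon-separated days,
#' empty allowed).
#'
#' @param path Path to the CSV file.
#' @return A list of [female_record()] objects (class `tardigrade_cohort`).
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop_glue("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(hatching_times = "character",
                                          female_id = "character"))
  required <- c("female_id", "generation", "rearing_temperature_C",
                "lifespan_days", "n_molts", "clutch_index",
                "oviposition_day", "eggs_laid", "eggs_hatched",
                "hatching_times")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_glue("cohort file missing columns: ", paste(missing, collapse = ", "))
  }
  cohort_from_long(df)
}

#' Assemble a cohort from a long-format data frame
#'
#' @param df Data frame in the layout documented for [load_cohort()].
#' @return A list of [female_record()] objects (class `tardigrade_cohort`).
#' @export
cohort_from_long <- function(df) {
  parse_times <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
  }
  cohort <- list()
  for (id in unique(df$female_id)) {
    rows <- df[df$female_id == id, , drop = FALSE]
    clutch_rows <- rows[!is.na(rows$clutch_index), , drop = FALSE]
    clutches <- list()
    if (nrow(clutch_rows)) {
      clutch_rows <- clutch_rows[order(clutch_rows$oviposition_day), ,
                                 drop = FALSE]
      for (i in seq_len(nrow(clutch_rows))) {
        r <- clutch_rows[i, ]
        times <- parse_times(r$hatching_times)
        cl <- tryCatch(
          clutch_record(r$clutch_index, r$oviposition_day, r$eggs_laid,
                        r$eggs_hatched, times),
          error = function(e) {
            stop_glue("female '", id, "', row ",
                      rownames(clutch_rows)[i], ": ", conditionMessage(e))
          }
        )
        clutches[[length(clutches) + 1L]] <- cl
      }
    }
    f <- tryCatch(
      female_record(id, rows$generation[1], rows$rearing_temperature_C[1],
                    rows$lifespan_days[1], rows$n_molts[1], clutches),
      error = function(e) stop(conditionMessage(e), call. = FALSE)
    )
    cohort[[length(cohort) + 1L]] <- f
  }
  structure(cohort, class = c("tardigrade_cohort", "list"))
}

#' Write a cohort to long-format CSV
#'
#' @param cohort List of [female_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(f) {
    if (!length(f$clutches)) {
      return(data.frame(
        female_id = f$female_id, generation = f$generation,
        rearing_temperature_C = f$rearing_temperature_C,
        lifespan_days = f$lifespan_days, n_molts = f$n_molts,
        clutch_index = NA_integer_, oviposition_day = NA_real_,
        eggs_laid = NA_integer_, eggs_hatched = NA_integer_,
        hatching_times = "", stringsAsFactors = FALSE
      ))
    }
    do.call(rbind, lapply(f$clutches, function(cl) data.frame(
      female_id = f$female_id, generation = f$generation,
      rearing_temperature_C = f$rearing_temperature_C,
      lifespan_days = f$lifespan_days, n_molts = f$n_molts,
      clutch_index = cl$clutch_index, oviposition_day = cl$oviposition_day,
      eggs_laid = cl$eggs_laid, eggs_hatched = cl$eggs_hatched,
      hatching_times = paste(cl$hatching_times, collapse = ";"),
      stringsAsFactors = FALSE
    )))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Derive per-female life-history traits
#'
#' Computes, for each female: fecundity (total eggs laid over the life span),
#' number of ovipositions, mean interval between successive ovipositions, age
#' at first oviposition, mean egg hatching time, total hatched eggs, and
#' hatching percentage. Traits that are undefined for a female (e.g., age at
#' first oviposition when she never laid) are reported as `NA`, never imputed.
#'
#' @param cohort List of [female_record()] objects.
#' @param interval_aggregator How to summarise the successive
#'   inter-oviposition differences into one value per female; `"mean"`
#'   (default) or `"median"`.
#' @return A data frame with one row per female.
#' @export
derive_traits <- function(cohort, interval_aggregator = c("mean", "median")) {
  interval_aggregator <- match.arg(interval_aggregator)
  agg <- if (interval_aggregator == "mean") mean else stats::median
  rows <- lapply(cohort, function(f) {
    cls <- f$clutches
    if (length(cls) > 1) {
      ord <- order(vapply(cls, function(cl) cl$oviposition_day, numeric(1)))
      cls <- cls[ord]
    }
    days <- vapply(cls, function(cl) cl$oviposition_day, numeric(1))
    laid <- vapply(cls, function(cl) as.numeric(cl$eggs_laid), numeric(1))
    hatched <- vapply(cls, function(cl) as.numeric(cl$eggs_hatched),
                      numeric(1))
    times <- unlist(lapply(cls, function(cl) cl$hatching_times))
    fecundity <- sum(laid)
    total_hatched <- sum(hatched)
    data.frame(
      female_id = f$female_id,
      generation = f$generation,
      rearing_temperature_C = f$rearing_temperature_C,
      lifespan_days = f$lifespan_days,
      n_molts = f$n_molts,
      fecundity = fecundity,
      n_ovipositions = length(cls),
      mean_interoviposition_days =
        if (length(days) >= 2) agg(diff(days)) else NA_real_,
      age_at_first_oviposition_days =
        if (length(days)) days[1] else NA_real_,
      mean_hatching_time_days =
        if (length(times)) mean(times) else NA_real_,
      total_hatched_eggs = total_hatched,
      hatching_percentage =
        if (fecundity > 0) 100 * total_hatched / fecundity else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Clutch-level table for order-of-oviposition models
#'
#' One row per clutch, carrying the female's metadata, the clutch's position
#' in the oviposition order, its size (fertility), and its hatching outcome.
#' Used for models of fertility against oviposition order and of hatching
#' time / hatching percentage against clutch size.
#'
#' @param cohort List of [female_record()] objects.
#' @return A data frame with one row per clutch.
#' @export
clutch_table <- function(cohort) {
  rows <- lapply(cohort, function(f) {
    if (!length(f$clutches)) return(NULL)
    cls <- f$clutches
    ord <- order(vapply(cls, function(cl) cl$oviposition_day, numeric(1)))
    cls <- cls[ord]
    do.call(rbind, lapply(seq_along(cls), function(i) {
      cl <- cls[[i]]
      data.frame(
        female_id = f$female_id, generation = f$generation,
        rearing_temperature_C = f$rearing_temperature_C,
        oviposition_order = i,
        oviposition_day = cl$oviposition_day,
        clutch_size = cl$eggs_laid,
        eggs_hatched = cl$eggs_hatched,
        mean_hatching_time_days =
          if (length(cl$hatching_times)) mean(cl$hatching_times) else NA_real_,
        hatching_percentage =
          if (cl$eggs_laid > 0) 100 * cl$eggs_hatched / cl$eggs_laid
          else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}
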
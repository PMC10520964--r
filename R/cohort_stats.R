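# Effect analysis of life-history traits: generalized linear models with
# Wald z intervals for generation, rearing temperature, and their
# interaction (plus clutch-level models of oviposition order and clutch
# size), and a Kruskal-Wallis comparison of fitness scores among groups.

# Family assignment when family = "auto". The study reports GLMs without
# naming families; we assign by the support of the response: durations are
# gaussian-identity, counts poisson-log (switching to negative binomial when
# the Pearson dispersion exceeds 1.5), and hatching percentages
# binomial-logit weighted by the number of eggs.
duration_traits <- c("lifespan_days", "mean_interoviposition_days",
                     "age_at_first_oviposition_days",
                     "mean_hatching_time_days", "oviposition_day")
count_traits <- c("n_molts", "n_ovipositions", "fecundity",
                  "total_hatched_eggs", "clutch_size", "eggs_hatched")
proportion_traits <- c("hatching_percentage")

resolve_family <- function(response, family) {
  if (family != "auto") return(family)
  if (response %in% duration_traits) return("gaussian")
  if (response %in% count_traits) return("poisson")
  if (response %in% proportion_traits) return("binomial")
  stop_glue("cannot infer a family for response '", response,
            "'; give one of gaussian, poisson, negbin, binomial")
}

# Build the model frame: categorical predictors as factors with the study's
# reference levels (generation P, or F1 when P is absent; temperature 5),
# numeric predictors untouched. Rows with any missing value are dropped.
build_model_data <- function(data, response, predictors, weight_col = NULL) {
  md <- data.frame(.y = data[[response]])
  for (p in setdiff(unique(unlist(strsplit(predictors, ":", fixed = TRUE))),
                    "")) {
    if (p == "generation") {
      levs <- intersect(c("P", "F1", "F2"), unique(data$generation))
      md$generation <- factor(data$generation, levels = levs)
    } else if (p == "temperature") {
      temps <- sort(unique(data$rearing_temperature_C))
      md$temperature <- factor(data$rearing_temperature_C, levels = temps)
    } else if (p %in% names(data)) {
      md[[p]] <- data[[p]]
    } else {
      stop_glue("unknown predictor: ", p)
    }
  }
  if (!is.null(weight_col)) md$.w <- data[[weight_col]]
  md[stats::complete.cases(md), , drop = FALSE]
}

wald_table <- function(fit) {
  cf <- summary(fit)$coefficients
  est <- cf[, 1]
  se <- cf[, 2]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(0.975)
  data.frame(
    term = rownames(cf),
    estimate = unname(est),
    std_error = unname(se),
    ci_low = unname(est - zq * se),
    ci_high = unname(est + zq * se),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
}

#' Fit a generalized linear model for a life-history trait
#'
#' Fits the trait against the requested predictors (any of `generation`,
#' `temperature`, `generation:temperature`, `oviposition_order`,
#' `clutch_size`) and returns maximum-likelihood coefficient estimates with
#' 95% confidence intervals and p-values from the Wald z approximation.
#' Reference levels are generation P (F1 when no parental females are
#' present) and the lowest temperature.
#'
#' With `family = "auto"`, durations get a gaussian-identity model, counts a
#' poisson-log model upgraded to a negative-binomial-log model when the
#' Pearson dispersion exceeds `dispersion_switch`, and hatching percentages
#' a binomial-logit model weighted by eggs laid.
#'
#' @param data Trait table from [derive_traits()] or clutch table from
#'   [clutch_table()].
#' @param response Name of the response column.
#' @param predictors Character vector of model terms.
#' @param family `"auto"` (default), `"gaussian"`, `"poisson"`, `"negbin"`,
#'   or `"binomial"`.
#' @param dispersion_switch Pearson dispersion above which a poisson model
#'   is refit as negative binomial (default 1.5).
#' @return Data frame of effect estimates (one row per model term), with the
#'   fitted family in attribute `"family"` and the fit in `"fit"`.
#' @export
fit_trait_glm <- function(data, response,
                          predictors = c("generation", "temperature",
                                         "generation:temperature"),
                          family = "auto", dispersion_switch = 1.5) {
  fam <- resolve_family(response, family)
  rhs <- paste(predictors, collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))

  if (fam == "binomial") {
    # Percentage responses are modelled as per-egg hatching probability,
    # weighted by the number of eggs behind each percentage.
    wcol <- if ("clutch_size" %in% names(data)) "clutch_size" else "fecundity"
    md <- build_model_data(data, response, predictors, weight_col = wcol)
    md <- md[md$.w > 0, , drop = FALSE]
    if (!nrow(md)) stop_glue("no complete cases for response '", response, "'")
    md$.y <- md$.y / 100
    fit <- stats::glm(form, data = md, family = stats::binomial(),
                      weights = md$.w)
  } else if (fam == "gaussian") {
    md <- build_model_data(data, response, predictors)
    if (!nrow(md)) stop_glue("no complete cases for response '", response, "'")
    fit <- stats::glm(form, data = md, family = stats::gaussian())
  } else {
    md <- build_model_data(data, response, predictors)
    if (!nrow(md)) stop_glue("no complete cases for response '", response, "'")
    fit <- stats::glm(form, data = md, family = stats::poisson())
    if (fam == "poisson") {
      disp <- sum(stats::residuals(fit, type = "pearson")^2) /
        stats::df.residual(fit)
      if (is.finite(disp) && disp > dispersion_switch) fam <- "negbin"
    }
    if (fam == "negbin") {
      fit <- MASS::glm.nb(form, data = md)
    }
  }
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_glue("singular design: term(s) ", paste(bad, collapse = ", "),
              " not estimable")
  }
  out <- wald_table(fit)
  attr(out, "family") <- fam
  attr(out, "fit") <- fit
  out
}

#' Standardized GLM coefficients
#'
#' Refits the model of [fit_trait_glm()] on a standardized version of the
#' data: numeric predictors (and, for gaussian models, the response) are
#' centered and scaled to unit standard deviation; categorical predictors
#' are untouched. For count and proportion families only the predictors are
#' standardized, since their likelihoods require the original response.
#'
#' @inheritParams fit_trait_glm
#' @return Data frame of standardized effect estimates.
#' @export
standardized_coefficients <- function(data, response,
                                      predictors = c("generation",
                                                     "temperature",
                                                     "generation:temperature"),
                                      family = "auto",
                                      dispersion_switch = 1.5) {
  fam <- resolve_family(response, family)
  sdata <- data
  numeric_predictors <- intersect(c("oviposition_order", "clutch_size"),
                                  unique(gsub(":.*|.*:", "", predictors)))
  for (p in numeric_predictors) {
    if (stats::sd(sdata[[p]], na.rm = TRUE) == 0) {
      stop_glue("zero-variance predictor: ", p)
    }
    sdata[[p]] <- as.numeric(scale(sdata[[p]]))
  }
  if (fam == "gaussian") {
    if (stats::sd(sdata[[response]], na.rm = TRUE) == 0) {
      stop_glue("zero-variance response: ", response)
    }
    sdata[[response]] <- as.numeric(scale(sdata[[response]]))
  }
  fit_trait_glm(sdata, response, predictors, family = fam,
                dispersion_switch = dispersion_switch)
}

#' Kruskal-Wallis comparison of fitness scores among groups
#'
#' Rank-based omnibus test with midranks and the standard tie correction;
#' the p-value comes from the chi-square approximation with `k - 1` degrees
#' of freedom. Pairwise post-hoc comparisons use rank-sum (Wilcoxon) tests
#' with Bonferroni (default) or Holm adjustment.
#'
#' @param x Numeric vector of scores.
#' @param g Group labels, one per score (e.g., generation x temperature).
#' @param posthoc_adjust `"bonferroni"` (default) or `"holm"`.
#' @return A list of class `kw_result`: `H`, `df`, `p_value`, `group_ids`,
#'   and `posthoc` (symmetric matrix of adjusted pairwise p-values).
#' @export
kruskal_wallis <- function(x, g, posthoc_adjust = c("bonferroni", "holm")) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  g <- factor(g)
  if (nlevels(g) < 2) stop_glue("need at least 2 groups")
  if (length(x) != length(g)) stop_glue("x and g lengths differ")
  k <- nlevels(g)
  if (length(unique(x)) == 1) {
    H <- 0
    p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
  }
  levs <- levels(g)
  ph <- matrix(NA_real_, k, k, dimnames = list(levs, levs))
  diag(ph) <- 1
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  raw <- vapply(pairs, function(pr) {
    xi <- x[g == pr[1]]
    xj <- x[g == pr[2]]
    if (length(unique(c(xi, xj))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(xi, xj, exact = FALSE)$p.value)
  }, numeric(1))
  adj <- stats::p.adjust(raw, method = posthoc_adjust)
  for (i in seq_along(pairs)) {
    ph[pairs[[i]][1], pairs[[i]][2]] <- adj[i]
    ph[pairs[[i]][2], pairs[[i]][1]] <- adj[i]
  }
  structure(
    list(H = H, df = k - 1, p_value = p, group_ids = levs, posthoc = ph),
    class = "kw_result"
  )
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis rank sum test\n")
  cat(sprintf("  H = %.4g, df = %d, p = %.4g\n", x$H, x$df, x$p_value))
  cat("  groups:", paste(x$group_ids, collapse = ", "), "\n")
  invisible(x)
}
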
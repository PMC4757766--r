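# Driver model: IME strength (|b|) against biogeophysical predictors.
# Collinearity pruning by variance inflation factors, gamma GLM with log
# link, AICc all-subsets selection with two-way interaction screening,
# nested-model analysis of deviance, and hierarchical partitioning of
# explained deviance.

#' Iterative collinearity pruning by variance inflation factors
#'
#' Repeatedly removes the predictor with the highest VIF (binary categorical
#' predictors enter as single indicator columns) and refits until all
#' remaining VIFs fall below `threshold`. Perfectly collinear (aliased)
#' predictors have infinite VIF and are removed first. The rule is
#' deterministic: ties go to the earlier predictor in `predictors` order.
#'
#' @param table Data frame of predictors (rows = locations).
#' @param predictors Character vector of columns to consider.
#' @param threshold VIF threshold (default 3).
#' @param keep Predictors never removed (manual override, e.g. to force a
#'   mechanistically motivated retained set).
#' @return An `ime_vif_report`: list with `iterations` tibble (`step`,
#'   `removed`, `vif`, `remaining` list-column of named VIF vectors) and
#'   `retained`.
#' @export
vif_prune <- function(table, predictors, threshold = 3, keep = NULL) {
  stopifnot(all(predictors %in% names(table)))
  if (nrow(table) <= length(predictors) + 1) {
    stop_ime("Need n > number of predictors + 1 for VIF computation.")
  }
  current <- predictors
  steps <- list()
  step <- 0L
  repeat {
    vifs <- compute_vifs(table, current)
    removable <- setdiff(current, keep)
    if (length(removable) == 0) break
    cand <- vifs[removable]
    if (length(current) < 2 || all(is.finite(cand) & cand < threshold)) break
    worst <- removable[which.max(cand)]
    step <- step + 1L
    steps[[step]] <- tibble::tibble(step = step, removed = worst,
                                    vif = unname(vifs[worst]),
                                    remaining = list(vifs))
    current <- setdiff(current, worst)
    if (length(current) < 2) break
  }
  structure(list(
    iterations = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), removed = character(),
                     vif = numeric(), remaining = list()),
    retained = current, threshold = threshold
  ), class = "ime_vif_report")
}

# VIFs of a predictor set via car::vif on an auxiliary lm (the response does
# not enter the VIF). Aliased (perfectly collinear) predictors -> +Inf.
compute_vifs <- function(table, predictors) {
  if (length(predictors) < 2) {
    return(setNames(rep(1, length(predictors)), predictors))
  }
  dat <- table[predictors]
  # VIFs do not depend on the response; any non-degenerate deterministic
  # auxiliary response works (keeps vif_prune reproducible without touching
  # the RNG stream)
  i <- seq_len(nrow(dat))
  dat$.aux_response <- sin(1.3 * i) + cos(0.7 * i)
  fit <- lm(reformulate(predictors, ".aux_response"), data = dat)
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    vifs <- setNames(rep(NA_real_, length(predictors)), predictors)
    hit <- predictors[vapply(predictors, function(p) any(startsWith(aliased, p)), TRUE)]
    vifs[hit] <- Inf
    ok <- setdiff(predictors, hit)
    if (length(ok) >= 2) vifs[ok] <- compute_vifs(table, ok)
    else if (length(ok)) vifs[ok] <- 1
    return(vifs)
  }
  v <- car::vif(fit)
  if (is.matrix(v)) v <- v[, 1] # GVIF column for df > 1 terms
  v[predictors]
}

#' @export
print.ime_vif_report <- function(x, ...) {
  cat("<ime_vif_report> retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$iterations)) {
    for (i in seq_len(nrow(x$iterations))) {
      cat("  step", x$iterations$step[i], "removed",
          x$iterations$removed[i], "(VIF", signif(x$iterations$vif[i], 4), ")\n")
    }
  }
  invisible(x)
}

#' Fit a gamma GLM with log link for IME strength
#'
#' The response is the positive IME index |b| of the enhanced locations; the
#' gamma family with a log link models its strictly positive, right-skewed
#' variation. Reported alongside the fit: explained deviance
#' `D^2 = 1 - deviance/null deviance` and small-sample AICc.
#'
#' @param response Positive numeric vector (|b| per location).
#' @param table Data frame of predictors, rows aligned with `response`.
#' @param formula RHS formula of predictors, e.g.
#'   `~ geomorphic_type + reef_area + bathy_slope + population_status +
#'   reef_area:geomorphic_type`.
#' @return An `ime_glm` (a `glm` with extra fields `d2`, `aicc`, `k`).
#' @export
fit_gamma_glm <- function(response, table, formula) {
  if (any(!is.finite(response)) || any(response <= 0)) {
    stop_ime("All responses must be positive: the IME index enters as |b| ",
             "(positive transformation of the log-log slope).")
  }
  dat <- as.data.frame(table)
  dat$.response <- response
  f <- stats::update.formula(formula, .response ~ .)
  fit <- tryCatch(
    glm(f, data = dat, family = Gamma(link = "log")),
    error = function(e) stop_ime("Gamma GLM failed to fit: ", conditionMessage(e)),
    warning = function(w) {
      suppressWarnings(glm(f, data = dat, family = Gamma(link = "log")))
    }
  )
  if (!fit$converged) stop_ime("Gamma GLM did not converge.")
  fit$d2 <- 1 - fit$deviance / fit$null.deviance
  fit$k <- attr(logLik(fit), "df") # coefficients + dispersion
  fit$aicc <- aicc(fit)
  class(fit) <- c("ime_glm", class(fit))
  fit
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)`, with `k` counting every estimated
#' parameter including the gamma dispersion/shape.
#'
#' @param fit A fitted model with `logLik` (e.g. from [fit_gamma_glm()]), or
#'   a numeric AIC value (then supply `n` and `k`).
#' @param n,k Sample size and parameter count, when `fit` is a bare AIC.
#' @return The AICc value.
#' @export
aicc <- function(fit, n = NULL, k = NULL) {
  if (is.numeric(fit)) {
    aic <- fit
    stopifnot(!is.null(n), !is.null(k))
  } else {
    ll <- logLik(fit)
    aic <- AIC(fit)
    k <- attr(ll, "df")
    n <- stats::nobs(fit)
  }
  if (n - k - 1 <= 0) {
    stop_ime("AICc undefined: n - k - 1 = ", n - k - 1, " <= 0.")
  }
  aic + 2 * k * (k + 1) / (n - k - 1)
}

# All subsets of a character vector (including the empty set).
power_set <- function(x) {
  sets <- list(character(0))
  for (k in seq_along(x)) {
    sets <- c(sets, combn(x, k, simplify = FALSE))
  }
  sets
}

# Two-way interactions among `mains` whose factor-factor cells are all
# populated; returns list(ok = labels, dropped = tibble(label, reason)).
screen_interactions <- function(table, mains) {
  if (length(mains) < 2) return(list(ok = character(), dropped = tibble::tibble()))
  pairs <- combn(mains, 2, simplify = FALSE)
  ok <- character(); dropped <- list()
  for (p in pairs) {
    lab <- paste(p, collapse = ":")
    is_fac <- vapply(table[p], function(col) is.factor(col) || is.character(col), TRUE)
    if (all(is_fac)) {
      tab <- table(table[[p[1]]], table[[p[2]]])
      if (any(tab == 0)) {
        dropped[[length(dropped) + 1]] <- tibble::tibble(
          interaction = lab,
          reason = "empty factor-combination cell (effect not estimable)")
        next
      }
    }
    ok <- c(ok, lab)
  }
  list(ok = ok,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
         tibble::tibble(interaction = character(), reason = character()))
}

#' All-subsets model selection by AICc
#'
#' Fits gamma GLMs (log link) for every subset of the main effects and, when
#' `interactions = TRUE`, every admissible set of two-way interactions under
#' strong hierarchy (an interaction may only enter when both parents are in
#' the model). Interactions with an empty crossed factor cell are dropped
#' with a logged reason. Models are ranked by AICc (ties resolved toward
#' fewer parameters); the candidate set is all models within 2 AICc of the
#' best, and Akaike weights are computed over all fitted models.
#'
#' @inheritParams fit_gamma_glm
#' @param predictors Character vector of main-effect columns (at most 8).
#' @param interactions Include two-way interactions (default `FALSE`).
#' @return An `ime_ranking`: list with `models` tibble (`formula`, `k`,
#'   `aicc`, `delta_aicc`, `weight`, `candidate`), `best_fit` (refitted
#'   `ime_glm`), `dropped_interactions`, and `failed` (per-model errors).
#' @export
all_subsets_selection <- function(response, table, predictors,
                                  interactions = FALSE) {
  if (length(predictors) > 8) {
    stop_ime("All-subsets enumeration is limited to 8 main effects.")
  }
  scr <- if (interactions) screen_interactions(table, predictors) else
    list(ok = character(),
         dropped = tibble::tibble(interaction = character(), reason = character()))
  formulas <- list()
  for (mains in power_set(predictors)) {
    inter_avail <- scr$ok[vapply(scr$ok, function(lab) {
      all(strsplit(lab, ":")[[1]] %in% mains)
    }, TRUE)]
    for (ints in power_set(inter_avail)) {
      terms <- c(mains, ints)
      formulas[[length(formulas) + 1]] <-
        if (length(terms)) reformulate(terms) else ~1
    }
  }
  n <- length(response)
  rows <- vector("list", length(formulas))
  failed <- list()
  for (i in seq_along(formulas)) {
    fml <- formulas[[i]]
    res <- tryCatch(fit_gamma_glm(response, table, fml), error = identity)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1]] <- tibble::tibble(
        formula = deparse1(fml), error = conditionMessage(res))
      next
    }
    ac <- tryCatch(res$aicc, error = identity)
    if (!is.numeric(ac) || !is.finite(ac)) {
      failed[[length(failed) + 1]] <- tibble::tibble(
        formula = deparse1(fml), error = "AICc undefined (n - k - 1 <= 0)")
      next
    }
    rows[[i]] <- tibble::tibble(formula = deparse1(fml), k = res$k,
                                d2 = res$d2, aicc = ac)
  }
  models <- dplyr::bind_rows(rows)
  if (nrow(models) == 0) stop_ime("No model could be fitted.")
  models <- dplyr::arrange(models, .data$aicc, .data$k)
  models$delta_aicc <- models$aicc - models$aicc[1]
  rel <- exp(-models$delta_aicc / 2)
  models$weight <- rel / sum(rel)
  models$candidate <- models$delta_aicc <= 2
  best_fit <- fit_gamma_glm(response, table, as.formula(models$formula[1]))
  structure(list(
    models = models, best_fit = best_fit,
    dropped_interactions = scr$dropped,
    failed = if (length(failed)) dplyr::bind_rows(failed) else
      tibble::tibble(formula = character(), error = character())
  ), class = "ime_ranking")
}

#' @export
print.ime_ranking <- function(x, ...) {
  cat("<ime_ranking>", nrow(x$models), "models;",
      sum(x$models$candidate), "in the dAICc <= 2 candidate set\n")
  print(head(x$models, 5))
  invisible(x)
}

#' Nested-model analysis of deviance
#'
#' Chi-squared test on the scaled deviance difference between a nested and a
#' full model, with degrees of freedom equal to the difference in parameter
#' count. The deviance is scaled by the fuller model's Pearson dispersion
#' estimate. Either argument may also be a bare list with `deviance`,
#' `df.residual` (and optionally `dispersion`) so externally fitted models
#' (e.g. a GAM or a region-random-intercept GLMM refit of the same data) can
#' be compared.
#'
#' @param nested,full Fitted models (the nested model's terms must be a
#'   subset of the full model's) or deviance lists as described.
#' @return List with `statistic`, `df`, `p`, `dispersion`.
#' @export
deviance_test <- function(nested, full) {
  get_parts <- function(m) {
    if (inherits(m, "glm")) {
      list(deviance = m$deviance, df = m$df.residual,
           dispersion = sum(stats::residuals(m, "pearson")^2) / m$df.residual,
           labels = attr(terms(m), "term.labels"))
    } else {
      stopifnot(is.list(m), !is.null(m$deviance), !is.null(m$df.residual))
      list(deviance = m$deviance, df = m$df.residual,
           dispersion = m$dispersion, labels = NULL)
    }
  }
  a <- get_parts(nested); b <- get_parts(full)
  if (!is.null(a$labels) && !is.null(b$labels)) {
    if (!all(a$labels %in% b$labels)) {
      stop_ime("Models are not nested: terms ",
               paste(setdiff(a$labels, b$labels), collapse = ", "),
               " of the first model are absent from the second.",
               class = "ime_not_nested")
    }
  }
  df <- a$df - b$df
  if (df < 0) {
    stop_ime("`nested` has fewer residual df than `full`: arguments reversed?",
             class = "ime_not_nested")
  }
  disp <- if (!is.null(b$dispersion)) b$dispersion else 1
  stat <- max(0, (a$deviance - b$deviance) / disp)
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, dispersion = disp)
}

#' Hierarchical partitioning of explained deviance
#'
#' Fits gamma GLMs (log link) for all 2^k subsets of the main-effect
#' predictors and averages, over all orderings in which a predictor can be
#' added, the gain in explained deviance D^2 it brings. The independent
#' contribution of predictor j is
#' `I_j = sum over subsets S not containing j of
#' |S|! (k-|S|-1)! / k! * (D2(S + j) - D2(S))`,
#' and the I_j sum exactly to the full model's D^2. Interaction terms do not
#' enter this analysis.
#'
#' @inheritParams fit_gamma_glm
#' @param predictors Character vector of main effects (at most 6).
#' @param metric Goodness-of-fit used for the gains: `"d2"` (explained
#'   deviance, the default) or `"loglik"`.
#' @return An `ime_partition`: list with `contributions` tibble
#'   (`predictor`, `independent`, `joint`, `percent`), `total` (full-model
#'   D^2) and `subset_fits` (per-subset metric values).
#' @export
hierarchical_partition <- function(response, table, predictors,
                                   metric = c("d2", "loglik")) {
  metric <- match.arg(metric)
  k <- length(predictors)
  if (k > 6) stop_ime("Hierarchical partitioning is limited to 6 predictors (2^k fits).")
  if (k < 1) stop_ime("Need at least one predictor.")
  subsets <- power_set(predictors)
  key <- function(s) if (length(s) == 0) "(null)" else paste(sort(s), collapse = "|")
  gof <- setNames(numeric(length(subsets)), vapply(subsets, key, ""))
  for (s in subsets) {
    fml <- if (length(s)) reformulate(s) else ~1
    fit <- tryCatch(fit_gamma_glm(response, table, fml), error = function(e) {
      stop_ime("Subset fit failed for {", paste(s, collapse = ", "), "}: ",
               conditionMessage(e))
    })
    gof[key(s)] <- switch(metric, d2 = fit$d2, loglik = as.numeric(logLik(fit)))
  }
  indep <- setNames(numeric(k), predictors)
  for (j in predictors) {
    others <- setdiff(predictors, j)
    for (s in power_set(others)) {
      wgt <- factorial(length(s)) * factorial(k - length(s) - 1) / factorial(k)
      indep[j] <- indep[j] + wgt * (gof[key(c(s, j))] - gof[key(s)])
    }
  }
  total <- gof[key(predictors)] - if (metric == "loglik") gof[key(character(0))] else 0
  marginal <- vapply(predictors, function(j) gof[key(j)] -
                       if (metric == "loglik") gof[key(character(0))] else 0, 0)
  structure(list(
    contributions = tibble::tibble(
      predictor = predictors,
      independent = unname(indep),
      joint = unname(marginal - indep),
      percent = 100 * unname(indep) / sum(indep)
    ),
    total = unname(total), metric = metric, subset_gof = gof
  ), class = "ime_partition")
}

#' @export
print.ime_partition <- function(x, ...) {
  cat("<ime_partition> total explained (", x$metric, "):",
      signif(x$total, 4), "\n")
  print(x$contributions)
  invisible(x)
}
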
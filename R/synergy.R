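# Chou-Talalay median-effect analysis: fraction affected, (m, Dm) fits,
# combination indices, Fa-CI summaries.

#' Fraction affected from treated and control signals
#'
#' Converts an absorbance/viability readout to the fraction of cells
#' affected: `fa = 1 - treated/control`, with the solvent-only control set
#' to 100% survival. Values are clamped into the open interval
#' `(1e-6, 1 - 1e-6)` (with a warning) because the median-effect
#' log-linearisation is undefined at 0 and 1.
#'
#' @param treated_signal,control_signal Non-negative readouts; the control
#'   must be positive. Vectors recycle as usual.
#' @return Numeric vector of fractions affected.
#' @export
fraction_affected <- function(treated_signal, control_signal) {
  if (any(treated_signal < 0) || any(control_signal < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  if (any(control_signal == 0)) {
    stop("control signal must be positive", call. = FALSE)
  }
  fa <- 1 - treated_signal / control_signal
  clamped <- fa <= 1e-6 | fa >= 1 - 1e-6
  if (any(clamped)) {
    warning(sprintf("%d fraction-affected value(s) clamped into (0, 1)",
                    sum(clamped)), call. = FALSE)
  }
  clamp_open_unit(fa)
}

#' Fit the median-effect model to a dose-response table
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` log-linearises to
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)`; an ordinary least-squares
#' line on that scale yields the sigmoidicity `m` (slope) and the
#' median-effect dose `Dm = 10^(-intercept/m)` (the IC50 under this model).
#' Replicates are averaged in fa space per dose before the transform.
#'
#' @param table Data frame with columns `dose` (µmol/L, > 0) and `fa`
#'   (fraction affected in (0,1)); an optional `drug` column names the fit.
#' @return Object of class `median_effect_fit`: list with `drug`, `m`, `Dm`,
#'   `r` (correlation of the linear fit), `n_points` and `valid` (`FALSE`,
#'   with a warning, when the fitted slope is not positive).
#' @export
median_effect_fit <- function(table) {
  if (!all(c("dose", "fa") %in% names(table))) {
    stop("dose-response table needs columns dose and fa", call. = FALSE)
  }
  drug <- if ("drug" %in% names(table)) as.character(table$drug[[1L]]) else "drug"
  if (any(table$dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(table$fa <= 0 | table$fa >= 1)) {
    stop("fa values must lie strictly in (0, 1)", call. = FALSE)
  }
  fa_mean <- tapply(table$fa, table$dose, mean)
  doses <- as.numeric(names(fa_mean))
  fa_mean <- as.numeric(fa_mean)
  if (length(doses) < 2L) {
    stop("need at least 2 distinct doses to fit", call. = FALSE)
  }
  x <- log10(doses)
  y <- log10(fa_mean / (1 - fa_mean))
  if (stats::var(x) == 0) stop("zero dose variance", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("fraction affected identical at all doses; no effect gradient to fit",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[[1L]]
  m <- fit$coefficients[[2L]]
  valid <- TRUE
  if (m <= 0) {
    warning("fitted sigmoidicity m <= 0; dose-response is not cytotoxic",
            call. = FALSE)
    valid <- FALSE
  }
  structure(
    list(drug = drug, m = m, Dm = 10^(-intercept / m), r = stats::cor(x, y),
         n_points = length(doses), valid = valid),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median_effect_fit '%s': m = %.4g, Dm = %.4g umol/L, r = %.4f (%d doses)%s\n",
              x$drug, x$m, x$Dm, x$r, x$n_points,
              if (x$valid) "" else " [flagged: m <= 0]"))
  invisible(x)
}

#' Single-agent dose producing a given effect
#'
#' Inverts the median-effect equation: `Dx = Dm (fa/(1-fa))^(1/m)`.
#'
#' @param fit A [median_effect_fit()] (or list with `m` and `Dm`).
#' @param fa Fraction affected in (0, 1).
#' @return Dose in the units of `Dm`.
#' @export
dose_for_effect <- function(fit, fa) {
  if (is.null(fit$m) || is.null(fit$Dm) || fit$m <= 0 || fit$Dm <= 0) {
    stop("invalid median-effect fit (need m > 0, Dm > 0)", call. = FALSE)
  }
  if (any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index of one dose pair
#'
#' For a combination `(d1, d2)` producing observed effect `fa_obs`, the
#' combination index is `CI = d1/Dx1 + d2/Dx2` where `Dx_i` is the dose of
#' drug `i` alone that produces `fa_obs` (the mutually exclusive two-term
#' form; `nonexclusive = TRUE` adds the cross term `d1 d2/(Dx1 Dx2)`).
#' `CI < 1` indicates synergism, `CI = 1` additivity, `CI > 1` antagonism;
#' the additive call is made within `additive_tol` of 1.
#'
#' @param d1,d2 Doses of the two agents (µmol/L; either may be 0).
#' @param fa_obs Observed fraction affected of the combination.
#' @param fit1,fit2 [median_effect_fit()] objects for the single agents.
#' @param nonexclusive Add the mutually nonexclusive cross term.
#' @param additive_tol Half-width of the additive band around CI = 1.
#' @return Object of class `combination_point`: list with `d1`, `d2`,
#'   `fa_obs`, `Dx1`, `Dx2`, `CI`, `call`.
#' @export
combination_index <- function(d1, d2, fa_obs, fit1, fit2,
                              nonexclusive = FALSE, additive_tol = 0.05) {
  if (d1 < 0 || d2 < 0) stop("doses must be non-negative", call. = FALSE)
  Dx1 <- dose_for_effect(fit1, fa_obs)
  Dx2 <- dose_for_effect(fit2, fa_obs)
  ci <- d1 / Dx1 + d2 / Dx2
  if (nonexclusive) ci <- ci + (d1 * d2) / (Dx1 * Dx2)
  call_label <- if (abs(ci - 1) <= additive_tol) {
    "additive"
  } else if (ci < 1) {
    "synergism"
  } else {
    "antagonism"
  }
  structure(
    list(d1 = d1, d2 = d2, fa_obs = fa_obs, Dx1 = Dx1, Dx2 = Dx2,
         CI = ci, call = call_label),
    class = "combination_point"
  )
}

#' Fa-CI table and summary for a set of combination points
#'
#' Arranges combination points by fraction affected (the x axis of an Fa-CI
#' plot) and summarises the combination with the mean and sample standard
#' deviation of CI across points, the form in which combination synergy is
#' conventionally reported (mean CI ± SD).
#'
#' @param points List of `combination_point` objects (or a data frame with
#'   the same columns).
#' @return List with `table` (data frame sorted by `fa_obs`) and `summary`
#'   (list `mean_ci`, `sd_ci`, `n`, `sd_defined`; with a single point the SD
#'   is reported as 0 and flagged undefined).
#' @export
fa_ci_table <- function(points) {
  if (inherits(points, "combination_point")) points <- list(points)
  if (is.data.frame(points)) {
    tab <- points
  } else {
    if (length(points) == 0L) stop("no combination points", call. = FALSE)
    tab <- do.call(rbind, lapply(points, function(p) {
      data.frame(d1 = p$d1, d2 = p$d2, fa_obs = p$fa_obs, Dx1 = p$Dx1,
                 Dx2 = p$Dx2, CI = p$CI, call = p$call,
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- tab[order(tab$fa_obs, tab$d1, tab$d2), , drop = FALSE]
  rownames(tab) <- NULL
  n <- nrow(tab)
  sd_defined <- n > 1L
  list(
    table = tab,
    summary = list(
      mean_ci = mean(tab$CI),
      sd_ci = if (sd_defined) stats::sd(tab$CI) else 0,
      n = n,
      sd_defined = sd_defined
    )
  )
}

#' Read a single-agent viability plate table
#'
#' Expects TSV columns `drug`, `dose_umol_per_L`, `replicate`,
#' `viability_fraction` (treated/control); returns the table with fraction
#' affected `fa = 1 - viability` added (clamped into the open unit
#' interval).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `drug`, `dose`, `replicate`, `fa`.
#' @export
read_viability <- function(path) {
  tab <- read_tsv(path)
  need <- c("drug", "dose_umol_per_L", "replicate", "viability_fraction")
  if (!all(need %in% names(tab))) {
    stop("viability TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    drug = as.character(tab$drug),
    dose = as.numeric(tab$dose_umol_per_L),
    replicate = as.integer(tab$replicate),
    fa = clamp_open_unit(1 - as.numeric(tab$viability_fraction)),
    stringsAsFactors = FALSE
  )
}

#' Read a combination viability table
#'
#' Expects TSV columns `d1`, `d2`, `replicate`, `viability_fraction`;
#' optional `drug1`/`drug2` columns label the agents.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns (`drug1`, `drug2`,) `d1`, `d2`,
#'   `replicate`, `fa`.
#' @export
read_combination <- function(path) {
  tab <- read_tsv(path)
  need <- c("d1", "d2", "replicate", "viability_fraction")
  if (!all(need %in% names(tab))) {
    stop("combination TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    d1 = as.numeric(tab$d1),
    d2 = as.numeric(tab$d2),
    replicate = as.integer(tab$replicate),
    fa = clamp_open_unit(1 - as.numeric(tab$viability_fraction)),
    stringsAsFactors = FALSE
  )
  if (all(c("drug1", "drug2") %in% names(tab))) {
    out$drug1 <- as.character(tab$drug1)
    out$drug2 <- as.character(tab$drug2)
  }
  out
}
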
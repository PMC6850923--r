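# Synthetic ground-truth generators: landmark-gene profile collections with
# planted signature-reversing/mimicking drugs, median-effect dose-response
# data, and Loewe-type combination data with a known interaction strength.

#' Configuration for a synthetic profile collection
#'
#' Describes a landmark-gene collection: a standard-normal z-score
#' background (978 genes by default, the landmark count of bead-based
#' expression profiling) with replicate profiles per drug, a query signature
#' drawn from the gene universe, and optional planted drugs whose profiles
#' shift the signature genes by a known effect size.
#'
#' @param n_genes Number of genes (default 978).
#' @param drugs Named integer vector mapping drug name to replicate count
#'   (default 100 drugs with 3 replicates each, the triplicate treatment
#'   design typical of such collections).
#' @param planted_reversers Named numeric vector mapping drug name to effect
#'   size delta (z-units, > 0): their profiles shift signature up-tags by
#'   `-delta` and down-tags by `+delta`, i.e. they reverse the signature.
#' @param planted_mimickers As above with the signs flipped (signature
#'   mimickers).
#' @param signature_size Length-2 integer vector `c(up, down)` tag counts
#'   (default 100 each).
#' @param noise_sd Background standard deviation in z-units (default 1).
#' @param cell_line Cell-line label stamped on every profile.
#' @param seed Integer seed; identical seeds give bit-identical collections.
#' @return A list of class `collection_config`.
#' @export
collection_config <- function(n_genes = 978,
                              drugs = stats::setNames(rep(3L, 100),
                                                      sprintf("drug%03d", 1:100)),
                              planted_reversers = numeric(0),
                              planted_mimickers = numeric(0),
                              signature_size = c(up = 100, down = 100),
                              noise_sd = 1,
                              cell_line = "CELL1",
                              seed = 1) {
  if (length(signature_size) != 2L) {
    stop("signature_size must give up and down tag counts", call. = FALSE)
  }
  signature_size <- as.integer(signature_size)
  names(signature_size) <- c("up", "down")
  if (n_genes < sum(signature_size)) {
    stop("gene universe smaller than the signature", call. = FALSE)
  }
  if (is.null(names(drugs)) || any(!nzchar(names(drugs))) ||
      anyDuplicated(names(drugs))) {
    stop("drugs must be a uniquely named vector of replicate counts",
         call. = FALSE)
  }
  planted <- c(names(planted_reversers), names(planted_mimickers))
  if (!all(planted %in% names(drugs))) {
    stop("planted drug absent from the drug list", call. = FALSE)
  }
  if (anyDuplicated(planted)) {
    stop("a drug cannot be both reverser and mimicker", call. = FALSE)
  }
  if (any(c(planted_reversers, planted_mimickers) <= 0)) {
    stop("planted effect sizes must be > 0", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), drugs = drugs,
         planted_reversers = planted_reversers,
         planted_mimickers = planted_mimickers,
         signature_size = signature_size, noise_sd = noise_sd,
         cell_line = cell_line, seed = as.integer(seed)),
    class = "collection_config"
  )
}

#' Generate a synthetic profile collection with known ground truth
#'
#' Background z-scores are i.i.d. normal with mean 0 and `noise_sd`; a query
#' signature of the configured sizes is drawn from the gene universe; each
#' replicate profile of a planted reverser has its up-tag genes shifted by
#' `-delta` and its down-tag genes by `+delta` (mimickers: signs flipped).
#' The truth table records each drug's role so downstream recovery can be
#' checked.
#'
#' @param config A [collection_config()].
#' @return List with `collection` (a [profile_collection()] in z-score
#'   space), `signature` (a [gene_signature()]) and `truth` (data frame
#'   `drug`, `role`, `delta`).
#' @export
make_collection <- function(config) {
  stopifnot(inherits(config, "collection_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  drug_names <- names(config$drugs)
  meta <- data.frame(
    perturbagen = rep(drug_names, times = config$drugs),
    replicate = unlist(lapply(config$drugs, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  meta$cell_line <- config$cell_line
  meta$profile_id <- sprintf("%s:%s:%d", meta$perturbagen, meta$cell_line,
                             meta$replicate)
  n_prof <- nrow(meta)

  with_seed(config$seed, {
    tags <- sample(genes, sum(config$signature_size))
    sig <- gene_signature(
      "synthetic_signature",
      up = tags[seq_len(config$signature_size[["up"]])],
      down = tags[-seq_len(config$signature_size[["up"]])]
    )
    values <- matrix(stats::rnorm(config$n_genes * n_prof, sd = config$noise_sd),
                     nrow = config$n_genes, ncol = n_prof)
  })
  i_up <- match(sig$up, genes)
  i_down <- match(sig$down, genes)
  shift_drug <- function(values, drug, delta_up, delta_down) {
    cols <- which(meta$perturbagen == drug)
    values[i_up, cols] <- values[i_up, cols] + delta_up
    values[i_down, cols] <- values[i_down, cols] + delta_down
    values
  }
  for (d in names(config$planted_reversers)) {
    delta <- config$planted_reversers[[d]]
    values <- shift_drug(values, d, -delta, +delta)
  }
  for (d in names(config$planted_mimickers)) {
    delta <- config$planted_mimickers[[d]]
    values <- shift_drug(values, d, +delta, -delta)
  }

  role <- rep("background", length(drug_names))
  delta_all <- rep(0, length(drug_names))
  role[drug_names %in% names(config$planted_reversers)] <- "reverser"
  role[drug_names %in% names(config$planted_mimickers)] <- "mimicker"
  delta_all[match(names(config$planted_reversers), drug_names)] <-
    unname(config$planted_reversers)
  delta_all[match(names(config$planted_mimickers), drug_names)] <-
    unname(config$planted_mimickers)

  list(
    collection = profile_collection(values, genes, meta,
                                    value_space = "zscore"),
    signature = sig,
    truth = data.frame(drug = drug_names, role = role, delta = delta_all,
                       stringsAsFactors = FALSE)
  )
}

#' Configuration for synthetic median-effect dose-response data
#'
#' @param m_true True sigmoidicity (> 0).
#' @param Dm_true True median-effect dose (µmol/L, > 0).
#' @param doses Strictly increasing positive dose vector. The default is an
#'   8-point sqrt(2)-fold dilution series centred on `Dm_true` spanning
#'   about Dm/3.4 to 3.4 Dm, which keeps the noiseless fraction affected
#'   inside roughly 0.2-0.8 — the range where the log-linearised
#'   median-effect fit is well conditioned, matching conventional
#'   combination-assay dose design.
#' @param noise_sd Gaussian noise on fa (default 0.02, a typical triplicate
#'   viability-assay scatter).
#' @param n_replicates Replicates per dose (default 3).
#' @param drug Drug name.
#' @param seed Integer seed.
#' @return A list of class `dose_response_config`.
#' @export
dose_response_config <- function(m_true = 1.2, Dm_true = 2,
                                 doses = Dm_true * 2^seq(-1.75, 1.75, by = 0.5),
                                 noise_sd = 0.02, n_replicates = 3,
                                 drug = "drugA", seed = 1) {
  if (m_true <= 0) stop("m_true must be > 0", call. = FALSE)
  if (Dm_true <= 0) stop("Dm_true must be > 0", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(m_true = m_true, Dm_true = Dm_true, doses = doses,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         drug = drug, seed = as.integer(seed)),
    class = "dose_response_config"
  )
}

median_effect_fa <- function(D, m, Dm) 1 / (1 + (Dm / D)^m)

#' Generate a synthetic dose-response table
#'
#' Noiseless fractions affected follow the median-effect model
#' `fa = 1/(1 + (Dm/D)^m)`; Gaussian noise is added per replicate and the
#' result clamped into `(1e-6, 1 - 1e-6)`.
#'
#' @param config A [dose_response_config()].
#' @return Data frame with columns `drug`, `dose`, `replicate`, `fa`.
#' @export
make_dose_response <- function(config) {
  stopifnot(inherits(config, "dose_response_config"))
  fa0 <- median_effect_fa(config$doses, config$m_true, config$Dm_true)
  tab <- data.frame(
    drug = config$drug,
    dose = rep(config$doses, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = length(config$doses)),
    fa = rep(fa0, each = config$n_replicates),
    stringsAsFactors = FALSE
  )
  if (config$noise_sd > 0) {
    tab$fa <- with_seed(config$seed, {
      tab$fa + stats::rnorm(nrow(tab), sd = config$noise_sd)
    })
  }
  tab$fa <- clamp_open_unit(tab$fa)
  tab
}

#' Configuration for synthetic drug-combination data
#'
#' The generative model inverts a Loewe-type dose-additivity sum with a
#' scalar interaction strength `gamma`: for each dose pair the fraction
#' affected solves `d1/Dx1(fa) + d2/Dx2(fa) = gamma`, so the combination
#' index recovered downstream from noiseless data equals `gamma` at every
#' pair (`gamma < 1` synergism, `1` additivity, `> 1` antagonism).
#'
#' @param fit1,fit2 Ground-truth single-agent parameters: lists (or
#'   [median_effect_fit()] objects) with `m`, `Dm` and optionally `drug`.
#' @param dose_pairs Data frame with positive columns `d1`, `d2` (default: a
#'   two-fold dilution series around the two Dm values).
#' @param gamma Interaction strength (> 0; default 1, additive).
#' @param noise_sd Gaussian noise on fa (default 0.02).
#' @param n_replicates Replicates per dose pair (default 3).
#' @param seed Integer seed.
#' @return A list of class `combination_config`.
#' @export
combination_config <- function(fit1, fit2,
                               dose_pairs = NULL,
                               gamma = 1, noise_sd = 0.02,
                               n_replicates = 3, seed = 1) {
  for (f in list(fit1, fit2)) {
    if (is.null(f$m) || is.null(f$Dm) || f$m <= 0 || f$Dm <= 0) {
      stop("fits must provide m > 0 and Dm > 0", call. = FALSE)
    }
  }
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(dose_pairs)) {
    k <- 2^seq(-2, 2, by = 1)
    dose_pairs <- data.frame(d1 = fit1$Dm * k, d2 = fit2$Dm * k)
  }
  if (!all(c("d1", "d2") %in% names(dose_pairs))) {
    stop("dose_pairs needs columns d1 and d2", call. = FALSE)
  }
  if (any(dose_pairs$d1 < 0 | dose_pairs$d2 < 0) ||
      any(dose_pairs$d1 + dose_pairs$d2 <= 0)) {
    stop("dose pairs must be non-negative with a positive total",
         call. = FALSE)
  }
  structure(
    list(fit1 = fit1, fit2 = fit2, dose_pairs = dose_pairs, gamma = gamma,
         noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "combination_config"
  )
}

# Solve d1/Dx1(fa) + d2/Dx2(fa) = gamma for fa in (0, 1). The left side
# decreases monotonically from +Inf (fa -> 0) to 0 (fa -> 1), so a unique
# root exists whenever gamma > 0 and d1 + d2 > 0.
solve_combination_fa <- function(d1, d2, fit1, fit2, gamma) {
  g <- function(fa) {
    d1 / dose_for_effect(fit1, fa) + d2 / dose_for_effect(fit2, fa) - gamma
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  if (!(g(lo) > 0 && g(hi) < 0)) {
    stop(sprintf("no fa root in (0, 1) for dose pair (%g, %g)", d1, d2),
         call. = FALSE)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Generate a synthetic drug-combination table
#'
#' For each configured dose pair the noiseless fraction affected is solved
#' from the generative Loewe sum (see [combination_config()]); replicate
#' noise is added and values clamped into `(1e-6, 1 - 1e-6)`.
#'
#' @param config A [combination_config()].
#' @return Data frame with columns `drug1`, `drug2`, `d1`, `d2`,
#'   `replicate`, `fa`; attribute `fa_true` carries the noiseless values per
#'   pair.
#' @export
make_combination <- function(config) {
  stopifnot(inherits(config, "combination_config"))
  dp <- config$dose_pairs
  fa0 <- vapply(seq_len(nrow(dp)), function(i) {
    solve_combination_fa(dp$d1[[i]], dp$d2[[i]], config$fit1, config$fit2,
                         config$gamma)
  }, numeric(1))
  nm1 <- if (!is.null(config$fit1$drug)) config$fit1$drug else "drug1"
  nm2 <- if (!is.null(config$fit2$drug)) config$fit2$drug else "drug2"
  tab <- data.frame(
    drug1 = nm1, drug2 = nm2,
    d1 = rep(dp$d1, each = config$n_replicates),
    d2 = rep(dp$d2, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = nrow(dp)),
    fa = rep(fa0, each = config$n_replicates),
    stringsAsFactors = FALSE
  )
  if (config$noise_sd > 0) {
    tab$fa <- with_seed(config$seed, {
      tab$fa + stats::rnorm(nrow(tab), sd = config$noise_sd)
    })
  }
  tab$fa <- clamp_open_unit(tab$fa)
  attr(tab, "fa_true") <- fa0
  tab
}

#' Write a dose-response table as a viability plate TSV
#'
#' Columns: `drug`, `dose_umol_per_L`, `replicate`, `viability_fraction`
#' (`1 - fa`).
#'
#' @param table Output of [make_dose_response()] (or any data frame with
#'   `drug`, `dose`, `replicate`, `fa`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_viability <- function(table, path) {
  out <- data.frame(
    drug = table$drug,
    dose_umol_per_L = table$dose,
    replicate = table$replicate,
    viability_fraction = 1 - table$fa,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Write a combination table as TSV
#'
#' Columns: `drug1`, `drug2`, `d1`, `d2`, `replicate`,
#' `viability_fraction`.
#'
#' @param table Output of [make_combination()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combination <- function(table, path) {
  out <- data.frame(
    drug1 = table$drug1, drug2 = table$drug2,
    d1 = table$d1, d2 = table$d2,
    replicate = table$replicate,
    viability_fraction = 1 - table$fa,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}
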
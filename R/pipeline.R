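# Pipeline orchestration: simulate / screen / synergy runs that read and
# write plain-text files. All outputs are deterministically formatted so an
# identical configuration and seed reproduce byte-identical files.

log_msg <- function(...) message(sprintf(...))

#' Generate and write a full synthetic study to disk
#'
#' Runs the three synthetic generators and writes: the profile collection
#' (`collection.gct`), the query signature (`signature_up.grp`,
#' `signature_down.grp`, `signature.gmt`), the drug-role truth table
#' (`truth.tsv`), a single-agent viability plate (`dose_response.tsv`) and a
#' combination plate (`combination.tsv`).
#'
#' @param out_dir Output directory (created if absent).
#' @param collection_cfg A [collection_config()].
#' @param dose_cfgs List of [dose_response_config()] objects (default: two
#'   drugs sharing a plate).
#' @param combo_cfg A [combination_config()] (default: the first two dose
#'   configs combined additively).
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir,
                         collection_cfg = collection_config(),
                         dose_cfgs = NULL,
                         combo_cfg = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(dose_cfgs)) {
    dose_cfgs <- list(
      dose_response_config(m_true = 1.2, Dm_true = 2, drug = "drugA",
                           seed = collection_cfg$seed),
      dose_response_config(m_true = 1.0, Dm_true = 5, drug = "drugB",
                           seed = collection_cfg$seed + 1L)
    )
  }
  if (is.null(combo_cfg)) {
    c1 <- dose_cfgs[[1L]]; c2 <- dose_cfgs[[2L]]
    combo_cfg <- combination_config(
      fit1 = list(drug = c1$drug, m = c1$m_true, Dm = c1$Dm_true),
      fit2 = list(drug = c2$drug, m = c2$m_true, Dm = c2$Dm_true),
      seed = collection_cfg$seed + 2L
    )
  }

  sim <- make_collection(collection_cfg)
  paths <- c(collection = file.path(out_dir, "collection.gct"))
  write_gct(sim$collection, paths[["collection"]])
  grp <- write_grp(sim$signature, out_dir)
  paths <- c(paths, signature_up = unname(grp[["up"]]),
             signature_down = unname(grp[["down"]]),
             signature_gmt = file.path(out_dir, "signature.gmt"),
             truth = file.path(out_dir, "truth.tsv"),
             dose_response = file.path(out_dir, "dose_response.tsv"),
             combination = file.path(out_dir, "combination.tsv"))
  write_gmt(sim$signature, paths[["signature_gmt"]])
  write_tsv(sim$truth, paths[["truth"]])
  plate <- do.call(rbind, lapply(dose_cfgs, make_dose_response))
  write_viability(plate, paths[["dose_response"]])
  write_combination(make_combination(combo_cfg), paths[["combination"]])
  log_msg("simulate: wrote %d files to %s", length(paths), out_dir)
  invisible(paths)
}

#' Run the in-silico signature-reversal screen
#'
#' Reads a profile collection and an up/down query signature, converts
#' intensities to robust z-scores when needed, scores every profile with
#' the KS connectivity statistic, and ranks drugs by pre-ranked enrichment
#' of their profiles in the connectivity-ordered list. Writes
#' `connectivity.tsv` (per-profile s and c), `drug_ranking.tsv` (per-drug
#' ES/NES/p), `running_sum_top.tsv` (enrichment-plot trace of the
#' top-ranked drug) and `run_log.txt` (the configuration; no timestamps, so
#' reruns are byte-identical).
#'
#' @param collection Path to a GCT file, or a [profile_collection()].
#' @param signature A [gene_signature()], or character vector
#'   `c(up_path, down_path)` of GRP files.
#' @param out_dir Output directory.
#' @param reverse_query Score against the swapped signature so that
#'   signature-reversing drugs rank on top (default TRUE: the screen hunts
#'   reversers).
#' @param w Enrichment weight exponent (default 1).
#' @param n_perm Permutations (default 1000; at least 100).
#' @param seed Integer seed.
#' @return The drug-ranking data frame, invisibly.
#' @export
cmd_screen <- function(collection, signature, out_dir,
                       reverse_query = TRUE, w = 1, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(collection)) {
    log_msg("screen: reading collection from %s", collection)
    collection <- read_gct(collection)
  }
  if (is.character(signature)) {
    signature <- read_grp(signature[[1L]], signature[[2L]], "query")
  }
  if (collection$value_space == "intensity") {
    log_msg("screen: robust z-scoring %d x %d intensity matrix",
            nrow(collection$values), ncol(collection$values))
    collection <- robust_zscore(collection)
  }
  ranking <- screen_drugs(collection, signature, w = w, n_perm = n_perm,
                          seed = seed, reverse_query = reverse_query)
  conn <- attr(ranking, "connectivity")
  ranked <- attr(ranking, "ranked")

  write_tsv(conn, file.path(out_dir, "connectivity.tsv"))
  write_tsv(ranking, file.path(out_dir, "drug_ranking.tsv"))

  top_drug <- ranking$drug[[1L]]
  hits <- conn$profile_id[conn$perturbagen == top_drug]
  es <- enrichment_score(ranked, hits, w = w)
  write_tsv(
    data.frame(position = seq_along(es$running_sum),
               profile_id = ranked$ids,
               is_hit = as.integer(ranked$ids %in% hits),
               running_sum = es$running_sum,
               stringsAsFactors = FALSE),
    file.path(out_dir, "running_sum_top.tsv")
  )

  writeLines(c(
    "connscreen screen run",
    sprintf("seed: %d", seed),
    sprintf("w: %g", w),
    sprintf("n_perm: %d", n_perm),
    sprintf("reverse_query: %s", reverse_query),
    sprintf("signature: %s (%d up / %d down tags)", signature$name,
            length(signature$up), length(signature$down)),
    sprintf("profiles: %d, genes: %d", ncol(collection$values),
            nrow(collection$values)),
    sprintf("top drug: %s (NES = %s, p = %s)", top_drug,
            fmt_num(ranking$NES[[1L]]), fmt_num(ranking$p_perm[[1L]]))
  ), file.path(out_dir, "run_log.txt"))
  log_msg("screen: top drug %s, NES %.3f", top_drug, ranking$NES[[1L]])
  invisible(ranking)
}

#' Run the drug-combination synergy analysis
#'
#' Fits the median-effect model to every drug in the single-agent plate,
#' then computes combination indices for each dose pair of the combination
#' table (replicate viabilities averaged in fa space per pair). Drugs that
#' cannot be fitted are reported and skipped. Writes `fits.tsv`,
#' `fa_ci.tsv` and `ci_summary.tsv`.
#'
#' @param plate_tsv Path to the single-agent viability TSV
#'   (see [read_viability()]).
#' @param combos_tsv Path to the combination TSV (see [read_combination()]),
#'   or `NULL` for a fits-only run.
#' @param out_dir Output directory.
#' @param drug1,drug2 Agent names when the combination table does not carry
#'   `drug1`/`drug2` columns (defaults: first two fitted drugs).
#' @param nonexclusive Use the three-term mutually nonexclusive CI form.
#' @return List with `fits`, `fa_ci` (or NULL) and `summary` (or NULL),
#'   invisibly.
#' @export
cmd_synergy <- function(plate_tsv, combos_tsv = NULL, out_dir,
                        drug1 = NULL, drug2 = NULL, nonexclusive = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  plate <- read_viability(plate_tsv)
  fits <- list()
  for (d in unique(plate$drug)) {
    sub <- plate[plate$drug == d, , drop = FALSE]
    fit <- tryCatch(median_effect_fit(sub), error = function(e) e)
    if (inherits(fit, "error")) {
      log_msg("synergy: drug %s unfittable (%s); skipping", d,
              conditionMessage(fit))
    } else {
      fits[[d]] <- fit
    }
  }
  if (length(fits) == 0L) stop("no drug could be fitted", call. = FALSE)
  fits_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(drug = f$drug, m = f$m, Dm = f$Dm, r = f$r,
               n_points = f$n_points, valid = f$valid,
               stringsAsFactors = FALSE)
  }))
  rownames(fits_df) <- NULL
  write_tsv(fits_df, file.path(out_dir, "fits.tsv"))

  fa_ci <- NULL; summary <- NULL
  if (!is.null(combos_tsv)) {
    combos <- read_combination(combos_tsv)
    if (!"drug1" %in% names(combos)) {
      if (is.null(drug1)) drug1 <- names(fits)[[1L]]
      if (is.null(drug2)) drug2 <- names(fits)[[min(2L, length(fits))]]
      combos$drug1 <- drug1
      combos$drug2 <- drug2
    }
    miss <- setdiff(unique(c(combos$drug1, combos$drug2)), names(fits))
    if (length(miss)) {
      stop("combination references unfitted drug(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    # Average replicates in fa space per dose pair, then one CI per pair.
    key <- paste(combos$drug1, combos$drug2, combos$d1, combos$d2, sep = "\r")
    agg <- stats::aggregate(fa ~ key, data = cbind(combos, key = key), mean)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    points <- lapply(seq_len(nrow(agg)), function(i) {
      p <- parts[[i]]
      combination_index(as.numeric(p[[3L]]), as.numeric(p[[4L]]),
                        agg$fa[[i]], fits[[p[[1L]]]], fits[[p[[2L]]]],
                        nonexclusive = nonexclusive)
    })
    fc <- fa_ci_table(points)
    fa_ci <- fc$table
    summary <- fc$summary
    write_tsv(fa_ci, file.path(out_dir, "fa_ci.tsv"))
    write_tsv(
      data.frame(n_points = summary$n, mean_ci = summary$mean_ci,
                 sd_ci = summary$sd_ci,
                 sd_defined = summary$sd_defined),
      file.path(out_dir, "ci_summary.tsv")
    )
    log_msg("synergy: mean CI %.3f +/- %.3f over %d dose pairs",
            summary$mean_ci, summary$sd_ci, summary$n)
  }
  invisible(list(fits = fits_df, fa_ci = fa_ci, summary = summary))
}
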
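# Drug-level pre-ranked enrichment over the connectivity-ranked profile
# list: weighted running-sum ES, gene-set-label permutation null, NES and
# permutation p-values.

#' Build a ranked profile list from connectivity scores
#'
#' Orders profiles by the ranking metric (scaled connectivity), largest
#' first, with ties broken by profile id so the ranking is reproducible.
#'
#' @param profile_ids Character vector of profile ids.
#' @param metric Numeric ranking metric, one value per profile.
#' @return Object of class `ranked_profile_list`: list with `ids`, `metric`
#'   (sorted non-increasing) and `N`.
#' @export
ranked_profile_list <- function(profile_ids, metric) {
  profile_ids <- as.character(profile_ids)
  if (length(profile_ids) != length(metric)) {
    stop("ids and metric differ in length", call. = FALSE)
  }
  if (anyDuplicated(profile_ids)) {
    stop("profile ids must be unique", call. = FALSE)
  }
  ord <- order_c(-metric, profile_ids)
  structure(
    list(ids = profile_ids[ord], metric = as.numeric(metric[ord]),
         N = length(ord)),
    class = "ranked_profile_list"
  )
}

# Weighted ES evaluated only at hit positions: the positive extreme of the
# running sum occurs at a hit, the negative extreme just before one, so the
# full N-length walk need not be materialised. `pos` must be sorted hit
# ranks, `wts` the matching |metric|^w values.
es_from_positions <- function(pos, wts, N, zero_policy = c("error", "zero")) {
  zero_policy <- match.arg(zero_policy)
  t <- length(pos)
  NR <- sum(wts)
  if (NR == 0) {
    if (zero_policy == "error") {
      stop("all hit metric weights are zero (N_R = 0)", call. = FALSE)
    }
    return(list(ES = 0, peak_index = pos[[1L]]))
  }
  p_hit <- cumsum(wts) / NR
  miss_before <- (pos - seq_len(t)) / (N - t)
  dev_pos <- p_hit - miss_before              # deviation at each hit
  dev_neg <- miss_before - c(0, p_hit[-t])    # deviation just before each hit
  i_pos <- which.max(dev_pos)
  i_neg <- which.max(dev_neg)
  if (dev_pos[[i_pos]] >= dev_neg[[i_neg]]) {
    list(ES = dev_pos[[i_pos]], peak_index = pos[[i_pos]])
  } else {
    list(ES = -dev_neg[[i_neg]], peak_index = pos[[i_neg]] - 1L)
  }
}

#' Weighted running-sum enrichment score of a hit set
#'
#' Walks the ranked profile list accumulating `|r_i|^w / N_R` at hits and
#' `1/(N - N_h)` at misses, where `N_R` is the total hit weight; the ES is
#' the deviation `P_hit - P_miss` of maximal absolute value, keeping its
#' sign. With `w = 0` every hit contributes `1/N_h` and the ES depends only
#' on the hit positions.
#'
#' @param ranked A [ranked_profile_list()].
#' @param hits Character vector of hit profile ids (non-empty, proper
#'   subset of the ranked ids).
#' @param w Weight exponent on the ranking metric (default 1, the standard
#'   weighted form; 0 gives the classic unweighted KS form).
#' @return List with `ES`, `peak_index` and `running_sum` (the deviation at
#'   every position; ends at 0 up to rounding).
#' @export
enrichment_score <- function(ranked, hits, w = 1) {
  stopifnot(inherits(ranked, "ranked_profile_list"))
  hits <- as.character(hits)
  if (anyDuplicated(hits)) stop("duplicate hit ids", call. = FALSE)
  is_hit <- ranked$ids %in% hits
  n_h <- sum(is_hit)
  if (n_h != length(hits)) {
    stop("hit ids absent from the ranked list", call. = FALSE)
  }
  if (n_h == 0L || n_h == ranked$N) {
    stop("hits must be a non-empty proper subset of the ranked profiles",
         call. = FALSE)
  }
  wts <- abs(ranked$metric)^w
  wts[!is_hit] <- 0
  NR <- sum(wts)
  if (NR == 0 && w > 0) {
    stop("all hit metric weights are zero (N_R = 0)", call. = FALSE)
  }
  p_hit <- cumsum(wts) / NR
  p_miss <- cumsum(!is_hit) / (ranked$N - n_h)
  dev <- p_hit - p_miss
  # ties between the positive and negative extreme resolve to the positive
  i_pos <- which.max(dev)
  i_neg <- which.min(dev)
  if (dev[[i_pos]] >= -dev[[i_neg]]) {
    list(ES = dev[[i_pos]], peak_index = i_pos, running_sum = dev)
  } else {
    list(ES = dev[[i_neg]], peak_index = i_neg, running_sum = dev)
  }
}

#' Permutation null for the enrichment score
#'
#' Draws `n_perm` random hit sets of the observed size uniformly without
#' replacement from the ranked profiles (set-label permutation) and
#' recomputes the ES for each. Permuted sets whose hit weights are all zero
#' score 0.
#'
#' @param ranked A [ranked_profile_list()].
#' @param n_h Hit-set size.
#' @param w Weight exponent.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed; the global RNG state is left untouched.
#' @return Numeric vector of `n_perm` permuted enrichment scores.
#' @export
permutation_null <- function(ranked, n_h, w = 1, n_perm = 1000, seed = 1) {
  stopifnot(inherits(ranked, "ranked_profile_list"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (n_h < 1L || n_h >= ranked$N) {
    stop("hit-set size must satisfy 1 <= n_h < N", call. = FALSE)
  }
  absw <- abs(ranked$metric)^w
  N <- ranked$N
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, n_h))
      es_from_positions(pos, absw[pos], N, zero_policy = "zero")$ES
    }, numeric(1))
  })
}

#' Normalized enrichment score and permutation p-value
#'
#' The ES is normalised by the mean magnitude of the same-sign permuted
#' scores (the standard sign-stratified normalisation), and the p-value uses
#' the add-one rule `(1 + #{|ES*| >= |ES|, same sign}) / (1 + #same-sign)`,
#' which never reports exactly zero. Conventions for degenerate cases:
#' `ES = 0` reports `NES = 0`, `p = 1`; an ES whose sign never occurs in the
#' null reports a signed infinite NES with `p = 1/(n_perm + 1)`.
#'
#' @param ES Observed enrichment score.
#' @param null Numeric vector of permuted enrichment scores.
#' @return List with `NES` and `p_perm`.
#' @export
normalize_and_test <- function(ES, null) {
  if (length(null) == 0L) stop("empty permutation null", call. = FALSE)
  if (ES == 0) return(list(NES = 0, p_perm = 1))
  same <- null[sign(null) == sign(ES)]
  if (length(same) == 0L) {
    return(list(NES = sign(ES) * Inf, p_perm = 1 / (length(null) + 1)))
  }
  list(
    NES = ES / mean(abs(same)),
    p_perm = (1 + sum(abs(same) >= abs(ES))) / (1 + length(same))
  )
}

#' Screen all drugs of a collection for signature connectivity enrichment
#'
#' The full in-silico screen: every profile is scored against the query
#' signature, profiles are ranked by scaled connectivity, and each drug's
#' profiles (replicates across cell lines grouped together) are tested as a
#' hit set by pre-ranked enrichment with a set-label permutation null.
#' Drugs whose profiles all carry zero connectivity report `ES = NES = 0`,
#' `p = 1`.
#'
#' With `reverse_query = TRUE` the signature's sides are swapped before
#' scoring, so drugs whose profiles *reverse* the query state (query-up
#' genes pushed down and vice versa) receive positive connectivity and rise
#' to the top of the ranking — the polarity used when hunting for agents
#' that oppose a disease signature.
#'
#' @param collection A [profile_collection()] in z-score space.
#' @param signature A [gene_signature()].
#' @param w Weight exponent for the enrichment score (default 1).
#' @param n_perm Permutations per null (default 1000).
#' @param seed Integer seed controlling the permutation draws.
#' @param reverse_query Score against the swapped (anti-) signature.
#' @return Data frame sorted by NES descending with columns `drug`,
#'   `n_profiles`, `ES`, `NES`, `p_perm`, `rank`; attribute `connectivity`
#'   carries the per-profile score table, `ranked` the ranked profile list.
#' @export
screen_drugs <- function(collection, signature, w = 1, n_perm = 1000,
                         seed = 1, reverse_query = FALSE) {
  stopifnot(inherits(collection, "profile_collection"))
  if (length(unique(collection$meta$perturbagen)) < 2L) {
    stop("screening needs at least 2 distinct perturbagens", call. = FALSE)
  }
  sig <- if (reverse_query) reverse_signature(signature) else signature
  conn <- connectivity_scores(collection, sig)
  ranked <- ranked_profile_list(conn$profile_id, conn$c)
  absw <- abs(ranked$metric)^w

  drugs <- sort(unique(conn$perturbagen))
  hit_sets <- lapply(drugs, function(d) conn$profile_id[conn$perturbagen == d])
  n_h <- vapply(hit_sets, length, integer(1))

  # The permutation null depends only on the ranked metric and the hit-set
  # size, so one null per distinct size serves every drug of that size.
  sizes <- sort(unique(n_h))
  nulls <- lapply(seq_along(sizes), function(k) {
    permutation_null(ranked, sizes[[k]], w = w, n_perm = n_perm,
                     seed = seed + k - 1L)
  })
  names(nulls) <- as.character(sizes)

  res <- lapply(seq_along(drugs), function(i) {
    pos <- sort.int(match(hit_sets[[i]], ranked$ids))
    es <- es_from_positions(pos, absw[pos], ranked$N, zero_policy = "zero")
    nt <- normalize_and_test(es$ES, nulls[[as.character(n_h[[i]])]])
    data.frame(drug = drugs[[i]], n_profiles = n_h[[i]], ES = es$ES,
               NES = nt$NES, p_perm = nt$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order_c(-out$NES, out$drug), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "connectivity") <- conn
  attr(out, "ranked") <- ranked
  attr(out, "params") <- list(w = w, n_perm = n_perm, seed = seed,
                              reverse_query = reverse_query,
                              signature = sig$name)
  out
}
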
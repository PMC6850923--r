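# Kolmogorov-Smirnov connectivity scoring of ranked profiles against
# up/down signatures, with collection-wide scaling.

#' Signed Kolmogorov-Smirnov enrichment statistic for a tag set
#'
#' Given the ranks `V(1) < ... < V(t)` of `t` tag genes within a list of `n`
#' genes ordered from most up- to most down-regulated, computes
#' `a = max_j (j/t - V(j)/n)` (how far the tags run ahead of a uniform
#' spread, i.e. concentrate at the top) and
#' `b = max_j (V(j)/n - (j-1)/t)` (concentration at the bottom), and returns
#' the signed statistic `ks = a` if `a > b`, else `-b`.
#'
#' @param positions Strictly increasing integer ranks of the tag genes.
#' @param n Total number of genes in the ranked list.
#' @return An object of class `ks_result`: list with `a`, `b`, `ks`.
#' @export
ks_statistic <- function(positions, n) {
  t <- length(positions)
  if (t < 1L) stop("tag set is empty", call. = FALSE)
  if (n < t) stop("more tags than list positions", call. = FALSE)
  if (anyDuplicated(positions)) {
    stop("duplicate tag positions", call. = FALSE)
  }
  if (any(positions < 1L | positions > n)) {
    stop("tag positions out of range 1..n", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("tag positions must be strictly increasing", call. = FALSE)
  }
  j <- seq_len(t)
  a <- max(j / t - positions / n)
  b <- max(positions / n - (j - 1) / t)
  structure(list(a = a, b = b, ks = if (a > b) a else -b),
            class = "ks_result")
}

#' Raw connectivity score of one profile against a signature
#'
#' Computes the signed KS statistic separately for the up and down tags of
#' the signature within the profile's gene ranking. When the two statistics
#' disagree in sign — up tags toward one end, down tags toward the other —
#' the raw connectivity is `s = ks_up - ks_down`; when they agree (both tag
#' sets piled at the same end, which carries no directional information) the
#' score is set to zero. Positive `s` means the profile expresses the
#' signature (up tags high, down tags low); negative `s` means it reverses
#' it.
#'
#' @param ranked A `ranked_profile` from [rank_genes()].
#' @param signature A [gene_signature()] already restricted to the ranked
#'   universe (see [restrict_to_universe()]).
#' @return An object of class `connectivity_result`: list with `profile_id`,
#'   `ks_up`, `ks_down`, `s` and a slot `c` (NA until the collection is
#'   scaled).
#' @export
raw_connectivity <- function(ranked, signature) {
  stopifnot(inherits(ranked, "ranked_profile"),
            inherits(signature, "gene_signature"))
  for (side in c("up", "down")) {
    tags <- signature[[side]]
    if (length(tags) == 0L) {
      stop("signature ", side, " tag set is empty", call. = FALSE)
    }
    if (!all(tags %in% names(ranked$position))) {
      stop("signature ", side, " tags missing from ranked universe; ",
           "restrict the signature first", call. = FALSE)
    }
  }
  ks_up <- ks_statistic(sort(unname(ranked$position[signature$up])), ranked$n)
  ks_down <- ks_statistic(sort(unname(ranked$position[signature$down])), ranked$n)
  same_sign <- sign(ks_up$ks) == sign(ks_down$ks)
  s <- if (same_sign) 0 else ks_up$ks - ks_down$ks
  structure(
    list(profile_id = ranked$profile_id, ks_up = ks_up, ks_down = ks_down,
         s = s, c = NA_real_),
    class = "connectivity_result"
  )
}

#' Scale raw connectivity scores across a collection
#'
#' Positive raw scores are divided by the collection maximum `p`, negative
#' ones by the magnitude of the collection minimum `q`, so that scaled
#' scores `c` span `[-1, 1]` with at least one profile at an endpoint
#' whenever any raw score is non-zero.
#'
#' @param s Numeric vector of raw connectivity scores.
#' @return List with `c` (scaled scores) and `constants` (list `p`, `q`).
#' @export
scale_collection <- function(s) {
  if (length(s) == 0L) stop("no connectivity scores to scale", call. = FALSE)
  p <- max(c(s, 0))
  q <- min(c(s, 0))
  c_scaled <- numeric(length(s))
  pos <- s > 0
  neg <- s < 0
  if (any(pos)) c_scaled[pos] <- s[pos] / p
  if (any(neg)) c_scaled[neg] <- -(s[neg] / q)
  list(c = c_scaled, constants = list(p = p, q = q))
}

#' Connectivity scores of every profile in a collection
#'
#' Ranks each profile, computes the raw KS connectivity against the
#' signature, and scales across the collection.
#'
#' @param collection A [profile_collection()] in z-score space.
#' @param signature A [gene_signature()]; it is restricted to the
#'   collection's gene universe automatically.
#' @return Data frame with columns `profile_id`, `perturbagen`, `cell_line`,
#'   `replicate`, `s`, `c`, plus attributes `scaling` (list `p`, `q`) and
#'   `signature_name`.
#' @export
connectivity_scores <- function(collection, signature) {
  stopifnot(inherits(collection, "profile_collection"),
            inherits(signature, "gene_signature"))
  sig <- restrict_to_universe(signature, collection$genes)
  ids <- collection$meta$profile_id
  s <- vapply(ids, function(pid) {
    raw_connectivity(rank_genes(collection, pid), sig)$s
  }, numeric(1))
  scaled <- scale_collection(unname(s))
  out <- data.frame(
    profile_id = ids,
    perturbagen = collection$meta$perturbagen,
    cell_line = collection$meta$cell_line,
    replicate = collection$meta$replicate,
    s = unname(s),
    c = scaled$c,
    stringsAsFactors = FALSE
  )
  attr(out, "scaling") <- scaled$constants
  attr(out, "signature_name") <- sig$name
  out
}

#' Scaled-connectivity matrix for several signatures
#'
#' @param collection A [profile_collection()] in z-score space.
#' @param signatures List of [gene_signature()] objects.
#' @return Numeric matrix, profiles in rows, signatures in columns, holding
#'   the scaled connectivity `c`.
#' @export
connectivity_matrix <- function(collection, signatures) {
  stopifnot(length(signatures) >= 1L)
  cols <- lapply(signatures, function(sig) {
    connectivity_scores(collection, sig)$c
  })
  m <- do.call(cbind, cols)
  rownames(m) <- collection$meta$profile_id
  colnames(m) <- vapply(signatures, function(s) s$name, character(1))
  m
}
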
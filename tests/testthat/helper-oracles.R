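# Independent brute-force oracles used to validate the vectorised
# implementations. These are written literally from the defining formulas
# and share no code with the package internals.

# Signed KS tag-set statistic: evaluate both max-formulas at every j with an
# explicit loop.
oracle_ks <- function(positions, n) {
  t <- length(positions)
  a_terms <- numeric(t)
  b_terms <- numeric(t)
  for (j in seq_len(t)) {
    a_terms[[j]] <- j / t - positions[[j]] / n
    b_terms[[j]] <- positions[[j]] / n - (j - 1) / t
  }
  a <- max(a_terms)
  b <- max(b_terms)
  list(a = a, b = b, ks = if (a > b) a else -b)
}

# Weighted running-sum enrichment score: literal prefix walk over every
# position of the ranked list.
oracle_es <- function(ids, metric, hits, w) {
  N <- length(ids)
  is_hit <- ids %in% hits
  n_h <- sum(is_hit)
  nr <- sum(abs(metric[is_hit])^w)
  ph <- 0
  pm <- 0
  dev <- numeric(N)
  for (i in seq_len(N)) {
    if (is_hit[[i]]) {
      ph <- ph + abs(metric[[i]])^w / nr
    } else {
      pm <- pm + 1 / (N - n_h)
    }
    dev[[i]] <- ph - pm
  }
  # positive extreme wins exact ties, matching the documented convention
  hi <- max(dev)
  lo <- min(dev)
  es <- if (hi >= -lo) hi else lo
  list(ES = es, dev = dev)
}

# Build a tiny z-space collection with prescribed values (genes x profiles).
toy_collection <- function(values, perturbagen = NULL,
                           value_space = "zscore") {
  values <- as.matrix(values)
  genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(perturbagen)) {
    perturbagen <- sprintf("drug%02d", seq_len(ncol(values)))
  }
  meta <- data.frame(
    profile_id = sprintf("p%02d", seq_len(ncol(values))),
    perturbagen = perturbagen,
    cell_line = "CELL1",
    replicate = 1L,
    stringsAsFactors = FALSE
  )
  profile_collection(values, genes, meta, value_space = value_space)
}

# A ranked profile with gene ranks exactly as given by decreasing values.
toy_ranked_profile <- function(z) {
  col <- toy_collection(matrix(rep(z, 3), ncol = 3),
                        perturbagen = c("a", "b", "c"))
  rank_genes(col, "p01")
}
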
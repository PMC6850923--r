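# Profile collections: GCT I/O, robust z-scoring, per-profile gene ranking.

#' Construct a profile collection
#'
#' A profile collection is a gene-by-profile expression matrix together with
#' per-profile perturbagen metadata. Values may be raw intensities or robust
#' z-scores; the `value_space` flag records which, and downstream scoring
#' requires z-scores.
#'
#' @param values Numeric matrix, genes in rows, profiles in columns.
#' @param genes Character vector of unique gene identifiers (row names).
#' @param meta Data frame with one row per profile and columns `profile_id`,
#'   `perturbagen`, `cell_line`, `replicate`.
#' @param value_space Either `"intensity"` or `"zscore"`.
#' @return An object of class `profile_collection`.
#' @export
profile_collection <- function(values, genes, meta,
                               value_space = c("intensity", "zscore")) {
  value_space <- match.arg(value_space)
  values <- as.matrix(values)
  genes <- as.character(genes)
  if (nrow(values) != length(genes)) {
    stop("row count of `values` must equal length of `genes`", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("gene ids must be unique", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("profile_id", "perturbagen", "cell_line", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stop("profile metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != ncol(values)) {
    stop("column count of `values` must equal number of metadata rows",
         call. = FALSE)
  }
  meta$profile_id <- as.character(meta$profile_id)
  meta$perturbagen <- as.character(meta$perturbagen)
  meta$cell_line <- as.character(meta$cell_line)
  meta$replicate <- as.integer(meta$replicate)
  if (anyDuplicated(meta$profile_id)) {
    stop("profile ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(meta$perturbagen))) {
    stop("perturbagen names must be non-empty", call. = FALSE)
  }
  dimnames(values) <- list(genes, meta$profile_id)
  structure(
    list(values = values, genes = genes, meta = meta,
         value_space = value_space),
    class = "profile_collection"
  )
}

#' @export
print.profile_collection <- function(x, ...) {
  cat(sprintf("profile_collection: %d genes x %d profiles [%s space]\n",
              nrow(x$values), ncol(x$values), x$value_space))
  cat(sprintf("  perturbagens: %d distinct\n", length(unique(x$meta$perturbagen))))
  invisible(x)
}

#' @export
dim.profile_collection <- function(x) dim(x$values)

gct_parse_error <- function(path, line, msg) {
  stop(sprintf("malformed GCT file '%s' (line %d): %s", path, line, msg),
       call. = FALSE)
}

#' Read a GCT expression matrix
#'
#' Parses GCT 1.2 or 1.3 text files into a [profile_collection()] in
#' intensity space. Per-profile metadata is taken from the GCT 1.3 column
#' metadata rows `perturbagen`, `cell_line` and `replicate` when present;
#' otherwise the column id is parsed with the header convention
#' `perturbagen:cell_line:replicate`, falling back to the bare column id as
#' the perturbagen name.
#'
#' @param path Path to a `.gct` file.
#' @return A [profile_collection()] with `value_space = "intensity"`.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L) gct_parse_error(path, 1L, "fewer than 3 lines")
  version <- trimws(lines[[1L]])
  if (!version %in% c("#1.2", "#1.3")) {
    gct_parse_error(path, 1L, paste0("unsupported version line '", version, "'"))
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]))
  if (version == "#1.2") {
    if (length(dims) != 2L || anyNA(dims)) {
      gct_parse_error(path, 2L, "dimension line must hold two integers")
    }
    n_rmeta <- 0L; n_cmeta <- 0L
  } else {
    if (length(dims) != 4L || anyNA(dims)) {
      gct_parse_error(path, 2L, "dimension line must hold four integers")
    }
    n_rmeta <- dims[[3L]]; n_cmeta <- dims[[4L]]
  }
  nr <- dims[[1L]]; nc <- dims[[2L]]
  split_row <- function(i) strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]

  header <- split_row(3L)
  # 1.2 carries an id and a Description column; 1.3 carries id + n_rmeta
  # metadata columns before the profile ids.
  n_lead <- if (version == "#1.2") 2L else 1L + n_rmeta
  ids <- header[-seq_len(n_lead)]
  if (length(ids) != nc) {
    gct_parse_error(path, 3L, sprintf(
      "header names %d profiles but dimension line says %d", length(ids), nc))
  }

  cmeta <- list()
  for (k in seq_len(n_cmeta)) {
    row <- split_row(3L + k)
    if (length(row) != n_lead + nc) {
      gct_parse_error(path, 3L + k, "column-metadata row has wrong field count")
    }
    cmeta[[row[[1L]]]] <- row[-seq_len(n_lead)]
  }

  first_data <- 3L + n_cmeta + 1L
  if (length(lines) < first_data + nr - 1L) {
    gct_parse_error(path, length(lines),
                    sprintf("expected %d data rows, found %d", nr,
                            max(0L, length(lines) - first_data + 1L)))
  }
  genes <- character(nr)
  values <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    row <- split_row(first_data + i - 1L)
    if (length(row) != n_lead + nc) {
      gct_parse_error(path, first_data + i - 1L, sprintf(
        "data row has %d fields, expected %d", length(row), n_lead + nc))
    }
    genes[[i]] <- row[[1L]]
    v <- suppressWarnings(as.numeric(row[-seq_len(n_lead)]))
    if (anyNA(v)) {
      gct_parse_error(path, first_data + i - 1L, "non-numeric expression value")
    }
    values[i, ] <- v
  }

  meta <- data.frame(profile_id = ids, stringsAsFactors = FALSE)
  if (all(c("perturbagen", "cell_line", "replicate") %in% names(cmeta))) {
    meta$perturbagen <- cmeta$perturbagen
    meta$cell_line <- cmeta$cell_line
    meta$replicate <- as.integer(cmeta$replicate)
  } else {
    parts <- strsplit(ids, ":", fixed = TRUE)
    meta$perturbagen <- vapply(parts, `[`, character(1), 1L)
    meta$cell_line <- vapply(parts, function(p) {
      if (length(p) >= 2L) p[[2L]] else "NA"
    }, character(1))
    meta$replicate <- vapply(parts, function(p) {
      r <- if (length(p) >= 3L) suppressWarnings(as.integer(p[[3L]])) else 1L
      if (is.na(r)) 1L else r
    }, integer(1))
  }
  profile_collection(values, genes, meta, value_space = "intensity")
}

#' Write a profile collection as GCT 1.3 text
#'
#' Values are serialised at full double precision; perturbagen, cell line and
#' replicate are stored as column metadata rows so that
#' [read_gct()] round-trips the collection exactly.
#'
#' @param collection A [profile_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(collection, path) {
  stopifnot(inherits(collection, "profile_collection"))
  v <- collection$values
  meta <- collection$meta
  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(...) writeLines(paste(..., sep = "\t"), con, sep = "\n")
  writeLines(c("#1.3", paste(nrow(v), ncol(v), 0L, 3L, sep = "\t")), con)
  wline(paste(c("id", meta$profile_id), collapse = "\t"))
  wline(paste(c("perturbagen", meta$perturbagen), collapse = "\t"))
  wline(paste(c("cell_line", meta$cell_line), collapse = "\t"))
  wline(paste(c("replicate", meta$replicate), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(collection$genes[[i]], fmt_num(v[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Convert intensities to per-gene robust z-scores
#'
#' Each gene (row) is centred on its median across profiles and scaled by
#' 1.4826 times its median absolute deviation, the consistency-adjusted MAD
#' that estimates the standard deviation under normality. Genes whose MAD is
#' zero get a floor of 1e-9 (their z-scores become 0 for ties at the median)
#' and trigger a warning.
#'
#' @param collection A [profile_collection()] in intensity space.
#' @return The collection with `value_space = "zscore"`.
#' @export
robust_zscore <- function(collection) {
  stopifnot(inherits(collection, "profile_collection"))
  if (collection$value_space != "intensity") {
    stop("robust_zscore() expects a collection in intensity space",
         call. = FALSE)
  }
  v <- collection$values
  if (ncol(v) < 3L) {
    stop("robust z-scoring needs at least 3 profiles", call. = FALSE)
  }
  med <- apply(v, 1L, stats::median)
  dev <- v - med
  mad_raw <- apply(abs(dev), 1L, stats::median)
  n_zero <- sum(mad_raw == 0)
  if (n_zero > 0L) {
    warning(sprintf("%d gene(s) have zero MAD; using floor 1e-9", n_zero),
            call. = FALSE)
    mad_raw <- pmax(mad_raw, 1e-9)
  }
  z <- dev / (1.4826 * mad_raw)
  out <- collection
  out$values <- z
  dimnames(out$values) <- dimnames(v)
  out$value_space <- "zscore"
  out
}

#' Rank the genes of one profile by z-score
#'
#' Genes are sorted by z-score, highest first; ties are broken by ascending
#' gene id so ranks are reproducible. The result carries both the ordering
#' and the inverse map from gene id to rank, as used by the connectivity
#' statistic.
#'
#' @param collection A [profile_collection()] in z-score space.
#' @param profile_id Id of the profile to rank.
#' @return An object of class `ranked_profile` with fields `profile_id`,
#'   `order` (gene ids best-to-worst), `position` (named integer ranks) and
#'   `n` (gene count).
#' @export
rank_genes <- function(collection, profile_id) {
  stopifnot(inherits(collection, "profile_collection"))
  if (collection$value_space != "zscore") {
    stop("rank_genes() expects a collection in z-score space", call. = FALSE)
  }
  j <- match(profile_id, collection$meta$profile_id)
  if (is.na(j)) stop("unknown profile_id: ", profile_id, call. = FALSE)
  z <- collection$values[, j]
  ord <- order_c(-z, collection$genes)
  order_ids <- collection$genes[ord]
  position <- integer(length(ord))
  position[ord] <- seq_along(ord)
  names(position) <- collection$genes
  structure(
    list(profile_id = as.character(profile_id), order = order_ids,
         position = position, n = length(ord)),
    class = "ranked_profile"
  )
}
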
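# Up/down query gene signatures: construction, validation, GRP/GMT I/O.

#' Construct an up/down gene signature
#'
#' A signature is a pair of disjoint gene lists describing a transcriptional
#' state: genes over-expressed in the state (`up`) and genes under-expressed
#' (`down`). The connectivity statistic asks whether a profile's ranking
#' places the up tags high and the down tags low (or the reverse).
#'
#' @param name Signature name.
#' @param up,down Character vectors of gene ids; must be disjoint and free of
#'   internal duplicates.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up)) stop("duplicate gene in up list", call. = FALSE)
  if (anyDuplicated(down)) stop("duplicate gene in down list", call. = FALSE)
  overlap <- intersect(up, down)
  if (length(overlap)) {
    stop("up and down lists overlap: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(name = as.character(name), up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up / %d down tags\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Swap the up and down sides of a signature
#'
#' The anti-signature queries for profiles that reverse the original state:
#' a screen for signature reversers scores each profile against the swapped
#' signature so that reversing profiles come out with positive connectivity.
#'
#' @param signature A [gene_signature()].
#' @return The signature with sides exchanged and `name` suffixed `.rev`.
#' @export
reverse_signature <- function(signature) {
  stopifnot(inherits(signature, "gene_signature"))
  gene_signature(paste0(signature$name, ".rev"),
                 up = signature$down, down = signature$up)
}

#' Build a signature from a differential-expression table
#'
#' Takes the top genes by signed test statistic on each side: `up` holds the
#' `n_per_side` most positive statistics, `down` the most negative, after an
#' optional adjusted-p filter. When fewer genes qualify on a side than
#' requested, the available ones are used and a warning is raised.
#'
#' @param table Data frame with columns `gene_id`, `t_stat` and (optionally)
#'   `p_adj`.
#' @param n_per_side Number of tag genes to take per side (default 100, a
#'   conventional connectivity-query size).
#' @param p_max Optional adjusted-p cutoff applied before ranking
#'   (default 0.05); use `NULL` to skip filtering.
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
signature_from_de_table <- function(table, n_per_side = 100, p_max = 0.05,
                                    name = "de_signature") {
  if (!all(c("gene_id", "t_stat") %in% names(table))) {
    stop("DE table needs columns gene_id and t_stat", call. = FALSE)
  }
  if (n_per_side < 1) stop("n_per_side must be >= 1", call. = FALSE)
  if (anyDuplicated(table$gene_id)) {
    stop("DE table has duplicated gene ids", call. = FALSE)
  }
  if (any(!is.finite(table$t_stat))) {
    stop("DE table statistics must be finite", call. = FALSE)
  }
  tab <- table
  if (!is.null(p_max)) {
    if (!"p_adj" %in% names(tab)) {
      stop("p_max filtering requested but table has no p_adj column",
           call. = FALSE)
    }
    tab <- tab[tab$p_adj <= p_max, , drop = FALSE]
  }
  pos <- tab[tab$t_stat > 0, , drop = FALSE]
  neg <- tab[tab$t_stat < 0, , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("DE table must contain both positive and negative statistics ",
         "after filtering", call. = FALSE)
  }
  pos <- pos[order_c(-pos$t_stat, pos$gene_id), , drop = FALSE]
  neg <- neg[order_c(neg$t_stat, neg$gene_id), , drop = FALSE]
  if (nrow(pos) < n_per_side || nrow(neg) < n_per_side) {
    warning(sprintf(
      "requested %d tags per side but only %d positive / %d negative qualify",
      n_per_side, nrow(pos), nrow(neg)), call. = FALSE)
  }
  gene_signature(
    name,
    up = utils::head(pos$gene_id, n_per_side),
    down = utils::head(neg$gene_id, n_per_side)
  )
}

#' Read a differential-expression table from TSV
#'
#' Expects a header with columns `gene_id`, `t_stat`, `p_adj`.
#'
#' @param path Path to the TSV file.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("gene_id", "t_stat") %in% names(tab))) {
    stop("DE table TSV needs columns gene_id and t_stat", call. = FALSE)
  }
  tab$gene_id <- as.character(tab$gene_id)
  tab
}

read_grp_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines)) {
    stop("duplicate gene id in GRP file: ", path, call. = FALSE)
  }
  lines
}

#' Read a signature from a pair of GRP files
#'
#' GRP files hold one gene id per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path_up,path_down Paths to the up-tag and down-tag GRP files.
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
read_grp <- function(path_up, path_down, name) {
  gene_signature(name, up = read_grp_file(path_up),
                 down = read_grp_file(path_down))
}

#' Write a signature as a pair of GRP files
#'
#' @param signature A [gene_signature()].
#' @param dir Output directory (created if absent).
#' @return Named character vector with the `up` and `down` file paths.
#' @export
write_grp <- function(signature, dir) {
  stopifnot(inherits(signature, "gene_signature"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    up = file.path(dir, paste0(signature$name, "_up.grp")),
    down = file.path(dir, paste0(signature$name, "_down.grp"))
  )
  writeLines(signature$up, paths[["up"]])
  writeLines(signature$down, paths[["down"]])
  paths
}

#' Write signatures as a GMT gene-set file
#'
#' Each signature contributes two sets, `<name>_UP` and `<name>_DN`, in the
#' usual tab-separated layout: set name, description, member genes.
#'
#' @param signatures A [gene_signature()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(s) {
    c(paste(c(paste0(s$name, "_UP"), "up tags", s$up), collapse = "\t"),
      paste(c(paste0(s$name, "_DN"), "down tags", s$down), collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("GMT line with fewer than 3 fields", call. = FALSE)
    }
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][[1L]]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Restrict a signature to a measured gene universe
#'
#' Tags absent from `genes` are dropped with a warning stating how many were
#' lost per side; an error is raised if either side empties, since the
#' connectivity statistic needs both.
#'
#' @param signature A [gene_signature()].
#' @param genes Character vector of measured gene ids.
#' @return The restricted [gene_signature()].
#' @export
restrict_to_universe <- function(signature, genes) {
  stopifnot(inherits(signature, "gene_signature"))
  if (length(genes) == 0L) stop("gene universe is empty", call. = FALSE)
  up <- signature$up[signature$up %in% genes]
  down <- signature$down[signature$down %in% genes]
  lost_up <- length(signature$up) - length(up)
  lost_down <- length(signature$down) - length(down)
  if (lost_up + lost_down > 0L) {
    warning(sprintf("dropped %d up and %d down tag(s) absent from universe",
                    lost_up, lost_down), call. = FALSE)
  }
  if (length(up) == 0L || length(down) == 0L) {
    stop("signature side empty after restriction to universe", call. = FALSE)
  }
  gene_signature(signature$name, up = up, down = down)
}
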
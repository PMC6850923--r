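# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the previous global RNG
#' state, so that seeded generators do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic, locale-independent ordering for character keys.
order_c <- function(...) order(..., method = "radix")

# Clamp numeric values into the open interval (lo, 1 - lo); used for
# fraction-affected values ahead of log-linearisation.
clamp_open_unit <- function(x, lo = 1e-6) {
  pmin(pmax(x, lo), 1 - lo)
}

# Format numbers for TSV output: full double precision, C locale,
# deterministic across runs (required for byte-identical reruns).
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

# Write a data.frame as TSV with deterministic formatting. Numeric columns
# are rendered with fmt_num; everything else with as.character.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    out[[j]] <- if (is.double(out[[j]])) fmt_num(out[[j]]) else as.character(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
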
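#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Open a text connection, transparently handling gzip
#'
#' Detection uses the gzip magic bytes (0x1f 0x8b), never the file
#' extension, so `.tsv` files that are secretly gzipped (and vice versa)
#' are handled correctly.
#'
#' @param path file path
#' @return an open connection in text-read mode; caller must close it
#' @keywords internal
#' @noRd
open_auto <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  if (gz) gzfile(path, "rt") else file(path, "rt")
}

#' Read all lines of a possibly-gzipped text file
#' @noRd
read_lines_auto <- function(path) {
  con <- open_auto(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Split TSV lines into a character matrix
#' @noRd
split_tsv <- function(lines) {
  if (length(lines) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- max(lengths(parts))
  mat <- matrix(NA_character_, nrow = length(parts), ncol = ncol)
  for (i in seq_along(parts)) {
    mat[i, seq_along(parts[[i]])] <- parts[[i]]
  }
  mat
}

#' Deterministic 31-bit hash of a character string
#'
#' Polynomial rolling hash over UTF-8 code points, modulo a prime below
#' 2^31. Used to derive per-gene-pair RNG streams that are stable across
#' sessions and independent of iteration order.
#'
#' @noRd
hash31 <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  p <- 2147483629  # largest prime < 2^31 - 18
  h <- 0
  for (cp in utf8ToInt(s)) {
    h <- (h * 131 + cp) %% p
  }
  as.integer(h)
}

#' Derive a 31-bit seed from a master seed and identifying strings
#'
#' The derived stream depends only on (seed, parts...), so subsetting or
#' reordering a gene list never changes the null draws for a surviving
#' pair.
#'
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), as.character, character(1))
  p <- 2147483629
  h <- as.numeric(seed) %% p
  for (s in parts) {
    h <- (h * 1103515245 + hash31(s)) %% p
  }
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed, restoring state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Format numbers for deterministic text output
#'
#' Fixed 15 significant digits, no scientific notation drift across
#' platforms: identical inputs always serialize to identical bytes.
#' @noRd
fmt_num <- function(x) {
  formatC(x, digits = 15, format = "g", flag = "")
}

#' Stop with an aggregated error listing all problems at once
#' @noRd
stop_aggregate <- function(problems, context) {
  stop(context, ":\n", paste0("  - ", problems, collapse = "\n"), call. = FALSE)
}
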
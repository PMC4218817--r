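# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reported tables use conventional half-up rounding at a fixed number of
#' decimals (e.g. frequencies at 2 decimals, percentages at 1). Base
#' [round()] rounds half to even, which differs on exact .5 boundary cases,
#' so serialization goes through this helper. Full precision is always
#' retained internally; rounding happens only when a table is formatted.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(8.275, 2) # 8.28
#' round_half_up(90.909, 1) # 90.9
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# The twenty standard amino-acid one-letter codes, alphabetical.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Placeholder/ambiguity letters tolerated in sequences. They count toward
# protein length but never match any repeat residue.
AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

#' @noRd
assert_single_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L ||
      nchar(residue) != 1L || !(residue %in% AA_STANDARD)) {
    stop("`residue` must be a single standard amino-acid letter, got: ",
         deparse(substitute(residue)), " = ",
         paste(format(residue), collapse = ", "), call. = FALSE)
  }
  invisible(residue)
}

#' @noRd
assert_proteome_df <- function(x, arg = "records") {
  needed <- c("protein_id", "gene_id", "sequence")
  if (!is.data.frame(x) || !all(needed %in% names(x))) {
    stop("`", arg, "` must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Write a data frame as a TSV report
#'
#' All report tables are tab-separated UTF-8 with Unix newlines and a
#' mandatory header row (gene descriptions contain commas, so CSV is
#' avoided throughout).
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  # flatten list columns (e.g. run-length lists) into ;-joined strings
  is_list_col <- vapply(x, is.list, logical(1))
  for (nm in names(x)[is_list_col]) {
    x[[nm]] <- vapply(x[[nm]], function(v) paste(v, collapse = ";"), character(1))
  }
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

#' @noRd
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# Derive a 32-bit-safe stream seed from (seed, index); keeps per-record
# generation reproducible independently of order.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
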
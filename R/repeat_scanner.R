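# Core motif scanner: maximal homopolymer runs, triplet repeat units,
# non-overlapping PPG counting, and per-protein motif profiles.

#' Repeat units in a homopolymer run
#'
#' Converts the length of a consecutive amino-acid run into repeat units by
#' the triplet rule: a run of n identical residues contributes
#' \code{floor(n / 3)} units. Runs of 3, 4 or 5 prolines are one PPP unit;
#' 6, 7 or 8 prolines are two units, and so on. There is no upper cap:
#' proteins carrying dozens of units are legal.
#'
#' @param length integer vector of run lengths (each >= 0).
#' @return integer vector of unit counts, `floor(length / 3)`.
#' @examples
#' run_units(3:8) # 1 1 1 2 2 2
#' @seealso [find_runs()], [triplet_units()]
#' @export
run_units <- function(length) {
  if (!is.numeric(length) || any(is.na(length)) || any(length < 0) ||
      any(length != floor(length))) {
    stop("`length` must be non-negative integers", call. = FALSE)
  }
  as.integer(length %/% 3L)
}

#' Find maximal homopolymer runs of one residue
#'
#' Scans a normalized (uppercase) amino-acid sequence for maximal runs of a
#' single residue: stretches flanked on both sides by a different letter or
#' by the sequence boundary (boundaries behave as non-matching flanks, so a
#' protein beginning or ending with the run still counts). Ambiguity
#' letters (X, B, Z, U, O, J) never match a standard residue and therefore
#' always terminate a run.
#'
#' @param sequence single amino-acid string, uppercase.
#' @param residue single standard amino-acid letter.
#' @param min_length smallest run length reported (default 3, the repeat
#'   threshold used throughout the unit census).
#' @return data frame with one row per run and columns `residue`, `start`
#'   (1-based position of the first residue of the run), `length`, and
#'   `units` (`floor(length / 3)`), ordered by `start`.
#' @examples
#' find_runs("APPPPGA", "P") # one run: start 2, length 4, units 1
#' @export
find_runs <- function(sequence, residue, min_length = 3L) {
  assert_single_residue(residue)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  stopifnot(length(min_length) == 1L, min_length >= 1L)
  empty <- data.frame(residue = character(0), start = integer(0),
                      length = integer(0), units = integer(0))
  if (nchar(sequence) == 0L) return(empty)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars == residue)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  if (!any(keep)) return(empty)
  data.frame(
    residue = residue,
    start   = starts[keep],
    length  = r$lengths[keep],
    units   = run_units(r$lengths[keep])
  )
}

#' Count non-overlapping PPG motifs
#'
#' Counts occurrences of the exact tripeptide Pro-Pro-Gly by a left-to-right
#' scan. PPG cannot overlap itself (two match positions always differ by at
#' least 3), so the non-overlapping count equals the number of all match
#' positions.
#'
#' @param sequence single amino-acid string, uppercase.
#' @return integer count of PPG occurrences.
#' @examples
#' count_ppg("PPGAPPGPPG") # 3
#' count_ppg("PPPPG")      # 1
#' @export
count_ppg <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  if (nchar(sequence) < 3L) return(0L)
  hits <- gregexpr("PPG", sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' Triplet repeat units of one residue in a sequence
#'
#' Total repeat units contributed by all maximal runs of `residue`: the sum
#' of `floor(n / 3)` over maximal run lengths n. For proline this is the
#' protein's PPP unit count; the same rule applies to each of the twenty
#' amino acids in the tandem-repeat census.
#'
#' @inheritParams find_runs
#' @return integer unit total.
#' @examples
#' triplet_units("QQQQQQQ", "Q") # 2
#' @export
triplet_units <- function(sequence, residue) {
  runs <- find_runs(sequence, residue, min_length = 3L)
  as.integer(sum(runs$units))
}

# One pass over the character run-length encoding, returning everything the
# profile needs: P runs, per-residue triplet units, residue counts.
#' @noRd
scan_sequence <- function(sequence) {
  n <- nchar(sequence)
  counts <- integer(length(AA_STANDARD) + 1L)
  names(counts) <- c(AA_STANDARD, "other")
  units <- integer(length(AA_STANDARD))
  names(units) <- AA_STANDARD
  p_runs <- integer(0)
  if (n > 0L) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    r <- rle(chars)
    std <- r$values %in% AA_STANDARD
    tab <- tapply(r$lengths[std], r$values[std], sum)
    counts[names(tab)] <- as.integer(tab)
    counts["other"] <- n - sum(counts[AA_STANDARD])
    rep_runs <- std & r$lengths >= 3L
    if (any(rep_runs)) {
      utab <- tapply(r$lengths[rep_runs] %/% 3L, r$values[rep_runs], sum)
      units[names(utab)] <- as.integer(utab)
    }
    p_runs <- as.integer(r$lengths[r$values == "P" & r$lengths >= 3L])
  }
  list(length = n, counts = counts, units = units, p_run_lengths = p_runs,
       ppg = count_ppg(sequence))
}

#' Build per-protein motif profiles for a proteome
#'
#' Runs the repeat scanner over every protein and assembles the per-protein
#' motif profile: protein length, PPP units (sum of `floor(n/3)` over
#' maximal proline runs of length >= 3), non-overlapping PPG count, total
#' proline count, and the list of maximal proline run lengths. PPP and PPG
#' are counted by independent scans of the same sequence, so a substring
#' like PPPPG contributes one PPP unit and one PPG.
#'
#' The returned data frame also carries two matrix attributes used by the
#' proteome-level census: `triplet_units` (proteins x 20 residues, repeat
#' units per residue) and `aa_counts` (proteins x 21, residue counts with
#' ambiguity letters pooled under `"other"`).
#'
#' @param records proteome data frame as returned by
#'   [read_proteome_fasta()] (columns `protein_id`, `gene_id`, `sequence`,
#'   optionally `description`).
#' @return data frame with columns `protein_id`, `gene_id`, `description`,
#'   `length`, `ppp_units`, `ppg_count`, `proline_count`, and the list
#'   column `run_lengths` (maximal P-run lengths >= 3, ascending position
#'   order); attributes as described above.
#' @examples
#' prot <- data.frame(protein_id = "p1", gene_id = "g1",
#'                    description = "", sequence = "MAPPPGPPL")
#' scan_proteome(prot)$ppp_units # 1
#' @export
scan_proteome <- function(records) {
  assert_proteome_df(records)
  scans <- lapply(records$sequence, scan_sequence)
  unit_mat <- do.call(rbind, lapply(scans, `[[`, "units"))
  count_mat <- do.call(rbind, lapply(scans, `[[`, "counts"))
  rownames(unit_mat) <- rownames(count_mat) <- records$protein_id
  profiles <- data.frame(
    protein_id    = records$protein_id,
    gene_id       = records$gene_id,
    description   = if ("description" %in% names(records)) records$description else "",
    length        = vapply(scans, `[[`, integer(1), "length"),
    ppp_units     = as.integer(unit_mat[, "P"]),
    ppg_count     = vapply(scans, `[[`, integer(1), "ppg"),
    proline_count = as.integer(count_mat[, "P"]),
    stringsAsFactors = FALSE
  )
  profiles$run_lengths <- I(lapply(scans, `[[`, "p_run_lengths"))
  attr(profiles, "triplet_units") <- unit_mat
  attr(profiles, "aa_counts") <- count_mat
  profiles
}

#' Profile a single protein
#'
#' Convenience wrapper around [scan_proteome()] for one record; returns the
#' same one-row profile data frame.
#'
#' @param record one-row proteome data frame, or a list with at least
#'   `protein_id`, `gene_id`, `sequence`.
#' @return one-row profile data frame (see [scan_proteome()]).
#' @export
scan_protein <- function(record) {
  if (!is.data.frame(record)) {
    record <- data.frame(
      protein_id = record$protein_id, gene_id = record$gene_id,
      description = if (is.null(record$description)) "" else record$description,
      sequence = record$sequence, stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(record) == 1L)
  scan_proteome(record)
}
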
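# Proteome-level aggregation: unit totals and calibrated frequencies,
# run-length distribution tables, threshold gene groups, length statistics,
# and the 20-amino-acid composition / triplet-unit census.

#' Construct a proteome summary from integer totals
#'
#' The proteome summary carries the integer totals (PPP units, PPG motifs,
#' prolines, amino acids, ORFs) together with the calibrated frequencies
#' derived from them: PPP and PPG frequency per 10,000 amino acids and
#' proline usage as a percentage. Frequencies are held at full precision;
#' rounding happens only when a report table is formatted.
#'
#' @param species_label character label for the proteome.
#' @param n_orfs number of proteins (ORFs).
#' @param total_aa total residue count.
#' @param total_ppp_units total PPP units (sum of `floor(n/3)` over maximal
#'   proline runs).
#' @param total_ppg total non-overlapping PPG motifs.
#' @param total_proline total proline residues.
#' @return object of class `proteome_summary`: a list with the fields above
#'   plus `ppp_freq_per_1e4`, `ppg_freq_per_1e4`, `proline_pct`.
#' @seealso [summarize_proteome()]
#' @export
proteome_summary <- function(species_label, n_orfs, total_aa,
                             total_ppp_units, total_ppg, total_proline) {
  stopifnot(total_aa > 0, n_orfs > 0,
            total_ppp_units >= 0, total_ppg >= 0, total_proline >= 0)
  out <- list(
    species_label = species_label,
    n_orfs = as.integer(n_orfs),
    total_aa = total_aa,
    total_ppp_units = total_ppp_units,
    total_ppg = total_ppg,
    total_proline = total_proline,
    ppp_freq_per_1e4 = total_ppp_units / total_aa * 1e4,
    ppg_freq_per_1e4 = total_ppg / total_aa * 1e4,
    proline_pct = total_proline / total_aa * 100
  )
  class(out) <- "proteome_summary"
  out
}

#' @export
print.proteome_summary <- function(x, ...) {
  cat("Proteome summary:", x$species_label, "\n")
  cat(sprintf("  ORFs %d | aa %d | PPP units %d | PPG %d | Pro %d\n",
              x$n_orfs, x$total_aa, x$total_ppp_units, x$total_ppg,
              x$total_proline))
  cat(sprintf("  PPP %.2f /10^4 aa | PPG %.2f /10^4 aa | Pro %.2f%%\n",
              x$ppp_freq_per_1e4, x$ppg_freq_per_1e4, x$proline_pct))
  invisible(x)
}

#' Summarize a proteome's motif profiles
#'
#' Sums per-protein profiles into proteome totals and calibrated
#' frequencies: total PPP units, PPG motifs and prolines divided by the
#' total amino-acid count, scaled per 10,000 residues (per cent for
#' proline usage).
#'
#' @param profiles profile data frame from [scan_proteome()].
#' @param label species label for the summary.
#' @return [proteome_summary()] object.
#' @export
summarize_proteome <- function(profiles, label = "proteome") {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    stop("`profiles` must be a non-empty profile data frame", call. = FALSE)
  }
  proteome_summary(
    species_label = label,
    n_orfs = nrow(profiles),
    total_aa = sum(profiles$length),
    total_ppp_units = sum(profiles$ppp_units),
    total_ppg = sum(profiles$ppg_count),
    total_proline = sum(profiles$proline_count)
  )
}

#' Run-length distribution table
#'
#' Histograms maximal proline-run lengths into the buckets 3, 4, ..., 10
#' and `>10` (lengths >= 11), with the total run count and the share of
#' triple-proline runs (`pct_3p`, per cent of total). The exact lengths
#' falling in the `>10` bucket are preserved in `overflow_lengths`, so unit
#' totals stay recomputable from the table. On a repeat-free input the
#' table is all zero and `pct_3p` is reported as 0 with `pct_3p_defined =
#' FALSE` rather than an error, so batch runs over repeat-free fixtures do
#' not abort.
#'
#' @param x profile data frame from [scan_proteome()], or an integer vector
#'   of maximal run lengths (each >= 3).
#' @return object of class `run_length_table`: list with `counts` (named
#'   integer vector `"3"`..`"10"`, `">10"`), `total_runs`, `pct_3p`,
#'   `pct_3p_defined`, `overflow_lengths`.
#' @export
run_length_table <- function(x) {
  lengths <- if (is.data.frame(x)) unlist(x$run_lengths, use.names = FALSE)
             else x
  if (is.null(lengths)) lengths <- integer(0)
  stopifnot(is.numeric(lengths))
  if (any(lengths < 3L)) {
    stop("run lengths below the repeat threshold of 3", call. = FALSE)
  }
  buckets <- c(as.character(3:10), ">10")
  counts <- integer(length(buckets))
  names(counts) <- buckets
  capped <- pmin(lengths, 11L)
  tab <- table(factor(ifelse(capped >= 11L, ">10", as.character(capped)),
                      levels = buckets))
  counts[] <- as.integer(tab)
  total <- sum(counts)
  out <- list(
    counts = counts,
    total_runs = total,
    pct_3p = if (total > 0L) counts[["3"]] / total * 100 else 0,
    pct_3p_defined = total > 0L,
    overflow_lengths = sort(as.integer(lengths[lengths >= 11L]))
  )
  class(out) <- "run_length_table"
  out
}

#' Recompute unit totals from a run-length table
#'
#' Applies the triplet unit rule to a run-length distribution:
#' `sum over n = 3..10 of count(n) * floor(n/3)`, plus `floor(m/3)` for each
#' exact length m in the `>10` bucket. This is the consistency link between
#' the run-length distribution table and the proteome unit totals: applied
#' to the same proteome they must agree exactly.
#'
#' @param table `run_length_table` object.
#' @param overflow_lengths exact lengths of the runs in the `>10` bucket;
#'   defaults to the lengths stored in the table. Must have exactly as many
#'   entries as that bucket's count.
#' @return integer unit total.
#' @export
units_from_table <- function(table, overflow_lengths = table$overflow_lengths) {
  stopifnot(inherits(table, "run_length_table"))
  if (is.null(overflow_lengths)) overflow_lengths <- integer(0)
  if (length(overflow_lengths) != table$counts[[">10"]]) {
    stop("overflow_lengths has ", length(overflow_lengths),
         " entries but the >10 bucket holds ", table$counts[[">10"]],
         " runs", call. = FALSE)
  }
  n <- 3:10
  as.integer(sum(table$counts[as.character(n)] * (n %/% 3L)) +
             sum(run_units(overflow_lengths)))
}

#' Gene groups by repeat-unit threshold
#'
#' Compiles, for each threshold, the group of genes whose PPP unit count
#' (or PPG motif count) reaches the threshold, with the group size and its
#' percentage of the proteome. Groups nest: every member at threshold k+1
#' is a member at threshold k.
#'
#' @param profiles profile data frame from [scan_proteome()].
#' @param motif `"PPP"` (unit counts) or `"PPG"` (motif counts).
#' @param thresholds positive, distinct integer thresholds (default
#'   `c(1, 2, 3)`, the one-or-more / two-or-more / three-or-more groups).
#' @return data frame with columns `motif`, `threshold`, `count`,
#'   `pct_of_proteome`, and list column `member_gene_ids`; rows ordered by
#'   ascending threshold.
#' @export
gene_groups <- function(profiles, motif = c("PPP", "PPG"),
                        thresholds = c(1L, 2L, 3L)) {
  motif <- match.arg(motif)
  stopifnot(is.numeric(thresholds), all(thresholds >= 1),
            !anyDuplicated(thresholds))
  thresholds <- sort(as.integer(thresholds))
  vals <- if (motif == "PPP") profiles$ppp_units else profiles$ppg_count
  n <- nrow(profiles)
  rows <- lapply(thresholds, function(k) {
    members <- profiles$gene_id[vals >= k]
    data.frame(motif = motif, threshold = k, count = length(members),
               pct_of_proteome = length(members) / n * 100)
  })
  out <- do.call(rbind, rows)
  out$member_gene_ids <- I(lapply(thresholds, function(k) {
    sort(unique(profiles$gene_id[vals >= k]))
  }))
  out
}

#' Protein length distribution statistics
#'
#' Box-plot statistics of protein lengths: n, minimum, lower quartile,
#' median, mean, upper quartile, maximum. Quartiles use linear
#' interpolation between closest order statistics ([stats::quantile()]
#' type 7); the method is configurable and recorded in the result.
#'
#' @param x profile data frame (uses its `length` column) or a numeric
#'   vector of lengths.
#' @param quantile_type order-statistic interpolation rule passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return named list with `n`, `min`, `q1`, `median`, `mean`, `q3`, `max`,
#'   `quantile_type`.
#' @export
length_stats <- function(x, quantile_type = 7L) {
  lengths <- if (is.data.frame(x)) x$length else x
  if (length(lengths) == 0L) stop("no lengths to summarize", call. = FALSE)
  q <- stats::quantile(lengths, probs = c(0.25, 0.5, 0.75),
                       type = quantile_type, names = FALSE)
  list(n = length(lengths), min = min(lengths), q1 = q[1L], median = q[2L],
       mean = mean(lengths), q3 = q[3L], max = max(lengths),
       quantile_type = quantile_type)
}

#' Amino-acid composition and triplet-unit census
#'
#' Totals, across the proteome, the residue count, residue frequency,
#' triplet repeat units and triplet-unit frequency (units per residue of
#' the whole proteome) for each of the twenty standard amino acids.
#' Ambiguity letters are pooled under `"other"` with zero units, so counts
#' always sum to the total amino-acid count.
#'
#' @param profiles profile data frame from [scan_proteome()] (must carry
#'   its `aa_counts` and `triplet_units` attributes).
#' @return data frame with columns `residue`, `count`, `frequency`,
#'   `triplet_units`, `unit_freq_per_1e4`.
#' @export
aa_composition <- function(profiles) {
  counts <- attr(profiles, "aa_counts")
  units <- attr(profiles, "triplet_units")
  if (is.null(counts) || is.null(units)) {
    stop("`profiles` must come from scan_proteome() (census attributes missing)",
         call. = FALSE)
  }
  total_aa <- sum(counts)
  ctot <- colSums(counts)
  utot <- c(colSums(units), other = 0)
  data.frame(
    residue = names(ctot),
    count = as.integer(ctot),
    frequency = as.numeric(ctot) / total_aa,
    triplet_units = as.integer(utot[names(ctot)]),
    unit_freq_per_1e4 = as.numeric(utot[names(ctot)]) / total_aa * 1e4,
    row.names = NULL
  )
}
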
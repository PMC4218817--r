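# Report tables and pipeline entry points. Tables are TSV, UTF-8, Unix
# newlines, header row mandatory; numbers are rounded half-up to the
# printed precision only at serialization.

#' Format the run-length distribution report ("table1" layout)
#'
#' One row per species with columns `3P` ... `10P`, `>10P`, the total run
#' count, and the triple-proline share of all runs (1 decimal).
#'
#' @param tables named list of [run_length_table()] objects (names are
#'   species labels).
#' @param precision decimals for the percentage column (default 1).
#' @return data frame in table layout.
#' @export
format_table1 <- function(tables, precision = 1L) {
  rows <- lapply(names(tables), function(sp) {
    t <- tables[[sp]]
    row <- as.data.frame(as.list(t$counts), check.names = FALSE)
    names(row) <- c(paste0(3:10, "P"), ">10P")
    row <- cbind(species = sp, row,
                 total = t$total_runs,
                 pct_3p = round_half_up(t$pct_3p, precision))
    row
  })
  do.call(rbind, rows)
}

#' Format the unit totals and frequencies report ("table2" layout)
#'
#' One row per species: total PPP units, total PPG, total prolines, total
#' amino acids, PPP and PPG frequency per 10,000 amino acids (2 decimals),
#' and proline percentage (2 decimals).
#'
#' @param summaries list of [proteome_summary()] objects.
#' @param precision decimals for frequency and percentage columns
#'   (default 2); `NA` keeps full precision.
#' @return data frame in table layout.
#' @export
format_table2 <- function(summaries, precision = 2L) {
  fmt <- function(x) if (is.na(precision)) x else round_half_up(x, precision)
  rows <- lapply(summaries, function(s) {
    data.frame(
      species = s$species_label,
      total_ppp_units = s$total_ppp_units,
      total_ppg = s$total_ppg,
      total_proline = s$total_proline,
      total_aa = s$total_aa,
      ppp_freq_per_1e4 = fmt(s$ppp_freq_per_1e4),
      ppg_freq_per_1e4 = fmt(s$ppg_freq_per_1e4),
      proline_pct = fmt(s$proline_pct)
    )
  })
  do.call(rbind, rows)
}

#' Format the threshold gene-group report ("groups" layout)
#'
#' @param groups_by_species named list: species label -> data frame from
#'   [gene_groups()].
#' @param precision decimals for the percentage column (default 1).
#' @return data frame: species, motif, threshold, n_proteins, percent.
#' @export
format_groups <- function(groups_by_species, precision = 1L) {
  rows <- lapply(names(groups_by_species), function(sp) {
    g <- groups_by_species[[sp]]
    data.frame(species = sp, motif = g$motif, threshold = g$threshold,
               n_proteins = g$count,
               percent = round_half_up(g$pct_of_proteome, precision))
  })
  do.call(rbind, rows)
}

#' @noRd
profiles_report <- function(profiles) {
  data.frame(
    protein_id = profiles$protein_id,
    gene_id = profiles$gene_id,
    description = profiles$description,
    length = profiles$length,
    ppp_units = profiles$ppp_units,
    ppg_count = profiles$ppg_count,
    proline_count = profiles$proline_count,
    run_lengths = vapply(profiles$run_lengths, paste, character(1),
                         collapse = ";")
  )
}

#' @noRd
log_stage <- function(...) message("[polyproscan] ", ...)

#' Scan proteome FASTA files and write per-protein and summary reports
#'
#' For each input proteome: read, optionally reduce to the longest isoform
#' per gene, scan, and write a per-protein profile TSV. A combined summary
#' TSV ("table2" layout), run-length TSV ("table1" layout) and gene-group
#' TSV complete the report set. Identical inputs and configuration produce
#' byte-identical outputs.
#'
#' @param fastas character vector of FASTA paths, one proteome each.
#' @param species species labels, same length as `fastas`.
#' @param out_dir output directory (created if needed).
#' @param header_schema FASTA header schema (see [read_proteome_fasta()]).
#' @param gene_maps optional character vector of gene-map TSV paths
#'   parallel to `fastas` (NA entries skipped).
#' @param longest_isoform reduce each proteome to one longest protein per
#'   gene before scanning (default TRUE).
#' @param thresholds unit thresholds for the gene-group report.
#' @param precision decimals for reported frequencies; `NA` disables
#'   rounding for full-precision output.
#' @return named list of written file paths, invisibly.
#' @export
run_scan <- function(fastas, species, out_dir, header_schema = "plain",
                     gene_maps = NULL, longest_isoform = TRUE,
                     thresholds = c(1L, 2L, 3L), precision = 2L) {
  stopifnot(length(fastas) == length(species))
  missing <- fastas[!file.exists(fastas)]
  if (length(missing)) {
    stop("input FASTA not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); rl_tables <- list(); groups <- list()
  paths <- list()
  for (i in seq_along(fastas)) {
    sp <- species[i]
    t0 <- Sys.time()
    gm <- if (!is.null(gene_maps) && !is.na(gene_maps[i])) {
      read_gene_map(gene_maps[i])
    } else NULL
    prot <- read_proteome_fasta(fastas[i], header_schema, gene_map = gm)
    if (longest_isoform) prot <- select_longest_per_gene(prot)
    profiles <- scan_proteome(prot)
    summaries[[sp]] <- summarize_proteome(profiles, sp)
    rl_tables[[sp]] <- run_length_table(profiles)
    groups[[sp]] <- rbind(gene_groups(profiles, "PPP", thresholds),
                          gene_groups(profiles, "PPG", thresholds))
    per_protein <- file.path(out_dir, paste0(sp, "_proteins.tsv"))
    write_tsv_report(profiles_report(profiles), per_protein)
    paths[[paste0(sp, "_proteins")]] <- per_protein
    s <- summaries[[sp]]
    log_stage(sprintf(
      "%s: %d proteins, %d aa, %d PPP units, %d PPG, %d Pro (%.2fs)",
      sp, s$n_orfs, s$total_aa, s$total_ppp_units, s$total_ppg,
      s$total_proline, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  paths$table1 <- write_tsv_report(
    format_table1(rl_tables, precision = if (is.na(precision)) 12L else 1L),
    file.path(out_dir, "table1_run_lengths.tsv"))
  paths$table2 <- write_tsv_report(
    format_table2(summaries, precision),
    file.path(out_dir, "table2_summary.tsv"))
  paths$groups <- write_tsv_report(
    format_groups(groups, precision = if (is.na(precision)) 12L else 1L),
    file.path(out_dir, "groups.tsv"))
  invisible(paths)
}

#' Run the synthetic end-to-end demonstration pipeline
#'
#' Generates a synthetic proteome with planted repeats and synthetic
#' five-species ortholog tables, runs the scanner and the pool builder over
#' them, and writes all report tables plus a ground-truth comparison table
#' whose `match` column records whether each recovered quantity equals its
#' planted/designed value. With the default spec the run completes in
#' seconds and every comparison row is `"match"`.
#'
#' @param out_dir output directory.
#' @param seed integer seed driving proteome and ortholog generation.
#' @param spec optional [synthetic_proteome_spec()]; the default plants
#'   proline runs of lengths 5 and 3 plus PPG trigrams on a zero-proline
#'   background so recovery is exact.
#' @return named list of written file paths, invisibly.
#' @export
run_simulation_pipeline <- function(out_dir, seed = 1L, spec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) {
    spec <- synthetic_proteome_spec(
      n_proteins = 50L,
      lengths = list(kind = "fixed", length = 400L),
      background = aa_background(proline = 0),
      planted_runs = data.frame(residue = "P", length = c(5L, 3L),
                                count = c(6L, 8L)),
      ppg_plants = 10L,
      seed = seed
    )
  }
  log_stage("simulate: ", spec$n_proteins, " synthetic proteins")
  sim <- generate_proteome(spec)
  fasta <- file.path(out_dir, "synthetic_proteome.fasta")
  write_proteome_fasta(sim$proteome, fasta)
  write_tsv_report(sim$truth$plants, file.path(out_dir, "ground_truth.tsv"))

  profiles <- scan_proteome(sim$proteome)
  summary <- summarize_proteome(profiles, "synthetic")
  paths <- run_scan(fasta, "synthetic", out_dir)

  recovered <- data.frame(
    quantity = c("ppp_units", "ppg_count", "proline_count"),
    planted = c(sim$truth$planted_units, sim$truth$planted_ppg,
                sim$truth$planted_proline),
    recovered = c(summary$total_ppp_units, summary$total_ppg,
                  summary$total_proline)
  )

  log_stage("pools: synthetic five-species ortholog tables")
  orth <- generate_ortholog_tables(
    species = c("focal", "sp_far", "sp_mid", "sp_near", "sp_sister"),
    shared_fractions = c(0.1, 0.2, 0.4, 0.6),
    genes_per_species = 200L, seed = seed,
    dir = file.path(out_dir, "orthologs"))
  seed_sets <- lapply(orth$comparators, function(comp) {
    filter_seed_orthologs(orth$tables[[comp]])[[orth$focal]]
  })
  names(seed_sets) <- orth$comparators
  pool_rows <- lapply(seq_along(orth$comparators), function(j) {
    pool <- build_pool(orth$focal,
                       seed_sets[j:length(seed_sets)], pool_id = j)
    data.frame(quantity = paste0("pool", j, "_size"),
               planted = length(orth$designed_pools[[j]]),
               recovered = length(pool$member_gene_ids))
  })
  recovered <- rbind(recovered, do.call(rbind, pool_rows))
  recovered$match <- ifelse(recovered$planted == recovered$recovered,
                            "match", "MISMATCH")
  paths$recovery <- write_tsv_report(
    recovered, file.path(out_dir, "ground_truth_recovery.tsv"))
  log_stage("recovery: ",
            sum(recovered$match == "match"), "/", nrow(recovered),
            " quantities match ground truth")
  invisible(paths)
}
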
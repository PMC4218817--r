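# Ortholog pools: parse InParanoid-style pairwise tables, apply the
# inparalog-score 1.0 seed filter, intersect pairwise comparisons into
# nested pools, and compute per-pool repeat statistics.

#' Parse an InParanoid-style pairwise ortholog table
#'
#' Reads a tab-separated "SQLtable"-layout file with header columns
#' `cluster_id`, `bitscore`, `species`, `inparalog_score`, `gene_id`, one
#' row per gene per cluster. Species values must be one of the two expected
#' labels; scores must parse as reals in \[0, 1\]. Violations are hard
#' errors reported with the offending line number.
#'
#' @param path TSV file path.
#' @param species_a,species_b the two species labels expected in the
#'   `species` column.
#' @return data frame of validated ortholog records.
#' @export
parse_ortholog_table <- function(path, species_a, species_b) {
  if (!file.exists(path)) stop("ortholog table not found: ", path, call. = FALSE)
  tab <- read_tsv_file(path)
  needed <- c("cluster_id", "bitscore", "species", "inparalog_score", "gene_id")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("ortholog table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # +1 for the header row when reporting line numbers
  line_of <- function(i) i + 1L
  bad_sp <- which(!(tab$species %in% c(species_a, species_b)))
  if (length(bad_sp)) {
    stop("unknown species '", tab$species[bad_sp[1L]], "' at line ",
         line_of(bad_sp[1L]), " of ", path, call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(tab$inparalog_score))
  bad_sc <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad_sc)) {
    stop("unparseable or out-of-range inparalog score '",
         tab$inparalog_score[bad_sc[1L]], "' at line ", line_of(bad_sc[1L]),
         " of ", path, call. = FALSE)
  }
  tab$inparalog_score <- score
  tab$bitscore <- suppressWarnings(as.numeric(tab$bitscore))
  key <- paste(tab$cluster_id, tab$species, tab$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (cluster, species, gene) row at line ",
         line_of(which(duplicated(key))[1L]), " of ", path, call. = FALSE)
  }
  tab[, needed]
}

#' Seed orthologs: genes with inparalog score 1.0
#'
#' From parsed pairwise records, extracts per species the set of gene ids
#' whose inparalog score equals 1.0 — the cluster seeds — and drops all
#' others. Scores are compared exactly by default (InParanoid writes exact
#' decimals); a tolerance can be supplied for tables with floating-point
#' artifacts, and a gene qualifying in several clusters counts once (set
#' semantics).
#'
#' @param records data frame from [parse_ortholog_table()].
#' @param tolerance accept scores >= `1 - tolerance` (default 0: exact
#'   equality with 1.0).
#' @return named list mapping each species to a sorted character vector of
#'   seed gene ids.
#' @export
filter_seed_orthologs <- function(records, tolerance = 0) {
  stopifnot(is.data.frame(records), tolerance >= 0)
  if (tolerance > 0) {
    message("inparalog-score filter using tolerance ", tolerance,
            " (scores >= ", 1 - tolerance, " accepted)")
  }
  keep <- records$inparalog_score >= 1 - tolerance
  sp <- unique(records$species)
  out <- lapply(sp, function(s) {
    sort(unique(records$gene_id[keep & records$species == s]))
  })
  names(out) <- sp
  out
}

#' Build an ortholog pool by pairwise intersection
#'
#' A pool is the set of focal-species genes present (as score-1.0 seeds) in
#' every pairwise comparison with the pool's comparator species: the
#' intersection of the focal-side seed sets. With nested comparator sets
#' the pools nest — more comparators can only shrink the pool, so pool 1
#' (shared across all species, the oldest proteins) is contained in pool 4
#' (shared with the closest comparator only, the newest).
#'
#' @param focal focal species label.
#' @param pairwise_sets named list: comparator species -> character vector
#'   of focal-side seed gene ids from that pairwise comparison.
#' @param pool_id pool identifier (1–4 in the five-species design; any
#'   positive integer is accepted).
#' @return object of class `ortholog_pool`: list with `focal_species`,
#'   `comparator_species`, `pool_id`, `member_gene_ids` (sorted).
#' @export
build_pool <- function(focal, pairwise_sets, pool_id) {
  if (!is.list(pairwise_sets) || length(pairwise_sets) == 0L) {
    stop("no comparator sets supplied for pool ", pool_id, call. = FALSE)
  }
  if (is.null(names(pairwise_sets)) || any(!nzchar(names(pairwise_sets)))) {
    stop("`pairwise_sets` must be a named list of comparator gene sets",
         call. = FALSE)
  }
  members <- Reduce(intersect, pairwise_sets)
  out <- list(
    focal_species = focal,
    comparator_species = names(pairwise_sets),
    pool_id = pool_id,
    member_gene_ids = sort(unique(members))
  )
  class(out) <- "ortholog_pool"
  out
}

#' @export
print.ortholog_pool <- function(x, ...) {
  cat(sprintf("Ortholog pool %s for %s: %d genes shared with {%s}\n",
              x$pool_id, x$focal_species, length(x$member_gene_ids),
              paste(x$comparator_species, collapse = ", ")))
  invisible(x)
}

#' Repeat statistics of an ortholog pool
#'
#' Restricts the per-protein motif profiles to the pool members and applies
#' the same proteome summary and length statistics as for a whole
#' proteome. Every member must have a profile; missing members are a hard
#' error listing the absent genes (identifier-namespace mismatches must be
#' resolved upstream via the gene map, never silently dropped).
#'
#' @param pool `ortholog_pool` object.
#' @param profiles profile data frame from [scan_proteome()] covering the
#'   focal species (matched on `gene_id`).
#' @return list with `pool_id`, `n_genes`, `summary`
#'   ([proteome_summary()]), and `lengths` ([length_stats()]).
#' @export
pool_statistics <- function(pool, profiles) {
  stopifnot(inherits(pool, "ortholog_pool"))
  if (length(pool$member_gene_ids) == 0L) {
    stop("pool ", pool$pool_id, " is empty; pool frequencies are undefined",
         call. = FALSE)
  }
  missing <- setdiff(pool$member_gene_ids, profiles$gene_id)
  if (length(missing)) {
    stop("pool member(s) without a profile: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ..." else "", call. = FALSE)
  }
  sub <- profiles[profiles$gene_id %in% pool$member_gene_ids, , drop = FALSE]
  label <- sprintf("%s pool %s", pool$focal_species, pool$pool_id)
  list(
    pool_id = pool$pool_id,
    n_genes = length(pool$member_gene_ids),
    summary = summarize_proteome(sub, label),
    lengths = length_stats(sub)
  )
}
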
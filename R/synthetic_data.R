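# Synthetic proteomes with planted repeat runs and synthetic multi-species
# ortholog tables, both carrying exact ground truth.

#' Background amino-acid composition
#'
#' Builds the residue probability vector used for background draws. The
#' proline probability defaults to 0.05, in the middle of the 4.3–6.3%
#' usage range observed across real proteomes; the remaining mass is
#' spread uniformly over the other nineteen residues unless a full named
#' vector is given.
#'
#' @param proline proline probability in \[0, 1\].
#' @param full optional full named probability vector over the 20 standard
#'   residues (must sum to 1 within 1e-9); overrides `proline`.
#' @return named numeric vector over the 20 standard residues, summing to 1.
#' @export
aa_background <- function(proline = 0.05, full = NULL) {
  if (!is.null(full)) {
    if (!all(sort(names(full)) == AA_STANDARD) ||
        abs(sum(full) - 1) > 1e-9 || any(full < 0)) {
      stop("`full` must be a probability vector named by the 20 standard residues",
           call. = FALSE)
    }
    return(full[AA_STANDARD])
  }
  stopifnot(proline >= 0, proline <= 1)
  p <- rep((1 - proline) / 19, 20)
  names(p) <- AA_STANDARD
  p["P"] <- proline
  p
}

#' Specify a synthetic proteome
#'
#' Describes a proteome to generate: number of proteins, a length sampler,
#' a background residue composition, planted homopolymer runs and planted
#' PPG trigrams, and a seed. Plants are distributed across proteins at
#' random and placed so that every planted run is maximal (non-matching
#' flanks are enforced) and no two plants touch.
#'
#' @param n_proteins number of proteins.
#' @param lengths length sampler: `list(kind = "fixed", length = L)`,
#'   `list(kind = "uniform", min = a, max = b)`, or
#'   `list(kind = "lognormal", meanlog = m, sdlog = s)` (values rounded,
#'   floored at 30 residues). The default, log-normal with meanlog 5.8 and
#'   sdlog 0.55, gives a median protein length of about 330 residues with a
#'   long right tail, the shape typical of real proteomes.
#' @param background residue probabilities from [aa_background()].
#' @param planted_runs data frame with columns `residue`, `length`
#'   (each >= 3) and `count`, one row per planted run class; `NULL` for
#'   none.
#' @param ppg_plants number of PPG trigrams to plant.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `synthetic_proteome_spec`.
#' @seealso [generate_proteome()], [expected_frequencies()]
#' @export
synthetic_proteome_spec <- function(n_proteins,
                                    lengths = list(kind = "lognormal",
                                                   meanlog = 5.8, sdlog = 0.55),
                                    background = aa_background(),
                                    planted_runs = NULL,
                                    ppg_plants = 0L,
                                    seed = 1L) {
  stopifnot(n_proteins >= 1, ppg_plants >= 0, is.list(lengths),
            lengths$kind %in% c("fixed", "uniform", "lognormal"))
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    stop("background probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.null(planted_runs)) {
    stopifnot(is.data.frame(planted_runs),
              all(c("residue", "length", "count") %in% names(planted_runs)))
    if (any(planted_runs$length < 3L)) {
      stop("planted run lengths must be >= 3", call. = FALSE)
    }
    if (!all(planted_runs$residue %in% AA_STANDARD)) {
      stop("planted run residues must be standard amino-acid letters",
           call. = FALSE)
    }
  }
  out <- list(n_proteins = as.integer(n_proteins), lengths = lengths,
              background = background, planted_runs = planted_runs,
              ppg_plants = as.integer(ppg_plants), seed = as.integer(seed))
  class(out) <- "synthetic_proteome_spec"
  out
}

#' @noRd
sample_lengths <- function(lengths, n) {
  L <- switch(lengths$kind,
    fixed = rep(lengths$length, n),
    uniform = sample(seq(lengths$min, lengths$max), n, replace = TRUE),
    lognormal = pmax(30, round(stats::rlnorm(n, lengths$meanlog, lengths$sdlog)))
  )
  as.integer(L)
}

# Draw one residue from `background` excluding the letters in `not`.
#' @noRd
draw_excluding <- function(background, not) {
  p <- background[!(names(background) %in% not)]
  sample(names(p), 1L, prob = p)
}

#' Generate a synthetic proteome with known ground truth
#'
#' Draws background residues independently from the spec's composition,
#' then plants the requested homopolymer runs and PPG trigrams at uniformly
#' chosen, non-touching positions. Flanking positions are redrawn whenever
#' the background would extend a planted run (and, for proline runs, a
#' right-flank G is also excluded so a planted run never creates an
#' unplanned PPG), so every planted run is maximal exactly as specified.
#' Placement uses rejection sampling with a retry cap; a spec whose plants
#' do not fit is a hard error.
#'
#' Per-protein draws come from a stream seeded by (seed, protein index),
#' so each record is reproducible independently of generation order, and
#' the whole proteome is byte-identical across runs of the same spec.
#'
#' @param spec [synthetic_proteome_spec()] object.
#' @return list with `proteome` (records data frame as from
#'   [read_proteome_fasta()]) and `truth`: a list holding `plants` (data
#'   frame: `protein_id`, `kind` (`"run"` or `"ppg"`), `residue`, `start`,
#'   `length`), `lengths` (realized protein lengths), and the planted
#'   totals `planted_units`, `planted_ppg`, `planted_proline`.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_proteome_spec"))
  n <- spec$n_proteins
  bg <- spec$background

  set.seed(derive_seed(spec$seed, 0L))
  L <- sample_lengths(spec$lengths, n)

  chars <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i))
    chars[[i]] <- sample(names(bg), L[i], replace = TRUE, prob = bg)
  }

  # expand plant classes into individual items
  items <- data.frame(residue = character(0), length = integer(0),
                      kind = character(0))
  if (!is.null(spec$planted_runs)) {
    items <- do.call(rbind, lapply(seq_len(nrow(spec$planted_runs)), function(r) {
      row <- spec$planted_runs[r, ]
      data.frame(residue = row$residue, length = as.integer(row$length),
                 kind = "run")[rep(1L, row$count), , drop = FALSE]
    }))
  }
  if (spec$ppg_plants > 0L) {
    items <- rbind(items, data.frame(residue = "P", length = 3L,
                                     kind = "ppg")[rep(1L, spec$ppg_plants), ])
  }

  set.seed(derive_seed(spec$seed, n + 1L))
  reserved <- replicate(n, matrix(integer(0), ncol = 2), simplify = FALSE)
  used <- integer(n) # reserved footprint per protein
  plants <- NULL
  if (nrow(items)) {
    items <- items[sample.int(nrow(items)), , drop = FALSE]
    plants_list <- vector("list", nrow(items))
    for (k in seq_len(nrow(items))) {
      len <- items$length[k]
      placed <- FALSE
      for (try in seq_len(500L)) {
        i <- sample.int(n, 1L)
        if (used[i] + len + 2L > L[i] || L[i] < len) next
        s <- sample.int(L[i] - len + 1L, 1L)
        lo <- s - 1L; hi <- s + len # reserved window incl. flank pads
        res <- reserved[[i]]
        clash <- nrow(res) > 0 && any(res[, 1] <= hi & res[, 2] >= lo)
        if (clash) next
        reserved[[i]] <- rbind(res, c(lo, hi))
        used[i] <- used[i] + len + 2L
        if (items$kind[k] == "run") {
          chars[[i]][s:(s + len - 1L)] <- items$residue[k]
          excl_left <- items$residue[k]
          excl_right <- if (items$residue[k] == "P") c("P", "G") else items$residue[k]
          if (s > 1L && chars[[i]][s - 1L] %in% excl_left) {
            chars[[i]][s - 1L] <- draw_excluding(bg, excl_left)
          }
          e <- s + len
          if (e <= L[i] && chars[[i]][e] %in% excl_right) {
            chars[[i]][e] <- draw_excluding(bg, excl_right)
          }
        } else { # ppg trigram
          chars[[i]][s:(s + 2L)] <- c("P", "P", "G")
          if (s > 1L && chars[[i]][s - 1L] == "P") {
            chars[[i]][s - 1L] <- draw_excluding(bg, "P")
          }
        }
        plants_list[[k]] <- data.frame(
          protein_index = i, kind = items$kind[k],
          residue = items$residue[k], start = s, length = len
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("infeasible synthetic spec: could not place a planted ",
             items$kind[k], " of length ", len,
             " after 500 attempts", call. = FALSE)
      }
    }
    plants <- do.call(rbind, plants_list)
  }

  ids <- sprintf("SYN%05d", seq_len(n))
  proteome <- data.frame(
    protein_id = ids, gene_id = ids, transcript_id = "",
    description = "synthetic protein",
    sequence = vapply(chars, paste, character(1), collapse = ""),
    stringsAsFactors = FALSE
  )
  if (is.null(plants)) {
    plants <- data.frame(protein_id = character(0), kind = character(0),
                         residue = character(0), start = integer(0),
                         length = integer(0))
  } else {
    plants <- data.frame(protein_id = ids[plants$protein_index],
                         kind = plants$kind, residue = plants$residue,
                         start = plants$start, length = plants$length)
    plants <- plants[order(plants$protein_id, plants$start), , drop = FALSE]
    rownames(plants) <- NULL
  }
  is_run <- plants$kind == "run"
  truth <- list(
    plants = plants,
    lengths = L,
    planted_units = as.integer(sum(run_units(plants$length[is_run]))),
    planted_ppg = as.integer(sum(!is_run)),
    planted_proline = as.integer(
      sum(plants$length[is_run & plants$residue == "P"]) + 2L * sum(!is_run))
  )
  list(proteome = proteome, truth = truth)
}

# Expected number of maximal runs of exactly n in an iid sequence of
# length L with residue probability p: interior starts need two
# non-matching flanks, the two boundary starts one, a full-length run none.
#' @noRd
expected_run_count <- function(n, L, p) {
  if (n > L || p == 0) return(0)
  if (n == L) return(p^L)
  2 * p^n * (1 - p) + max(L - n - 1, 0) * p^n * (1 - p)^2
}

#' @noRd
expected_units_one <- function(L, p) {
  if (p == 0 || L < 3) return(0)
  total <- 0
  for (n in 3:L) {
    c_n <- expected_run_count(n, L, p)
    total <- total + (n %/% 3) * c_n
    if (c_n < 1e-18 && n > 12) break
  }
  total
}

#' Closed-form expected repeat content of a synthetic proteome
#'
#' Combines the planted ground truth with the analytic expectation of the
#' background contribution: for each protein, the expected unit count of an
#' iid background of the realized length minus the planted footprint, via
#' the exact expected count of maximal runs of each length. Background PPG
#' expectation is the trigram match probability summed over positions, and
#' expected prolines add the background rate to the planted prolines.
#' Flank-redraw edge effects at plant boundaries are ignored, so the
#' expectation carries a Monte-Carlo tolerance of order one unit per plant
#' site; the generator's recovery tests compare observations to these
#' values using an empirical standard error across seeds.
#'
#' @param spec [synthetic_proteome_spec()] object.
#' @param truth ground-truth list from [generate_proteome()].
#' @return list with `expected_ppp_units`, `expected_ppg`,
#'   `expected_proline`, `total_aa`, and the derived
#'   `expected_ppp_freq_per_1e4`.
#' @export
expected_frequencies <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_proteome_spec"))
  p <- spec$background[["P"]]
  pg <- spec$background[["G"]]
  footprint <- integer(spec$n_proteins)
  if (nrow(truth$plants)) {
    idx <- match(truth$plants$protein_id,
                 sprintf("SYN%05d", seq_len(spec$n_proteins)))
    fp <- tapply(truth$plants$length, idx, sum)
    footprint[as.integer(names(fp))] <- as.integer(fp)
  }
  L_bg <- pmax(truth$lengths - footprint, 0L)
  exp_units <- truth$planted_units + sum(vapply(L_bg, expected_units_one,
                                                numeric(1), p = p))
  exp_ppg <- truth$planted_ppg + sum(pmax(L_bg - 2, 0)) * p^2 * pg
  exp_pro <- truth$planted_proline + sum(L_bg) * p
  total_aa <- sum(truth$lengths)
  list(
    expected_ppp_units = exp_units,
    expected_ppg = exp_ppg,
    expected_proline = exp_pro,
    total_aa = total_aa,
    expected_ppp_freq_per_1e4 = exp_units / total_aa * 1e4
  )
}

#' Generate synthetic pairwise ortholog tables with designed pools
#'
#' Builds InParanoid-style pairwise tables for a focal species against an
#' ordered set of comparators (most distant first), such that pool
#' construction recovers a designed nested membership exactly. Pool j is
#' shared with comparators j..m, so designed sizes must be non-decreasing
#' from pool 1 (shared with all, the oldest genes) to pool m (closest
#' comparator only). Designed members receive inparalog score 1.0; decoy
#' clusters carry random scores below 1.0.
#'
#' @param species character vector of species labels; the first is the
#'   focal species, the rest are comparators ordered most distant first.
#' @param shared_fractions numeric vector, one fraction per pool (length =
#'   number of comparators), non-decreasing; pool j holds
#'   `round(fraction[j] * genes_per_species)` focal genes.
#' @param genes_per_species genes in the focal gene universe.
#' @param seed integer seed.
#' @param dir optional directory; when given, each pairwise table is also
#'   written as `<focal>__<comparator>.tsv`.
#' @return list with `focal`, `comparators`, `tables` (named list of
#'   pairwise record data frames, one per comparator), `designed_pools`
#'   (list pool id -> sorted member gene ids), and `paths` when `dir` was
#'   given.
#' @export
generate_ortholog_tables <- function(species, shared_fractions,
                                     genes_per_species, seed = 1L,
                                     dir = NULL) {
  stopifnot(length(species) >= 2L, genes_per_species >= 1L)
  focal <- species[1L]
  comparators <- species[-1L]
  m <- length(comparators)
  if (length(shared_fractions) != m ||
      any(shared_fractions < 0) || any(shared_fractions > 1)) {
    stop("`shared_fractions` needs one value in [0,1] per comparator",
         call. = FALSE)
  }
  sizes <- round(shared_fractions * genes_per_species)
  if (is.unsorted(sizes)) {
    stop("infeasible nesting: designed pool sizes must be non-decreasing ",
         "from pool 1 to pool ", m, call. = FALSE)
  }
  set.seed(derive_seed(seed, 0L))
  genes <- sprintf("%s_g%04d", focal, seq_len(genes_per_species))
  # nested design: draw the largest pool, then subsample downwards
  designed <- vector("list", m)
  designed[[m]] <- sort(sample(genes, sizes[m]))
  if (m > 1L) {
    for (j in (m - 1L):1L) {
      designed[[j]] <- sort(sample(designed[[j + 1L]], sizes[j]))
    }
  }
  names(designed) <- as.character(seq_len(m))

  tables <- vector("list", m)
  names(tables) <- comparators
  for (j in seq_len(m)) {
    comp <- comparators[j]
    seeds <- designed[[j]] # focal genes with score 1.0 against comparator j
    rows <- list()
    cl <- 0L
    for (g in seeds) {
      cl <- cl + 1L
      partner <- sprintf("%s_o%04d", comp, cl)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = as.character(cl),
        bitscore = round(stats::runif(2, 100, 2000), 1),
        species = c(focal, comp),
        inparalog_score = c(1.0, 1.0),
        gene_id = c(g, partner)
      )
    }
    # decoy inparalogs with scores strictly below 1.0
    decoys <- setdiff(genes, seeds)
    if (length(decoys)) {
      n_decoy <- min(length(decoys), max(3L, length(seeds) %/% 2L))
      for (g in sample(decoys, n_decoy)) {
        cl <- cl + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = as.character(cl),
          bitscore = round(stats::runif(2, 100, 2000), 1),
          species = c(focal, comp),
          inparalog_score = c(round(stats::runif(1, 0.05, 0.99), 3), 1.0),
          gene_id = c(g, sprintf("%s_o%04d", comp, cl))
        )
      }
    }
    tables[[comp]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cluster_id = character(0), bitscore = numeric(0),
                 species = character(0), inparalog_score = numeric(0),
                 gene_id = character(0))
  }
  out <- list(focal = focal, comparators = comparators, tables = tables,
              designed_pools = designed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$paths <- vapply(comparators, function(comp) {
      p <- file.path(dir, paste0(focal, "__", comp, ".tsv"))
      write_tsv_report(tables[[comp]], p)
      p
    }, character(1))
  }
  out
}
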
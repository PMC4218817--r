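# Independent brute-force oracles (plain character loops, no shared code
# with the package internals) and small fixture builders.

# All maximal runs of `residue` with length >= min_len, by linear walk.
oracle_runs <- function(sequence, residue, min_len = 3L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- data.frame(start = integer(0), length = integer(0))
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == residue) {
      j <- i
      while (j < n && chars[j + 1L] == residue) j <- j + 1L
      if (j - i + 1L >= min_len) {
        out <- rbind(out, data.frame(start = i, length = j - i + 1L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Greedy left-to-right count of disjoint XXX trigrams of one residue.
# Runs of different letters separate matches, so this equals the sum of
# floor(run length / 3) over maximal runs.
oracle_triplet_greedy <- function(sequence, residue) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  count <- 0L
  i <- 1L
  while (i <= n - 2L) {
    if (chars[i] == residue && chars[i + 1L] == residue &&
        chars[i + 2L] == residue) {
      count <- count + 1L
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  count
}

# All window positions matching the exact trigram P,P,G.
oracle_ppg_positions <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  pos <- integer(0)
  if (n >= 3L) {
    for (i in 1:(n - 2L)) {
      if (chars[i] == "P" && chars[i + 1L] == "P" && chars[i + 2L] == "G") {
        pos <- c(pos, i)
      }
    }
  }
  pos
}

# Random test sequence over an alphabet enriched for P and G so that runs
# and PPG motifs actually occur.
random_motif_seq <- function(len) {
  paste(sample(c("P", "G", "A", "Q", "L"), len, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.2, 0.1)), collapse = "")
}

# Write a FASTA fixture from raw lines; returns the path.
write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

toy_proteome <- function(sequences, gene_ids = NULL) {
  ids <- sprintf("p%d", seq_along(sequences))
  data.frame(
    protein_id = ids,
    gene_id = if (is.null(gene_ids)) ids else gene_ids,
    transcript_id = "",
    description = "",
    sequence = sequences,
    stringsAsFactors = FALSE
  )
}
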
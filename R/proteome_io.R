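# Proteome input/output: FASTA reading with header-schema parsing,
# normalization, longest-isoform selection, gene maps, FASTA re-emission.

#' Read a protein FASTA file into a proteome data frame
#'
#' Reads protein sequences with [Biostrings::readAAStringSet()] and parses
#' identifiers out of the headers according to a named schema:
#'
#' * `"plain"` — the first whitespace-delimited token is the protein id;
#'   `gene_id` is set equal to it; the rest of the header is the
#'   description.
#' * `"ensembl"` — Ensembl peptide headers: first token is the protein id,
#'   and `gene:`, `transcript:`, `gene_biotype:`/`transcript_biotype:` tags
#'   populate the remaining fields. Entries whose biotype tags mention
#'   pseudogenes or transposable elements are dropped, mirroring curated
#'   proteome preparation that filters ORFs from pseudogenes and
#'   transposons.
#' * `"keyvalue"` — whitespace-separated `key=value` pairs after the first
#'   token (`gene=`, `transcript=`, `description=`).
#'
#' Sequences are uppercased and a single trailing stop symbol `*` is
#' stripped. A record with an empty sequence, an internal `*` or `.`, or a
#' duplicated protein id is a hard error naming the offending entry:
#' internal stops indicate pseudogene leakage and are rejected rather than
#' silently trimmed. Ambiguity letters (X, B, Z, U, O, J) are retained —
#' they count toward protein length but never match a repeat residue.
#'
#' @param path path to a FASTA file (multi-line or single-line sequences).
#' @param header_schema one of `"plain"`, `"ensembl"`, `"keyvalue"`.
#' @param gene_map optional gene map data frame from [read_gene_map()];
#'   overrides header-derived `gene_id`/`transcript_id` by `protein_id`.
#' @return data frame with columns `protein_id`, `gene_id`,
#'   `transcript_id`, `description`, `sequence`.
#' @seealso [select_longest_per_gene()], [write_proteome_fasta()]
#' @export
read_proteome_fasta <- function(path, header_schema = "plain", gene_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  schemas <- c("plain", "ensembl", "keyvalue")
  if (!is.character(header_schema) || length(header_schema) != 1L ||
      !(header_schema %in% schemas)) {
    stop("unknown header schema: ", paste(header_schema, collapse = ", "),
         " (supported: ", paste(schemas, collapse = ", "), ")", call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  names(seqs) <- NULL

  parsed <- parse_fasta_headers(headers, header_schema)
  seqs <- sub("\\*$", "", seqs)

  bad_empty <- which(!nzchar(seqs))
  if (length(bad_empty)) {
    stop("FASTA entry with empty sequence: ",
         parsed$protein_id[bad_empty[1L]], call. = FALSE)
  }
  bad_internal <- grep("[*.]", seqs)
  if (length(bad_internal)) {
    stop("corrupt record (internal stop or gap symbol): ",
         parsed$protein_id[bad_internal[1L]], call. = FALSE)
  }
  bad_ws <- grep("[[:space:][:digit:]]", seqs)
  if (length(bad_ws)) {
    stop("corrupt record (whitespace or digits in sequence): ",
         parsed$protein_id[bad_ws[1L]], call. = FALSE)
  }
  dup <- parsed$protein_id[duplicated(parsed$protein_id)]
  if (length(dup)) {
    stop("duplicate protein identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  out <- data.frame(
    protein_id = parsed$protein_id,
    gene_id = parsed$gene_id,
    transcript_id = parsed$transcript_id,
    description = parsed$description,
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  out <- out[!parsed$drop, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gene_map)) out <- apply_gene_map(out, gene_map)
  out
}

#' @noRd
parse_fasta_headers <- function(headers, schema) {
  first <- sub("\\s.*$", "", headers)
  rest <- trimws(sub("^\\S+\\s*", "", headers))
  gene <- first
  transcript <- rep("", length(headers))
  desc <- rest
  drop <- rep(FALSE, length(headers))
  grab <- function(tag) {
    m <- regmatches(rest, regexpr(paste0(tag, "\\S+"), rest))
    out <- rep("", length(rest))
    out[regexpr(paste0(tag, "\\S+"), rest) > 0] <- sub(paste0("^", tag), "", m)
    out
  }
  if (schema == "ensembl") {
    g <- grab("gene:"); t <- grab("transcript:")
    gene <- ifelse(nzchar(g), g, first)
    transcript <- t
    bio <- paste(grab("gene_biotype:"), grab("transcript_biotype:"))
    drop <- grepl("pseudogene|transposable_element|transposon", bio,
                  ignore.case = TRUE)
    desc <- trimws(sub(".*description:", "", rest))
    desc[!grepl("description:", rest)] <- ""
  } else if (schema == "keyvalue") {
    g <- grab("gene="); t <- grab("transcript=")
    gene <- ifelse(nzchar(g), g, first)
    transcript <- t
    d <- grab("description=")
    desc <- ifelse(nzchar(d), d, "")
  }
  list(protein_id = first, gene_id = gene, transcript_id = transcript,
       description = desc, drop = drop)
}

#' Read a protein-to-gene mapping table
#'
#' A 2–3 column TSV with a mandatory header row: `protein_id`, `gene_id`
#' and optionally `transcript_id`. Used to assign gene identity when FASTA
#' headers carry only protein ids, so longest-isoform selection can operate
#' per gene.
#'
#' @param path TSV file path.
#' @return data frame with columns `protein_id`, `gene_id`, and
#'   `transcript_id` (empty strings when the column is absent).
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map not found: ", path, call. = FALSE)
  gm <- read_tsv_file(path)
  if (!all(c("protein_id", "gene_id") %in% names(gm))) {
    stop("gene map must have header columns protein_id and gene_id",
         call. = FALSE)
  }
  if (!"transcript_id" %in% names(gm)) gm$transcript_id <- ""
  if (anyDuplicated(gm$protein_id)) {
    stop("gene map has duplicate protein_id rows", call. = FALSE)
  }
  gm[, c("protein_id", "gene_id", "transcript_id")]
}

#' @noRd
apply_gene_map <- function(records, gene_map) {
  idx <- match(records$protein_id, gene_map$protein_id)
  hit <- !is.na(idx)
  records$gene_id[hit] <- gene_map$gene_id[idx[hit]]
  records$transcript_id[hit] <- gene_map$transcript_id[idx[hit]]
  records
}

#' Reduce a proteome to one longest protein per gene
#'
#' Finalizes a transcript-level proteome by keeping, for every distinct
#' `gene_id`, the longest protein sequence. Ties on length are broken by
#' the lexicographically smallest `protein_id`, which makes the selection
#' deterministic across input orderings. Output rows are ordered by
#' `gene_id`.
#'
#' @param records proteome data frame (every row must have a `gene_id`).
#' @return proteome data frame with exactly one row per gene.
#' @export
select_longest_per_gene <- function(records) {
  assert_proteome_df(records)
  if (any(is.na(records$gene_id) | !nzchar(records$gene_id))) {
    stop("every record needs a non-empty gene_id", call. = FALSE)
  }
  len <- nchar(records$sequence)
  # order: gene asc, length desc, protein_id asc; first row per gene wins
  ord <- order(records$gene_id, -len, records$protein_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  out <- records[!duplicated(records$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a proteome back to FASTA
#'
#' Emits records in order with 60-column sequence wrapping; the header is
#' `>protein_id description` (description omitted when empty).
#'
#' @param records proteome data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(records, path) {
  assert_proteome_df(records)
  aas <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(aas) <- trimws(paste(records$protein_id, desc))
  Biostrings::writeXStringSet(aas, filepath = path, width = 60L)
  invisible(path)
}
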
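# File formats: FASTA (via Biostrings), the 3-line topology dialect,
# metadata TSV, segment TSV, similarity-matrix TSV, benchmark config JSON.
# All readers tolerate LF or CRLF and uppercase sequences on input.

#' Read amino-acid sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header line
#' and must be unique.
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences; names are ids,
#'   input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not valid FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), .AA_ALPHABET)
    if (length(bad))
      stop("sequence ", ids[i], " contains non-amino-acid letters: ",
           paste(bad, collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a 3-line topology file
#'
#' Each record is three lines: `>id`, the amino-acid sequence, and the
#' same-length residue-state string. Every id must be present in `sequences`
#' and the record's sequence must agree with it.
#'
#' @param path topology file.
#' @param sequences named character vector of reference sequences.
#' @param allow_loop,allow_placeholder passed to [validate_states()]; enable
#'   for raw PDBTM input (`L` loop states, `1`/`2` unoriented sides).
#' @return named character vector of state strings.
#' @export
read_topology_file <- function(path, sequences, allow_loop = FALSE,
                               allow_placeholder = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in topology file: ", path)
  if (length(lines) %% 3L != 0L)
    stop("malformed topology file (line count not a multiple of 3): ", path)
  n <- length(lines) %/% 3L
  out <- character(n)
  ids <- character(n)
  for (k in seq_len(n)) {
    hdr <- lines[3L * k - 2L]
    if (!startsWith(hdr, ">"))
      stop("malformed topology record ", k, ": expected '>' header, got ",
           sQuote(hdr))
    id <- strsplit(sub("^>", "", hdr), "[ \t]+")[[1]][1L]
    seq <- toupper(lines[3L * k - 1L])
    states <- lines[3L * k]
    if (!id %in% names(sequences))
      stop("id not in sequence set: ", id)
    if (seq != sequences[[id]])
      stop("sequence mismatch for ", id, " between topology file and FASTA")
    validate_states(states, seq, allow_loop = allow_loop,
                    allow_placeholder = allow_placeholder)
    ids[k] <- id
    out[k] <- states
  }
  if (anyDuplicated(ids))
    stop("duplicate id(s) in topology file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(out) <- ids
  out
}

#' Write a 3-line topology file
#'
#' @param states named character vector of state strings.
#' @param sequences named character vector covering all ids in `states`.
#' @param path output file.
#' @export
write_topology_file <- function(states, sequences, path) {
  ids <- names(states)
  if (is.null(ids) || !all(ids %in% names(sequences)))
    stop("all state strings must be named with ids present in 'sequences'")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    writeLines(c(paste0(">", id), sequences[[id]], states[[id]]), con)
  }
  invisible(path)
}

#' Read a segment-list TSV and convert to state strings
#'
#' Alternative prediction/annotation input: a TSV with columns `id`, `start`,
#' `end`, `kind` is converted immediately to the canonical state-string form,
#' filling non-membrane positions with `U`.
#'
#' @param path TSV file with header.
#' @param sequences named character vector of sequences (provides lengths).
#' @return named character vector of state strings (one per id that appears).
#' @export
read_segments_tsv <- function(path, sequences) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "start", "end")
  if (!all(req %in% names(df)))
    stop("segment TSV needs columns id, start, end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-integer segment bounds")
  bad <- setdiff(unique(df$id), names(sequences))
  if (length(bad)) stop("id(s) not in sequence set: ", paste(bad, collapse = ", "))
  out <- vapply(unique(df$id), function(id) {
    seg <- df[df$id == id, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    .validate_segments(seg, nchar(sequences[[id]]))
    states_from_segments(seg, nchar(sequences[[id]]), side_fill = "U")
  }, character(1))
  names(out) <- unique(df$id)
  out
}

#' Read the protein metadata table
#'
#' TSV with header columns `id`, `chain_class`, `kingdom`, `family`,
#' `exp_method`, `resolution`, `year`, `helix_profile`. Resolution may be
#' empty/NA for NMR entries.
#'
#' @param path TSV file.
#' @param sequences optional named character vector; when given, every id must
#'   have a sequence, which is attached as a `sequence` column.
#' @return validated `tm_records` data frame (see [protein_records()]).
#' @export
read_metadata <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"resolution" %in% names(df)) stop("missing metadata columns: resolution")
  res <- suppressWarnings(as.numeric(df$resolution))
  if (any(is.na(res) & !is.na(df$resolution)))
    stop("unparseable resolution value(s): ",
         paste(df$resolution[is.na(res) & !is.na(df$resolution)], collapse = ", "))
  df$resolution <- res
  yr <- suppressWarnings(as.integer(df$year))
  if (any(is.na(yr) & !is.na(df$year)))
    stop("unparseable year value(s)")
  df$year <- yr
  if (!is.null(sequences)) {
    miss <- setdiff(df$id, names(sequences))
    if (length(miss))
      stop("no sequence for id(s): ", paste(miss, collapse = ", "))
    df$sequence <- unname(sequences[df$id])
  }
  protein_records(df)
}

#' Write the protein metadata table
#'
#' @param records `tm_records` data frame.
#' @param path output TSV.
#' @export
write_metadata <- function(records, path) {
  cols <- c("id", "chain_class", "kingdom", "family", "exp_method",
            "resolution", "year", "helix_profile")
  utils::write.table(as.data.frame(records)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise similarity matrix from long-form TSV
#'
#' Expects a header and three columns: two ids and the percent identity of
#' their alignment. The matrix is symmetrised (conflicting asymmetric entries
#' are an error) and the diagonal fixed at 100.
#'
#' @param path TSV file.
#' @param alignment_kind provenance label, `"global"` or `"local"`.
#' @return object of class `tm_simmatrix`: list with `ids`, `values`
#'   (symmetric numeric matrix, percent), `alignment_kind`.
#' @export
read_similarity_matrix <- function(path, alignment_kind = c("global", "local")) {
  alignment_kind <- match.arg(alignment_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("similarity TSV needs 3 columns: id_a, id_b, percent")
  names(df)[1:3] <- c("id_a", "id_b", "percent")
  df$percent <- as.numeric(df$percent)
  if (anyNA(df$percent)) stop("unparseable similarity value(s)")
  similarity_matrix_from_pairs(df$id_a, df$id_b, df$percent, alignment_kind)
}

#' Build a similarity matrix from pair lists
#'
#' @param id_a,id_b,percent parallel vectors of pairwise percent identities.
#' @param alignment_kind provenance label.
#' @return `tm_simmatrix` object.
#' @export
similarity_matrix_from_pairs <- function(id_a, id_b, percent,
                                         alignment_kind = "global") {
  if (any(percent < 0 | percent > 100)) stop("similarity values outside [0,100]")
  ids <- sort(unique(c(id_a, id_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_along(id_a)) {
    a <- id_a[k]; b <- id_b[k]
    if (a == b) next
    if (m[a, b] != 0 && m[a, b] != percent[k])
      stop("conflicting similarity values for pair ", a, "/", b)
    m[a, b] <- percent[k]
    if (m[b, a] != 0 && m[b, a] != percent[k])
      stop("conflicting similarity values for pair ", a, "/", b)
    m[b, a] <- percent[k]
  }
  diag(m) <- 100
  structure(list(ids = ids, values = m, alignment_kind = alignment_kind),
            class = "tm_simmatrix")
}

#' Read a benchmark subset configuration from JSON
#'
#' @param path JSON file; fields as in [subset_config()].
#' @return validated `tm_subset_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(subset_config, cfg)
}
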
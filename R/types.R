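# Domain types: residue-state strings, helix segments, reference annotations,
# prediction records, protein metadata records.
#
# Residue-state alphabet:
#   M  membrane helix        i  inside (cytoplasmic) side
#   o  outside (extracellular) side
#   L  membrane loop (PDBTM's state for short membrane-dipping segments)
#   U  unassigned (no side emitted, e.g. topography-only methods)
#   1/2  placeholder side labels for raw PDBTM annotations whose two membrane
#        faces are not yet oriented as inside/outside (see map_sides()).

.STATE_CORE <- c("M", "i", "o", "U")
.STATE_LOOP <- "L"
.STATE_PLACEHOLDER <- c("1", "2")
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.CHAIN_CLASSES <- c("helical_membrane", "beta_barrel", "soluble")
.EXP_METHODS <- c("xray", "nmr", "other")
.HELIX_PROFILES <- c("tm_only", "has_half_membrane", "none")
.CONVENTIONS <- c("opm", "opm_adjusted", "pdbtm", "pdbtm_with_loops")

#' Validate a residue-state string
#'
#' Checks a per-residue topology string against the state alphabet and,
#' optionally, against the length of the corresponding amino-acid sequence.
#'
#' @param states single character string over the state alphabet.
#' @param sequence optional amino-acid sequence the states annotate; when
#'   given, lengths must agree.
#' @param allow_loop allow the PDBTM loop state `L`.
#' @param allow_placeholder allow unoriented side placeholders `1`/`2`.
#' @return `states`, invisibly, after validation.
#' @export
validate_states <- function(states, sequence = NULL, allow_loop = FALSE,
                            allow_placeholder = FALSE) {
  if (!is.character(states) || length(states) != 1L || is.na(states))
    stop("'states' must be a single character string")
  if (nchar(states) == 0L)
    stop("state string is empty")
  allowed <- .STATE_CORE
  if (allow_loop) allowed <- c(allowed, .STATE_LOOP)
  if (allow_placeholder) allowed <- c(allowed, .STATE_PLACEHOLDER)
  chars <- unique(strsplit(states, "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad))
    stop("state string contains characters outside the alphabet: ",
         paste(sQuote(bad), collapse = ", "))
  if (!is.null(sequence) && nchar(states) != nchar(sequence))
    stop("state string length (", nchar(states),
         ") does not match sequence length (", nchar(sequence), ")")
  invisible(states)
}

#' Extract membrane-helix segments from a state string
#'
#' Returns the maximal runs of `M` as 1-based, inclusive segments.
#'
#' @param states residue-state string.
#' @return data frame with columns `start`, `end` (integer, 1-based
#'   inclusive), sorted by `start`.
#' @examples
#' segments_from_states("iiMMMooMMi")
#' @export
segments_from_states <- function(states) {
  v <- strsplit(states, "")[[1]]
  r <- rle(v == "M")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Build a state string from helix segments
#'
#' Inverse of [segments_from_states()] on the `M` positions. Non-membrane
#' positions are filled from `side_fill`, either a single state character or a
#' full-length string supplying the inside/outside pattern.
#'
#' @param segments data frame with `start`, `end` columns (1-based inclusive).
#' @param length chain length in residues.
#' @param side_fill single character (default `"U"`) or a string of `length`
#'   characters whose non-membrane states are used as filler.
#' @return residue-state string.
#' @export
states_from_segments <- function(segments, length, side_fill = "U") {
  length <- as.integer(length)
  if (length < 1L) stop("'length' must be >= 1")
  if (nchar(side_fill) == 1L) {
    fill <- rep(side_fill, length)
  } else {
    if (nchar(side_fill) != length)
      stop("'side_fill' must be a single character or have length ", length)
    fill <- strsplit(side_fill, "")[[1]]
  }
  v <- fill
  if (nrow(segments)) {
    seg <- segments[order(segments$start), , drop = FALSE]
    if (any(seg$start > seg$end))
      stop("segment with start > end")
    if (any(seg$start < 1L) || any(seg$end > length))
      stop("segment outside [1, length]")
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      stop("overlapping segments")
    for (k in seq_len(nrow(seg))) v[seg$start[k]:seg$end[k]] <- "M"
  }
  paste(v, collapse = "")
}

# Validate a helix-segment table: sorted, non-overlapping, gap >= 1 residue.
.validate_segments <- function(segments, length = NULL) {
  if (!all(c("start", "end") %in% names(segments)))
    stop("segments need 'start' and 'end' columns")
  if (!nrow(segments)) return(invisible(segments))
  if (any(segments$start > segments$end)) stop("segment with start > end")
  if (is.unsorted(segments$start, strictly = TRUE) && nrow(segments) > 1L)
    stop("segments must be sorted by start")
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] - segments$end[-nrow(segments)] < 2L))
    stop("segments must be non-overlapping and non-adjacent (gap >= 1)")
  if (!is.null(length) &&
      (any(segments$start < 1L) || any(segments$end > length)))
    stop("segment outside chain bounds")
  invisible(segments)
}

# Nearest non-membrane flank labels of each helix; used to call re-entrant
# (half-membrane) helices. M, L and U are skipped when looking for a flank.
.flank_labels <- function(states, segments) {
  v <- strsplit(states, "")[[1]]
  sides <- !(v %in% c("M", "L", "U"))
  n <- length(v)
  t(vapply(seq_len(nrow(segments)), function(k) {
    left <- NA_character_
    right <- NA_character_
    lpos <- segments$start[k] - 1L
    while (lpos >= 1L) {
      if (sides[lpos]) { left <- v[lpos]; break }
      lpos <- lpos - 1L
    }
    rpos <- segments$end[k] + 1L
    while (rpos <= n) {
      if (sides[rpos]) { right <- v[rpos]; break }
      rpos <- rpos + 1L
    }
    c(left, right)
  }, character(2)))
}

# Helix kinds from flank context: same label on both flanks -> half_membrane
# (re-entrant); anything else (crossing, terminal single flank, no sides)
# -> full_tm.
.kinds_from_flanks <- function(states, segments) {
  if (!nrow(segments)) return(character(0))
  fl <- .flank_labels(states, segments)
  ifelse(!is.na(fl[, 1L]) & !is.na(fl[, 2L]) & fl[, 1L] == fl[, 2L],
         "half_membrane", "full_tm")
}

#' Construct a reference annotation
#'
#' Bundles a per-residue state string with its derived helix-segment list and
#' the annotation convention it came from. Helices are always the maximal `M`
#' runs of `states`; their `kind` (full transmembrane vs half-membrane
#' re-entrant) is derived from the flanking side labels via the same rule as
#' [flag_half_membrane()].
#'
#' @param protein_id protein/chain identifier.
#' @param states residue-state string. `L` is only permitted under the
#'   `pdbtm` convention; placeholder sides `1`/`2` only under `pdbtm`.
#' @param convention one of `"opm"`, `"opm_adjusted"`, `"pdbtm"`,
#'   `"pdbtm_with_loops"`.
#' @param sequence optional amino-acid sequence (length-checked).
#' @return object of class `tm_annotation` with elements `protein_id`,
#'   `states`, `helices` (data frame `start`, `end`, `kind`), `convention`.
#' @export
reference_annotation <- function(protein_id, states,
                                 convention = c("opm", "opm_adjusted",
                                                "pdbtm", "pdbtm_with_loops"),
                                 sequence = NULL) {
  convention <- match.arg(convention)
  validate_states(states, sequence,
                  allow_loop = convention == "pdbtm",
                  allow_placeholder = convention == "pdbtm")
  helices <- segments_from_states(states)
  helices$kind <- .kinds_from_flanks(states, helices)
  structure(list(protein_id = protein_id, states = states,
                 helices = helices, convention = convention),
            class = "tm_annotation")
}

#' Construct a prediction record
#'
#' A single method's per-residue prediction for one protein. The PDBTM loop
#' state `L` is not permitted; `U` is, for topography-only methods that emit
#' no inside/outside sides.
#'
#' @param protein_id protein/chain identifier.
#' @param method method name.
#' @param states residue-state string over `M`/`i`/`o`/`U`.
#' @param sequence optional amino-acid sequence (length-checked).
#' @return object of class `tm_prediction` with `protein_id`, `method`,
#'   `states`, `helices`.
#' @export
prediction_record <- function(protein_id, method, states, sequence = NULL) {
  validate_states(states, sequence)
  structure(list(protein_id = protein_id, method = method, states = states,
                 helices = segments_from_states(states)),
            class = "tm_prediction")
}

#' @export
print.tm_annotation <- function(x, ...) {
  cat("<tm_annotation> ", x$protein_id, " [", x$convention, "], ",
      nchar(x$states), " aa, ", nrow(x$helices), " helices (",
      sum(x$helices$kind == "half_membrane"), " half-membrane)\n", sep = "")
  invisible(x)
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat("<tm_prediction> ", x$protein_id, " by ", x$method, ", ",
      nchar(x$states), " aa, ", nrow(x$helices), " helices\n", sep = "")
  invisible(x)
}

#' Construct and validate a table of protein metadata records
#'
#' One row per protein chain with the attributes the benchmark filters on:
#' chain class, phylogenetic kingdom, structure-function family, experimental
#' method and resolution, year of structure submission, and the helix profile
#' (transmembrane-only vs containing half-membrane helices).
#'
#' @param df data frame with columns `id`, `chain_class`, `kingdom`, `family`,
#'   `exp_method`, `resolution`, `year`, `helix_profile` and optionally
#'   `sequence`.
#' @return the validated data frame, classed `tm_records`.
#' @export
protein_records <- function(df) {
  req <- c("id", "chain_class", "kingdom", "family", "exp_method",
           "resolution", "year", "helix_profile")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing metadata columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate protein id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$chain_class %in% .CHAIN_CLASSES))
    stop("unknown chain_class token(s): ",
         paste(setdiff(df$chain_class, .CHAIN_CLASSES), collapse = ", "))
  if (!all(df$exp_method %in% .EXP_METHODS))
    stop("unknown exp_method token(s): ",
         paste(setdiff(df$exp_method, .EXP_METHODS), collapse = ", "))
  if (!all(df$helix_profile %in% .HELIX_PROFILES))
    stop("unknown helix_profile token(s): ",
         paste(setdiff(df$helix_profile, .HELIX_PROFILES), collapse = ", "))
  df$resolution <- as.numeric(df$resolution)
  df$year <- as.integer(df$year)
  if (any(!is.na(df$resolution) & df$resolution <= 0))
    stop("resolution must be > 0 when present")
  # helix_profile 'none' exactly for non-helical chains
  is_hel <- df$chain_class == "helical_membrane"
  if (any(is_hel & df$helix_profile == "none"))
    stop("helical_membrane records must have a tm helix profile")
  if (any(!is_hel & df$helix_profile != "none"))
    stop("non-helical records must have helix_profile 'none'")
  if ("sequence" %in% names(df)) {
    df$sequence <- toupper(df$sequence)
    for (s in df$sequence[!is.na(df$sequence)]) {
      bad <- setdiff(unique(strsplit(s, "")[[1]]), .AA_ALPHABET)
      if (length(bad))
        stop("sequence contains non-amino-acid letters: ",
             paste(bad, collapse = ", "))
    }
  }
  class(df) <- c("tm_records", "data.frame")
  df
}
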
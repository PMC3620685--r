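# Topology scores: on which side of the membrane do the N-terminus and the
# inter-helix segments sit.
#
#   orientation     per-protein: side of the first sided residue correct
#   localisation    per-protein: topography fully correct AND every observed
#                   non-membrane segment on its correct side
#   seg_topology    per-segment: observed non-membrane segments whose side is
#                   predicted correctly (strict residue majority)
#   res_topology    per-residue 3-state (i/o/M) agreement
#
# Positions where either string carries U are not scorable for sides and are
# excluded from the 3-state denominator; a prediction with no side labels at
# all yields NA ("not applicable") rather than 0.

.first_side <- function(states) {
  v <- strsplit(states, "")[[1]]
  idx <- which(v %in% c("i", "o"))
  if (!length(idx)) NA_character_ else v[idx[1L]]
}

.has_sides <- function(states) {
  any(strsplit(states, "")[[1]] %in% c("i", "o"))
}

#' N-terminal orientation correctness
#'
#' Compares the side label (`i`/`o`) of the first non-membrane, non-`U`
#' residue of the observation and the prediction.
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @return TRUE/FALSE, or `NA` when the prediction carries no side labels
#'   (topography-only method).
#' @export
orientation_correct <- function(observed_states, predicted_states) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  obs <- .first_side(observed_states)
  if (is.na(obs)) stop("observation has no sided residues")
  pred <- .first_side(predicted_states)
  if (is.na(pred)) return(NA)
  obs == pred
}

#' Per-segment topology score
#'
#' The observed segmentation defines the units: every maximal observed
#' non-membrane run (of `i` or `o`) is one segment, and it is correct iff a
#' strict majority (>50%) of its residues carry the correct predicted side
#' label. Predicted `M` or `U` at a position counts against the majority.
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @return list `correct`, `total`, `fraction`; `fraction` is `NA` when
#'   there are no sided observed segments or the prediction has no sides.
#' @export
segment_topology_score <- function(observed_states, predicted_states) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  o <- strsplit(observed_states, "")[[1]]
  p <- strsplit(predicted_states, "")[[1]]
  r <- rle(o %in% c("i", "o"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep) || !.has_sides(predicted_states))
    return(list(correct = NA_integer_, total = length(keep),
                fraction = NA_real_))
  n_ok <- 0L
  for (k in keep) {
    pos <- starts[k]:ends[k]
    if (mean(p[pos] == o[pos]) > 0.5) n_ok <- n_ok + 1L
  }
  list(correct = n_ok, total = length(keep),
       fraction = n_ok / length(keep))
}

#' Per-protein localisation correctness
#'
#' TRUE iff the topography is fully correct ([per_protein_correct()]) and
#' every observed non-membrane segment is on its correct predicted side under
#' the rule of [segment_topology_score()]. The scorer makes no alternation
#' assumption, so a prediction identical to a reference containing re-entrant
#' (same-side-flank) helices scores TRUE.
#'
#' @param match `tm_match` for this protein.
#' @param observed_states,predicted_states equal-length state strings.
#' @return TRUE/FALSE, or `NA` when the prediction carries no side labels.
#' @export
protein_localisation_correct <- function(match, observed_states,
                                         predicted_states) {
  st <- segment_topology_score(observed_states, predicted_states)
  if (is.na(st$fraction)) {
    if (!.has_sides(predicted_states)) return(NA)
    # observation has no sided segments: localisation reduces to topography
    return(per_protein_correct(match))
  }
  per_protein_correct(match) && st$correct == st$total
}

#' Per-residue 3-state topology score
#'
#' Fraction of scorable residues where the predicted 3-state label (`i`, `o`
#' or `M`) equals the observed one. Positions where either string is `U` are
#' excluded from the denominator.
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @return fraction in `[0, 1]`, or `NA` if no residue is scorable.
#' @export
residue_topology_score <- function(observed_states, predicted_states) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  o <- strsplit(observed_states, "")[[1]]
  p <- strsplit(predicted_states, "")[[1]]
  scorable <- o != "U" & p != "U"
  if (!any(scorable)) return(NA_real_)
  mean(o[scorable] == p[scorable])
}

#' Aggregate topology scores over a dataset
#'
#' Localisation and orientation are pooled over proteins, segment topology is
#' pooled over observed segments, and residue topology is a per-protein mean,
#' mirroring the topography aggregation conventions. Proteins where a score
#' is not applicable (no sides predicted) are excluded from that score.
#'
#' @param results list of per-protein score lists from [score_protein()].
#' @return list of class `tm_topology_scores` with fields `localisation`,
#'   `orientation`, `seg_topology`, `res_topology` (percent, `NA` when not
#'   applicable anywhere).
#' @export
aggregate_topology <- function(results) {
  if (!length(results)) stop("empty dataset")
  loc <- vapply(results, `[[`, logical(1), "localisation")
  ori <- vapply(results, `[[`, logical(1), "orientation")
  segc <- vapply(results, function(r) r$seg_topology$correct, integer(1))
  segt <- vapply(results, function(r) r$seg_topology$total, integer(1))
  rest <- vapply(results, `[[`, numeric(1), "res_topology")
  pct <- function(x) if (all(is.na(x))) NA_real_ else 100 * mean(x, na.rm = TRUE)
  seg_total <- sum(segt[!is.na(segc)])
  structure(list(
    localisation = pct(loc),
    orientation = pct(ori),
    seg_topology = if (seg_total > 0L)
      100 * sum(segc, na.rm = TRUE) / seg_total else NA_real_,
    res_topology = pct(rest)
  ), class = "tm_topology_scores")
}
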
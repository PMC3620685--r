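# Reconciliation between annotation conventions.
#
# OPM annotates membrane helices with oriented inside/outside sides. PDBTM
# annotates the two membrane faces without saying which is inside, and keeps
# a separate "loop" state for short membrane-dipping segments (the coil part
# of re-entrant helices). Three mechanical steps connect the conventions:
#   * promote_loops(): count PDBTM loop states as membrane helices
#     ("PDBTM membrane helices and loops" reference choice);
#   * map_sides(): orient PDBTM's two anonymous faces as inside/outside by
#     majority agreement with the OPM annotation of the same chain;
#   * flag_half_membrane(): call re-entrant helices from flank context.

#' Promote PDBTM loop states to membrane helices
#'
#' Every maximal run of `L` becomes `M`. A promoted run adjacent to an
#' existing helix merges with it into a single helix. Helix kinds are
#' recomputed after merging: an isolated promoted run is flagged
#' `half_membrane` (it was a PDBTM membrane loop); a merged run takes its kind
#' from the flanking side labels, like [flag_half_membrane()].
#'
#' Idempotent: applying it to an annotation without `L` only retags the
#' convention.
#'
#' @param annotation `tm_annotation` with convention `pdbtm` (or
#'   `pdbtm_with_loops`, in which case it is returned unchanged).
#' @return `tm_annotation` with convention `pdbtm_with_loops`.
#' @export
promote_loops <- function(annotation) {
  if (!inherits(annotation, "tm_annotation"))
    stop("'annotation' must be a tm_annotation")
  if (annotation$convention == "pdbtm_with_loops")
    return(annotation)
  if (annotation$convention != "pdbtm")
    stop("promote_loops() expects a pdbtm-convention annotation, got ",
         annotation$convention)
  v <- strsplit(annotation$states, "")[[1]]
  was_L <- v == "L"
  was_M <- v == "M"
  v[was_L] <- "M"
  states <- paste(v, collapse = "")
  helices <- segments_from_states(states)
  kind <- .kinds_from_flanks(states, helices)
  if (nrow(helices)) {
    for (k in seq_len(nrow(helices))) {
      pos <- helices$start[k]:helices$end[k]
      # purely-promoted run: was a PDBTM membrane loop, i.e. a re-entrant
      # half-membrane element regardless of flank labels
      if (all(was_L[pos])) kind[k] <- "half_membrane"
    }
  }
  helices$kind <- kind
  out <- annotation
  out$states <- states
  out$helices <- helices
  out$convention <- "pdbtm_with_loops"
  out
}

#' Orient PDBTM membrane sides as inside/outside using OPM
#'
#' PDBTM names the two membrane faces without orientation (placeholder labels
#' `1`/`2`, or an arbitrary provisional `i`/`o` labelling). The orientation is
#' recovered by comparing against the OPM annotation of the same chain: over
#' all positions where the PDBTM string carries a side label and the OPM
#' string carries `i` or `o`, choose the assignment (side1 to inside or side1
#' to outside) that maximises residue agreement. An exact 50/50 split is
#' ambiguous and raises an error rather than guessing.
#'
#' @param pdbtm_states state string whose sides are placeholders `1`/`2` (or
#'   provisional `i`/`o`, treated as side1/side2).
#' @param opm_states oriented state string of the same chain (same length).
#' @return list with `states` (the oriented string, placeholders replaced by
#'   `i`/`o`) and `side_map` (list `side1_label`, `side2_label`,
#'   `agreement_fraction`).
#' @export
map_sides <- function(pdbtm_states, opm_states) {
  if (nchar(pdbtm_states) != nchar(opm_states))
    stop("state strings differ in length")
  validate_states(pdbtm_states, allow_loop = TRUE, allow_placeholder = TRUE)
  validate_states(opm_states)
  p <- strsplit(pdbtm_states, "")[[1]]
  q <- strsplit(opm_states, "")[[1]]
  s1 <- p %in% c("1", "i")
  s2 <- p %in% c("2", "o")
  cmp <- (s1 | s2) & q %in% c("i", "o")
  n_cmp <- sum(cmp)
  if (n_cmp == 0L)
    stop("no comparable residues between the two annotations")
  # agreement under mapping side1 -> i, side2 -> o
  agree_io <- sum((s1 & q == "i" & cmp) | (s2 & q == "o" & cmp)) / n_cmp
  if (agree_io == 0.5)
    stop("ambiguous side mapping: exactly 50/50 agreement over ",
         n_cmp, " comparable residues")
  if (agree_io > 0.5) {
    map <- c(side1_label = "i", side2_label = "o")
    agreement <- agree_io
  } else {
    map <- c(side1_label = "o", side2_label = "i")
    agreement <- 1 - agree_io
  }
  out <- p
  out[s1] <- map[["side1_label"]]
  out[s2] <- map[["side2_label"]]
  list(states = paste(out, collapse = ""),
       side_map = list(side1_label = map[["side1_label"]],
                       side2_label = map[["side2_label"]],
                       agreement_fraction = agreement))
}

#' Flag half-membrane (re-entrant) helices from flank context
#'
#' A helix whose nearest flanking non-membrane, non-unassigned side labels on
#' both sides are the same is a re-entrant (half-membrane) helix: it enters
#' and leaves the membrane on the same face. Helices at a chain terminus with
#' only one resolvable flank are full transmembrane.
#'
#' @param annotation `tm_annotation` whose states carry side labels around
#'   helices.
#' @return the annotation with `helices$kind` recomputed.
#' @export
flag_half_membrane <- function(annotation) {
  if (!inherits(annotation, "tm_annotation"))
    stop("'annotation' must be a tm_annotation")
  annotation$helices$kind <- .kinds_from_flanks(annotation$states,
                                                annotation$helices)
  annotation
}
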
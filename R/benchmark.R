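# Benchmark orchestration: select the data subset, reconcile references,
# score every method, and emit the score table, subset summary and
# per-protein visual comparisons.

#' Score one protein under one prediction
#'
#' Computes all per-protein quantities that feed the dataset aggregates:
#' the helix match, the per-protein topography flag, the per-residue
#' two-state scores (`q2`, `mcc`), Sov, and the topology scores
#' (orientation, per-segment, localisation, per-residue 3-state).
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @param min_overlap matching threshold in residues (default 3).
#' @return list of per-protein scores; `NA` marks scores that are not
#'   applicable (e.g. topology of a sideless prediction).
#' @export
score_protein <- function(observed_states, predicted_states,
                          min_overlap = 3L) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  m <- match_segments(segments_from_states(observed_states),
                      segments_from_states(predicted_states),
                      min_overlap = min_overlap)
  cc <- residue_confusion(observed_states, predicted_states)
  st <- segment_topology_score(observed_states, predicted_states)
  n_scored <- cc$tp + cc$tn + cc$fp + cc$fn
  list(match = m,
       n_observed = m$n_observed, n_predicted = m$n_predicted,
       n_pairs = nrow(m$pairs),
       topo_ok = per_protein_correct(m),
       q2 = 100 * (cc$tp + cc$tn) / n_scored,
       mcc = mcc(cc),
       sov = sov(observed_states, predicted_states),
       orientation = if (!.has_sides(observed_states)) NA else
         orientation_correct(observed_states, predicted_states),
       seg_topology = st,
       localisation = protein_localisation_correct(m, observed_states,
                                                   predicted_states),
       res_topology = residue_topology_score(observed_states,
                                             predicted_states))
}

#' Summarise a benchmark data subset
#'
#' Counts sequences, full transmembrane helices, half-membrane helices, and
#' their total over the reconciled references; the total is always
#' `#TMH + #half-membrane`.
#'
#' @param records `tm_records` for the subset.
#' @param references named list of `tm_annotation` covering the record ids.
#' @return list of class `tm_subset_summary` with `n_seqs`, `n_tmh`,
#'   `n_half`, `n_mh`, and `per_class` (named integer vector).
#' @export
summarize_subset <- function(records, references) {
  ids <- records$id
  miss <- setdiff(ids, names(references))
  if (length(miss))
    stop("no reference annotation for id(s): ", paste(miss, collapse = ", "))
  n_tmh <- 0L; n_half <- 0L
  for (id in ids) {
    h <- references[[id]]$helices
    n_tmh <- n_tmh + sum(h$kind == "full_tm")
    n_half <- n_half + sum(h$kind == "half_membrane")
  }
  per_class <- table(factor(records$chain_class, levels = .CHAIN_CLASSES))
  structure(list(n_seqs = length(ids), n_tmh = n_tmh, n_half = n_half,
                 n_mh = n_tmh + n_half,
                 per_class = stats::setNames(as.integer(per_class),
                                             names(per_class))),
            class = "tm_subset_summary")
}

#' @export
print.tm_subset_summary <- function(x, ...) {
  cat("subset: ", x$n_seqs, " seqs | #TMH ", x$n_tmh, " + #half ", x$n_half,
      " = #MH ", x$n_mh, "\n", sep = "")
  invisible(x)
}

#' Run a benchmark over a set of prediction methods
#'
#' Applies the subset configuration to the records (attribute filters, plus
#' Hobohm-2 redundancy reduction when a similarity matrix is supplied and
#' the configured threshold is set), then scores every method on the
#' selected proteins. Methods that lack predictions for some selected
#' proteins are scored on the intersection, with the per-row protein count
#' reporting the actual coverage.
#'
#' @param config `tm_subset_config`.
#' @param records `tm_records` (all candidate proteins).
#' @param references named list of `tm_annotation`.
#' @param predictions_by_method named list (method -> named list/vector of
#'   state strings or `tm_prediction` objects, keyed by protein id).
#' @param similarity optional `tm_simmatrix` for the similarity threshold.
#' @param min_overlap matching threshold in residues.
#' @return object of class `tm_score_table`: list with `table` (one row per
#'   method, full precision), `config`, `subset_ids`, `min_overlap`.
#' @export
run_benchmark <- function(config, records, references, predictions_by_method,
                          similarity = NULL, min_overlap = 3L) {
  if (!length(predictions_by_method)) stop("no methods supplied")
  sel <- filter_records(records, config)
  if (!is.na(config$similarity_threshold) && !is.null(similarity)) {
    m <- if (inherits(similarity, "tm_simmatrix")) similarity$values
    else similarity
    present <- intersect(sel$id, rownames(m))
    if (length(present)) {
      kept <- hobohm2_reduce(m[present, present, drop = FALSE],
                             config$similarity_threshold)
      # ids absent from the matrix have no known similar pair; keep them
      sel <- sel[sel$id %in% c(kept, setdiff(sel$id, present)), ,
                 drop = FALSE]
    }
  }
  if (!nrow(sel)) stop("no proteins left after filtering")
  miss_ref <- setdiff(sel$id, names(references))
  if (length(miss_ref))
    stop("no reference annotation for id(s): ",
         paste(miss_ref, collapse = ", "))
  rows <- list()
  for (method in names(predictions_by_method)) {
    preds <- predictions_by_method[[method]]
    pred_states <- vapply(preds, function(p) {
      if (inherits(p, "tm_prediction")) p$states else p
    }, character(1))
    ids <- intersect(sel$id, names(pred_states))
    if (!length(ids)) {
      rows[[method]] <- data.frame(method = method, n_proteins = 0L)
      next
    }
    results <- lapply(ids, function(id)
      score_protein(references[[id]]$states, pred_states[[id]],
                    min_overlap = min_overlap))
    topo <- aggregate_topography(results)
    topol <- aggregate_topology(results)
    rows[[method]] <- data.frame(
      method = method,
      n_proteins = length(ids),
      n_observed = topo$n_observed,
      n_predicted = topo$n_predicted,
      q_ok = topo$q_ok, sens = topo$sens, spec = topo$spec,
      boundary_exact = topo$boundary_exact,
      boundary_within2 = topo$boundary_within2,
      boundary_mad = topo$boundary_mad,
      q2 = topo$q2, mcc = topo$mcc, sov = topo$sov,
      localisation = topol$localisation,
      orientation = topol$orientation,
      seg_topology = topol$seg_topology,
      res_topology = topol$res_topology)
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[, all_cols]
  })
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 config = config, subset_ids = sel$id,
                 min_overlap = as.integer(min_overlap)),
            class = "tm_score_table")
}

#' @export
print.tm_score_table <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  # human-readable table is integer-rounded (except mad, 1 decimal); the
  # full-precision values live in the object / TSV output
  shown <- tab
  for (col in names(tab)[num]) {
    shown[[col]] <- if (col == "boundary_mad") round(tab[[col]], 1)
    else round(tab[[col]])
  }
  cat("Benchmark over", length(x$subset_ids), "proteins (min_overlap =",
      x$min_overlap, "residues)\n")
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Write the full-precision score table to TSV
#'
#' Not-applicable scores are written as the literal `NA`, never as 0.
#'
#' @param score_table `tm_score_table`.
#' @param path output TSV.
#' @export
write_score_table <- function(score_table, path) {
  utils::write.table(score_table$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a full benchmark report directory
#'
#' Emits the machine-readable full-precision score table (`scores.tsv`), the
#' integer-rounded human table (`scores.txt`), the subset summary
#' (`subset.txt`), and one visual comparison file per scored protein and
#' method under `comparisons/<method>/`. Output is deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param score_table `tm_score_table` from [run_benchmark()].
#' @param records `tm_records` including a `sequence` column.
#' @param references named list of `tm_annotation`.
#' @param predictions_by_method named list of per-method prediction sets.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark_report <- function(score_table, records, references,
                                   predictions_by_method, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_score_table(score_table, file.path(out_dir, "scores.tsv"))
  writeLines(utils::capture.output(print(score_table)),
             file.path(out_dir, "scores.txt"))
  sel <- records[records$id %in% score_table$subset_ids, , drop = FALSE]
  writeLines(utils::capture.output(print(summarize_subset(sel, references))),
             file.path(out_dir, "subset.txt"))
  if ("sequence" %in% names(records)) {
    seqs <- stats::setNames(records$sequence, records$id)
    for (method in names(predictions_by_method)) {
      mdir <- file.path(out_dir, "comparisons", method)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      preds <- predictions_by_method[[method]]
      pred_states <- vapply(preds, function(p) {
        if (inherits(p, "tm_prediction")) p$states else p
      }, character(1))
      for (id in intersect(score_table$subset_ids, names(pred_states))) {
        writeLines(render_comparison(seqs[[id]], references[[id]]$states,
                                     pred_states[[id]], id = id),
                   file.path(mdir, paste0(id, ".txt")))
      }
    }
  }
  invisible(out_dir)
}

#' Render a per-protein visual comparison
#'
#' Fixed-width text block with a machine-readable comment header and four
#' tracks per 60-column line block: amino-acid sequence, observed states,
#' predicted states, and a mismatch track marking topography disagreements
#' (`*` where exactly one of the two strings has `M`) and side disagreements
#' (`~` where both are non-membrane with different `i`/`o` labels).
#'
#' @param sequence amino-acid sequence.
#' @param observed,predicted equal-length state strings.
#' @param id protein id for the header.
#' @param width wrap width in columns (default 60).
#' @return character scalar (the text block, lines joined by newline).
#' @export
render_comparison <- function(sequence, observed, predicted, id = "?",
                              width = 60L) {
  n <- nchar(sequence)
  if (nchar(observed) != n || nchar(predicted) != n)
    stop("sequence and state strings differ in length")
  o <- strsplit(observed, "")[[1]]
  p <- strsplit(predicted, "")[[1]]
  mism <- rep(" ", n)
  mism[xor(o == "M", p == "M")] <- "*"
  side_diff <- o %in% c("i", "o") & p %in% c("i", "o") & o != p
  mism[side_diff] <- "~"
  lines <- c(paste0("# id: ", id),
             paste0("# length: ", n),
             paste0("# tracks: SEQ OBS PRD DIF"),
             paste0("# mismatches: ", sum(mism != " ")))
  for (from in seq(1L, n, by = width)) {
    to <- min(from + width - 1L, n)
    lines <- c(lines,
               sprintf("SEQ %6d %s", from, substr(sequence, from, to)),
               sprintf("OBS        %s", substr(observed, from, to)),
               sprintf("PRD        %s", substr(predicted, from, to)),
               sprintf("DIF        %s",
                       paste(mism[from:to], collapse = "")),
               "")
  }
  paste(lines, collapse = "\n")
}
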
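# Topography scores: where are the membrane helices along the sequence,
# irrespective of sidedness.
#
# Score hierarchy:
#   q_ok            per-protein: all and only all observed helices predicted
#   sens / spec     per-segment: matched observed / matched predicted helices
#   boundary_*      helix-end placement (exact, within +/-2, mean abs dev)
#   q2, mcc         per-residue two-state (M vs not-M)
#   sov             segment overlap score for the M state (Zemla-style)

.seg_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

#' Match observed and predicted helices one-to-one
#'
#' Finds the one-to-one pairing of observed and predicted helix segments that
#' maximises the number of pairs with overlap of at least `min_overlap`
#' residues, breaking ties by larger total overlap, then by pairing the
#' leftmost observed helix with the leftmost eligible predicted helix. A
#' predicted helix can satisfy only one observed helix, so merged or split
#' predictions are penalised. Because segments within each list are disjoint
#' and sorted, every valid matching is non-crossing, and an exact dynamic
#' programme over the two lists finds the optimum deterministically.
#'
#' @param observed,predicted helix tables (data frames with `start`, `end`)
#'   or objects with a `helices` element.
#' @param min_overlap minimum overlap in residues for a pair (default 3).
#' @return object of class `tm_match`: list with `pairs` (data frame
#'   `obs_idx`, `pred_idx`, `obs_start`, `obs_end`, `pred_start`, `pred_end`,
#'   `overlap`), `unmatched_observed`, `unmatched_predicted` (integer index
#'   vectors), `n_observed`, `n_predicted`, `min_overlap`.
#' @export
match_segments <- function(observed, predicted, min_overlap = 3L) {
  obs <- .as_segments(observed)
  pred <- .as_segments(predicted)
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("'min_overlap' must be >= 1")
  n <- nrow(obs); m <- nrow(pred)
  ov <- matrix(0L, n, m)
  if (n && m)
    for (i in seq_len(n)) for (j in seq_len(m))
      ov[i, j] <- .seg_overlap(obs$start[i], obs$end[i],
                               pred$start[j], pred$end[j])
  # suffix DP: best (pairs, total overlap) over obs i.., pred j..
  pairs_dp <- matrix(0L, n + 1L, m + 1L)
  ovl_dp <- matrix(0L, n + 1L, m + 1L)
  if (n && m) {
    for (i in n:1L) for (j in m:1L) {
      best_p <- pairs_dp[i + 1L, j]; best_o <- ovl_dp[i + 1L, j]   # skip obs
      if (pairs_dp[i, j + 1L] > best_p ||
          (pairs_dp[i, j + 1L] == best_p && ovl_dp[i, j + 1L] > best_o)) {
        best_p <- pairs_dp[i, j + 1L]; best_o <- ovl_dp[i, j + 1L] # skip pred
      }
      if (ov[i, j] >= min_overlap) {
        mp <- pairs_dp[i + 1L, j + 1L] + 1L
        mo <- ovl_dp[i + 1L, j + 1L] + ov[i, j]
        if (mp > best_p || (mp == best_p && mo > best_o)) {
          best_p <- mp; best_o <- mo
        }
      }
      pairs_dp[i, j] <- best_p; ovl_dp[i, j] <- best_o
    }
  }
  # reconstruct; on ties prefer match, then skip-pred (keeps the current
  # observed helix available for a later predicted helix -> leftmost observed
  # is matched first)
  pr <- list(); i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    if (ov[i, j] >= min_overlap &&
        pairs_dp[i, j] == pairs_dp[i + 1L, j + 1L] + 1L &&
        ovl_dp[i, j] == ovl_dp[i + 1L, j + 1L] + ov[i, j]) {
      pr[[length(pr) + 1L]] <- c(i, j, ov[i, j])
      i <- i + 1L; j <- j + 1L
    } else if (pairs_dp[i, j] == pairs_dp[i, j + 1L] &&
               ovl_dp[i, j] == ovl_dp[i, j + 1L]) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(pr)) {
    pm <- do.call(rbind, pr)
    pairs <- data.frame(obs_idx = pm[, 1L], pred_idx = pm[, 2L],
                        obs_start = obs$start[pm[, 1L]],
                        obs_end = obs$end[pm[, 1L]],
                        pred_start = pred$start[pm[, 2L]],
                        pred_end = pred$end[pm[, 2L]],
                        overlap = pm[, 3L])
  } else {
    pairs <- data.frame(obs_idx = integer(0), pred_idx = integer(0),
                        obs_start = integer(0), obs_end = integer(0),
                        pred_start = integer(0), pred_end = integer(0),
                        overlap = integer(0))
  }
  structure(list(pairs = pairs,
                 unmatched_observed = setdiff(seq_len(n), pairs$obs_idx),
                 unmatched_predicted = setdiff(seq_len(m), pairs$pred_idx),
                 n_observed = n, n_predicted = m,
                 min_overlap = min_overlap),
            class = "tm_match")
}

.as_segments <- function(x) {
  if (inherits(x, c("tm_annotation", "tm_prediction"))) x <- x$helices
  if (is.character(x) && length(x) == 1L) x <- segments_from_states(x)
  if (!is.data.frame(x)) stop("expected a segment table, annotation or states")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  .validate_segments(x)
  x
}

#' Is a protein's topography fully correct?
#'
#' TRUE iff every observed helix is matched and every predicted helix is
#' matched (no missed and no spurious helices). Vacuously TRUE when neither
#' side has helices.
#'
#' @param match `tm_match` from [match_segments()].
#' @return logical.
#' @export
per_protein_correct <- function(match) {
  nrow(match$pairs) == match$n_observed &&
    nrow(match$pairs) == match$n_predicted
}

#' Pooled per-segment sensitivity and specificity
#'
#' Sensitivity: percentage of observed (reference) helices matched by a
#' predicted helix. Specificity: percentage of predicted helices that match
#' an observed helix. Pooled over all proteins' segments.
#'
#' @param matches list of `tm_match` objects.
#' @return list with `sens`, `spec` (percent, `NA` when the respective
#'   denominator is zero), `n_pairs`, `n_observed`, `n_predicted`.
#' @export
dataset_segment_scores <- function(matches) {
  if (inherits(matches, "tm_match")) matches <- list(matches)
  np <- sum(vapply(matches, function(m) nrow(m$pairs), integer(1)))
  no <- sum(vapply(matches, function(m) m$n_observed, integer(1)))
  npr <- sum(vapply(matches, function(m) m$n_predicted, integer(1)))
  list(sens = if (no > 0L) 100 * np / no else NA_real_,
       spec = if (npr > 0L) 100 * np / npr else NA_real_,
       n_pairs = np, n_observed = no, n_predicted = npr)
}

#' Helix boundary accuracy over matched pairs
#'
#' Each matched pair contributes two end deviations,
#' `|obs_start - pred_start|` and `|obs_end - pred_end|`. Three variants are
#' reported: the percentage of ends placed exactly, the percentage within
#' +/-2 residues, and the mean absolute deviation in residues.
#'
#' @param matches list of `tm_match` objects (or a single one).
#' @return list `boundary_exact`, `boundary_within2` (percent),
#'   `boundary_mad` (residues), `n_ends`; all score fields `NA` when there
#'   are no matched pairs.
#' @export
boundary_accuracy <- function(matches) {
  if (inherits(matches, "tm_match")) matches <- list(matches)
  devs <- unlist(lapply(matches, function(m) {
    if (!nrow(m$pairs)) return(numeric(0))
    c(abs(m$pairs$obs_start - m$pairs$pred_start),
      abs(m$pairs$obs_end - m$pairs$pred_end))
  }))
  if (!length(devs))
    return(list(boundary_exact = NA_real_, boundary_within2 = NA_real_,
                boundary_mad = NA_real_, n_ends = 0L))
  list(boundary_exact = 100 * mean(devs == 0),
       boundary_within2 = 100 * mean(devs <= 2),
       boundary_mad = mean(devs),
       n_ends = length(devs))
}

#' Per-residue two-state confusion counts
#'
#' Membrane (`M`) is the positive class; every other state, including `U`,
#' counts as non-membrane on both sides of the comparison.
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @return list `tp`, `fp`, `tn`, `fn` (residue counts).
#' @export
residue_confusion <- function(observed_states, predicted_states) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  o <- strsplit(observed_states, "")[[1]] == "M"
  p <- strsplit(predicted_states, "")[[1]] == "M"
  list(tp = sum(o & p), fp = sum(!o & p), tn = sum(!o & !p), fn = sum(o & !p))
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; if any factor of
#' the denominator is zero the score is 0 by convention.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn`.
#' @return numeric in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Segment overlap (Sov) score for the membrane state
#'
#' Zemla-style segment overlap for the two-state (M vs not-M) problem. For
#' every observed segment s1 and each predicted segment s2 overlapping it,
#' the pair contributes `len(s1) * (minov + delta) / maxov`, where `minov` is
#' the length of their intersection, `maxov` the length of their union span,
#' and `delta = min(maxov - minov, minov, floor(len(s1)/2),
#' floor(len(s2)/2))`. Observed segments with no overlapping prediction
#' contribute `len(s1)` to the normalisation only. The result is scaled to
#' `[0, 100]`.
#'
#' @param observed_states,predicted_states equal-length state strings.
#' @return numeric Sov in `[0, 100]`, or `NA` if the observation contains no
#'   membrane segment.
#' @export
sov <- function(observed_states, predicted_states) {
  if (nchar(observed_states) != nchar(predicted_states))
    stop("state strings differ in length")
  s_obs <- segments_from_states(observed_states)
  s_pred <- segments_from_states(predicted_states)
  if (!nrow(s_obs)) return(NA_real_)
  num <- 0
  den <- 0
  for (i in seq_len(nrow(s_obs))) {
    len1 <- s_obs$end[i] - s_obs$start[i] + 1L
    hit <- FALSE
    if (nrow(s_pred)) {
      for (j in seq_len(nrow(s_pred))) {
        minov <- .seg_overlap(s_obs$start[i], s_obs$end[i],
                              s_pred$start[j], s_pred$end[j])
        if (minov == 0L) next
        hit <- TRUE
        len2 <- s_pred$end[j] - s_pred$start[j] + 1L
        maxov <- max(s_obs$end[i], s_pred$end[j]) -
          min(s_obs$start[i], s_pred$start[j]) + 1L
        delta <- min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
        num <- num + len1 * (minov + delta) / maxov
        den <- den + len1
      }
    }
    if (!hit) den <- den + len1
  }
  100 * num / den
}

#' Aggregate topography scores over a dataset
#'
#' Per-protein fractions (`q_ok`) are pooled over proteins; per-segment
#' sensitivity/specificity are pooled over segments; boundary scores are
#' pooled over matched helix ends; the per-residue scores (`q2`, `mcc`,
#' `sov`) are computed per protein and averaged with equal protein weight
#' (proteins where a score is undefined are excluded from its mean).
#'
#' @param results list of per-protein score lists from [score_protein()].
#' @return list of class `tm_topography_scores` with fields `q_ok`, `sens`,
#'   `spec`, `boundary_exact`, `boundary_within2`, `boundary_mad`, `q2`,
#'   `mcc`, `sov`, and counts `n_proteins`, `n_observed`, `n_predicted`.
#' @export
aggregate_topography <- function(results) {
  if (!length(results)) stop("empty dataset")
  matches <- lapply(results, `[[`, "match")
  seg <- dataset_segment_scores(matches)
  bnd <- boundary_accuracy(matches)
  ok <- vapply(results, `[[`, logical(1), "topo_ok")
  q2 <- vapply(results, `[[`, numeric(1), "q2")
  mccs <- vapply(results, `[[`, numeric(1), "mcc")
  sovs <- vapply(results, `[[`, numeric(1), "sov")
  structure(list(
    q_ok = 100 * mean(ok),
    sens = seg$sens, spec = seg$spec,
    boundary_exact = bnd$boundary_exact,
    boundary_within2 = bnd$boundary_within2,
    boundary_mad = bnd$boundary_mad,
    q2 = mean(q2, na.rm = TRUE),
    mcc = mean(mccs, na.rm = TRUE),
    sov = if (all(is.na(sovs))) NA_real_ else mean(sovs, na.rm = TRUE),
    n_proteins = length(results),
    n_observed = seg$n_observed,
    n_predicted = seg$n_predicted
  ), class = "tm_topography_scores")
}
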
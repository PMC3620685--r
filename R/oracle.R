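# Independent oracle: expected metric values computed from a perturbation
# log by literal, brute-force code paths — exhaustive enumeration for the
# helix matching, explicit per-position loops for the residue counts, and a
# literal transcription of the Sov formula over residue index sets. None of
# these routines share code with the metric modules; their agreement with
# the fast implementations is the package's central correctness property.

# Exhaustive one-to-one matcher: enumerate every valid matching and keep the
# best by (number of pairs, total overlap, lexicographically smallest pair
# sequence). Feasible because synthetic fixtures keep helix counts small.
.oracle_match <- function(obs, pred, min_overlap = 3L) {
  n <- nrow(obs); m <- nrow(pred)
  ov <- matrix(0L, max(n, 1L), max(m, 1L))
  if (n && m)
    for (i in seq_len(n)) for (j in seq_len(m))
      ov[i, j] <- max(0L, min(obs$end[i], pred$end[j]) -
                        max(obs$start[i], pred$start[j]) + 1L)
  best <- NULL
  consider <- function(pairs, tot) {
    np <- if (is.null(pairs)) 0L else nrow(pairs)
    seqv <- if (np) as.vector(t(pairs)) else integer(0)
    if (is.null(best)) { best <<- list(np = np, tot = tot, seqv = seqv,
                                       pairs = pairs); return() }
    if (np > best$np || (np == best$np && tot > best$tot)) {
      best <<- list(np = np, tot = tot, seqv = seqv, pairs = pairs)
    } else if (np == best$np && tot == best$tot && np > 0L) {
      for (k in seq_along(seqv)) {
        if (seqv[k] < best$seqv[k]) {
          best <<- list(np = np, tot = tot, seqv = seqv, pairs = pairs)
          break
        }
        if (seqv[k] > best$seqv[k]) break
      }
    }
  }
  used <- rep(FALSE, m)
  rec <- function(i, pairs, tot) {
    if (i > n) { consider(pairs, tot); return() }
    rec(i + 1L, pairs, tot)                       # leave obs i unmatched
    if (m) for (j in seq_len(m)) {
      if (!used[j] && ov[i, j] >= min_overlap) {
        used[j] <<- TRUE
        rec(i + 1L, rbind(pairs, c(i, j)), tot + ov[i, j])
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, NULL, 0L)
  pairs <- best$pairs
  if (is.null(pairs)) pairs <- matrix(integer(0), 0L, 2L)
  list(pairs = data.frame(obs_idx = pairs[, 1L], pred_idx = pairs[, 2L]),
       n_pairs = nrow(pairs), n_observed = n, n_predicted = m,
       overlap_total = best$tot,
       devs = if (nrow(pairs)) c(abs(obs$start[pairs[, 1L]] -
                                       pred$start[pairs[, 2L]]),
                                 abs(obs$end[pairs[, 1L]] -
                                       pred$end[pairs[, 2L]]))
       else numeric(0))
}

# Literal Sov transcription over residue index sets.
.oracle_sov <- function(obs_states, pred_states) {
  o <- strsplit(obs_states, "")[[1]]
  p <- strsplit(pred_states, "")[[1]]
  runs <- function(v) {
    out <- list(); k <- 1L
    while (k <= length(v)) {
      if (v[k] == "M") {
        s <- k
        while (k <= length(v) && v[k] == "M") k <- k + 1L
        out[[length(out) + 1L]] <- s:(k - 1L)
      } else k <- k + 1L
    }
    out
  }
  S1 <- runs(o); S2 <- runs(p)
  if (!length(S1)) return(NA_real_)
  num <- 0; den <- 0
  for (s1 in S1) {
    overlapped <- FALSE
    for (s2 in S2) {
      inter <- intersect(s1, s2)
      if (!length(inter)) next
      overlapped <- TRUE
      minov <- length(inter)
      maxov <- max(c(s1, s2)) - min(c(s1, s2)) + 1L
      delta <- min(maxov - minov, minov,
                   floor(length(s1) / 2), floor(length(s2) / 2))
      num <- num + length(s1) * (minov + delta) / maxov
      den <- den + length(s1)
    }
    if (!overlapped) den <- den + length(s1)
  }
  100 * num / den
}

# Per-position two-state counts by explicit loop.
.oracle_confusion <- function(obs_states, pred_states) {
  o <- strsplit(obs_states, "")[[1]]
  p <- strsplit(pred_states, "")[[1]]
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(o)) {
    om <- o[k] == "M"; pm <- p[k] == "M"
    if (om && pm) tp <- tp + 1L
    else if (!om && pm) fp <- fp + 1L
    else if (om && !pm) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

.oracle_mcc <- function(cc) {
  f1 <- cc$tp + cc$fp; f2 <- cc$tp + cc$fn
  f3 <- cc$tn + cc$fp; f4 <- cc$tn + cc$fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (as.numeric(cc$tp) * cc$tn - as.numeric(cc$fp) * cc$fn) /
    (sqrt(f1) * sqrt(f2) * sqrt(f3) * sqrt(f4))
}

# Literal 3-state and per-segment topology scoring.
.oracle_topology <- function(obs_states, pred_states) {
  o <- strsplit(obs_states, "")[[1]]
  p <- strsplit(pred_states, "")[[1]]
  pred_has_sides <- any(p %in% c("i", "o"))
  # orientation: first sided residue of each
  fs <- function(v) { for (x in v) if (x %in% c("i", "o")) return(x); NA }
  orientation <- if (!pred_has_sides || is.na(fs(o))) NA else
    fs(o) == fs(p)
  # observed non-membrane segments: maximal runs of sided states, each
  # correct iff a strict majority of its residues carries the observed side
  seg_correct <- 0L; seg_total <- 0L
  k <- 1L
  while (k <= length(o)) {
    if (o[k] %in% c("i", "o")) {
      s <- k
      while (k <= length(o) && o[k] %in% c("i", "o")) k <- k + 1L
      seg_total <- seg_total + 1L
      hits <- 0L
      for (q in s:(k - 1L)) if (p[q] == o[q]) hits <- hits + 1L
      if (hits / (k - s) > 0.5) seg_correct <- seg_correct + 1L
    } else k <- k + 1L
  }
  res_num <- 0L; res_den <- 0L
  for (q in seq_along(o)) {
    if (o[q] != "U" && p[q] != "U") {
      res_den <- res_den + 1L
      if (o[q] == p[q]) res_num <- res_num + 1L
    }
  }
  list(orientation = orientation,
       seg_correct = if (pred_has_sides && seg_total > 0L) seg_correct
       else NA_integer_,
       seg_total = seg_total,
       res_topology = if (res_den > 0L) res_num / res_den else NA_real_,
       pred_has_sides = pred_has_sides)
}

#' Expected per-protein scores from a perturbation log
#'
#' Replays the log against the reference and computes every topography and
#' topology score through independent literal code paths: exhaustive
#' enumeration for the helix matching, per-position loops for residue
#' counts, and a direct transcription of the Sov formula. Used as the oracle
#' that the fast metric implementations must reproduce.
#'
#' @param reference `tm_annotation`.
#' @param log perturbation log from [perturb()].
#' @param min_overlap matching threshold in residues.
#' @return list with the same score fields as [score_protein()].
#' @export
expected_scores_from_log <- function(reference, log, min_overlap = 3L) {
  pred_states <- replay_log(reference, log)
  obs_states <- reference$states
  obs <- reference$helices
  pred <- segments_from_states(pred_states)
  m <- .oracle_match(obs, pred, min_overlap)
  cc <- .oracle_confusion(obs_states, pred_states)
  topo_ok <- m$n_pairs == m$n_observed && m$n_pairs == m$n_predicted
  topol <- .oracle_topology(obs_states, pred_states)
  loc <- if (!topol$pred_has_sides) {
    NA
  } else if (is.na(topol$seg_correct)) {
    topo_ok
  } else {
    topo_ok && topol$seg_correct == topol$seg_total
  }
  list(protein_id = reference$protein_id,
       n_observed = m$n_observed, n_predicted = m$n_predicted,
       n_pairs = m$n_pairs,
       boundary_devs = sort(m$devs),
       topo_ok = topo_ok,
       q2 = 100 * (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
       mcc = .oracle_mcc(cc),
       sov = .oracle_sov(obs_states, pred_states),
       orientation = if (is.na(topol$orientation)) NA else topol$orientation,
       seg_topology = list(correct = topol$seg_correct,
                           total = topol$seg_total,
                           fraction = if (is.na(topol$seg_correct) ||
                                          topol$seg_total == 0L) NA_real_
                           else topol$seg_correct / topol$seg_total),
       localisation = loc,
       res_topology = topol$res_topology)
}
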
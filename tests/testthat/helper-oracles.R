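# Independent test oracles, deliberately coded by different routes than the
# package (and than the package's own expected_scores_from_log): a literal
# transcription of the published Sov formula driven by regex-extracted
# segments, and an exhaustive-enumeration matcher that returns the maximum
# achievable pair count.

# Segments of the M state via regex (the package uses rle()).
segments_regex <- function(states) {
  m <- gregexpr("M+", states)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Literal Sov (two-state, M positive), per the published definition:
# Sov = 100/N * sum over overlapping pairs (s1,s2) of
#       len(s1) * (minov + delta) / maxov,
# N = sum of len(s1) over pairs + len(s1) over observed segments with no
# overlap, delta = min(maxov-minov, minov, len(s1)%/%2, len(s2)%/%2).
sov_oracle <- function(obs_states, pred_states) {
  s1s <- segments_regex(obs_states)
  s2s <- segments_regex(pred_states)
  if (!nrow(s1s)) return(NA_real_)
  total <- 0
  norm <- 0
  for (i in seq_len(nrow(s1s))) {
    r1 <- s1s$start[i]:s1s$end[i]
    len1 <- length(r1)
    any_ov <- FALSE
    for (j in seq_len(nrow(s2s))) {
      r2 <- s2s$start[j]:s2s$end[j]
      common <- intersect(r1, r2)
      if (!length(common)) next
      any_ov <- TRUE
      minov <- length(common)
      maxov <- length(min(c(r1, r2)):max(c(r1, r2)))
      delta <- min(maxov - minov, minov, len1 %/% 2, length(r2) %/% 2)
      total <- total + len1 * (minov + delta) / maxov
      norm <- norm + len1
    }
    if (!any_ov) norm <- norm + len1
  }
  100 * total / norm
}

# Maximum achievable number of one-to-one pairs with overlap >= t, by
# exhaustive recursion over all injective assignments.
max_pairs_oracle <- function(obs, pred, t) {
  n <- nrow(obs); m <- nrow(pred)
  if (!n || !m) return(0L)
  ovl <- function(i, j)
    max(0L, min(obs$end[i], pred$end[j]) - max(obs$start[i], pred$start[j]) + 1L)
  best <- 0L
  rec <- function(i, used, acc) {
    if (acc + (n - i + 1L) <= best) return()  # cannot beat best
    if (i > n) { best <<- max(best, acc); return() }
    for (j in seq_len(m)) {
      if (!used[j] && ovl(i, j) >= t) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + 1L)
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, acc)
  }
  rec(1L, rep(FALSE, m), 0L)
  best
}

# Random disjoint sorted segment list on a chain of length L.
random_segments <- function(L, max_segs = 4L) {
  k <- sample(0:max_segs, 1L)
  if (!k) return(data.frame(start = integer(0), end = integer(0)))
  cuts <- sort(sample(seq_len(L), min(2L * k, L)))
  if (length(cuts) %% 2L) cuts <- cuts[-length(cuts)]
  if (!length(cuts)) return(data.frame(start = integer(0), end = integer(0)))
  st <- cuts[seq(1, length(cuts), 2)]
  en <- cuts[seq(2, length(cuts), 2)]
  keep <- c(TRUE, st[-1] - en[-length(en)] >= 2L)
  # enforce the >=1 residue gap invariant
  data.frame(start = st[keep], end = en[keep])
}

# Random state string with alternating sides and occasional U.
random_states <- function(L, p_m = 0.3) {
  segs <- random_segments(L)
  fill <- paste(rep(sample(c("i", "o"), 1L), L), collapse = "")
  states_from_segments(segs, L, side_fill = fill)
}
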
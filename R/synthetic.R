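# Synthetic fixtures: membrane-protein topologies with known reference
# annotations, plus predictions derived from them by controlled, logged
# perturbations. Because every edit is logged, every benchmark metric has an
# expected value computable by an independent code path
# (expected_scores_from_log), which is the package's main test oracle.
#
# Generated chains follow the canonical grammar of helical membrane
# topologies: alternating inside/outside loops separated by full
# transmembrane helices, except around half-membrane (re-entrant) helices,
# whose flanking loops lie on the same side. Beta-barrel-like and soluble
# decoys carry no membrane annotation at all (all-U reference states).
# Amino-acid content is cosmetic (hydrophobic-biased inside membrane runs,
# polar elsewhere); no metric reads the sequence letters.

.HYDROPHOBIC <- c("A", "I", "L", "V", "F", "M", "W", "G", "C")

# sample() interprets a scalar first argument as 1:x; these helpers keep
# degenerate ranges (e.g. helix_count_range = c(3, 3)) honest
.sample_range <- function(lo, hi, n = 1L) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  sample(lo:hi, n, replace = TRUE)
}
.sample1 <- function(v) v[sample.int(length(v), 1L)]
.POLAR <- c("D", "E", "K", "R", "N", "Q", "S", "T", "H", "P", "Y")

#' Specification for the synthetic dataset generator
#'
#' Defaults emulate the composition of a structure-derived benchmark set:
#' roughly 46% helical membrane chains, 9% beta-barrel decoys and 45% soluble
#' decoys, with about one in ten membrane helices re-entrant so that a
#' realistic minority of chains (~15-20%) contains at least one half-membrane
#' helix. Helix lengths default to the canonical 15-30 residue transmembrane
#' span.
#'
#' @param n_proteins number of chains to generate.
#' @param helix_count_range integer range of helices per helical chain.
#' @param helix_length_range helix length range in residues (default 15-30).
#' @param loop_length_range loop length range in residues.
#' @param p_half_membrane probability that a helix is re-entrant.
#' @param n_terminal_side `"i"`, `"o"` or `"random"`.
#' @param class_mix named proportions over `helical_membrane`,
#'   `beta_barrel`, `soluble`.
#' @param seed integer; fixes all randomness. One seed drives a splittable
#'   scheme (a per-protein seed stream), so increasing `n_proteins` does not
#'   reshuffle earlier chains.
#' @return validated list of class `tm_generator_spec`.
#' @export
generator_spec <- function(n_proteins = 50,
                           helix_count_range = c(1L, 5L),
                           helix_length_range = c(15L, 30L),
                           loop_length_range = c(5L, 20L),
                           p_half_membrane = 0.1,
                           n_terminal_side = "random",
                           class_mix = c(helical_membrane = 481 / 1045,
                                         beta_barrel = 95 / 1045,
                                         soluble = 469 / 1045),
                           seed = 1L) {
  stopifnot(n_proteins >= 0,
            length(helix_count_range) == 2L,
            helix_count_range[1L] >= 1L,
            helix_count_range[1L] <= helix_count_range[2L],
            helix_length_range[1L] >= 3L,
            helix_length_range[1L] <= helix_length_range[2L],
            loop_length_range[1L] >= 1L,
            loop_length_range[1L] <= loop_length_range[2L],
            p_half_membrane >= 0, p_half_membrane <= 1)
  if (!n_terminal_side %in% c("i", "o", "random"))
    stop("n_terminal_side must be 'i', 'o' or 'random'")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% .CHAIN_CLASSES) || any(class_mix < 0) ||
      sum(class_mix) <= 0)
    stop("class_mix must be non-negative proportions named by chain class")
  structure(list(n_proteins = as.integer(n_proteins),
                 helix_count_range = as.integer(helix_count_range),
                 helix_length_range = as.integer(helix_length_range),
                 loop_length_range = as.integer(loop_length_range),
                 p_half_membrane = p_half_membrane,
                 n_terminal_side = n_terminal_side,
                 class_mix = class_mix / sum(class_mix),
                 seed = as.integer(seed)),
            class = "tm_generator_spec")
}

#' Specification for the prediction perturbation model
#'
#' @param boundary_jitter_max maximum absolute shift of each helix end, in
#'   residues (each end drawn uniformly from `-max..max`, then clamped so
#'   helices never touch or cross).
#' @param p_drop_helix per-helix probability of deletion.
#' @param p_insert_helix per-protein probability of inserting one spurious
#'   helix into a sufficiently long non-membrane run.
#' @param p_flip_orientation per-protein probability of swapping all
#'   inside/outside labels.
#' @param p_merge_adjacent per-adjacent-pair probability of merging two
#'   helices by filling the loop between them.
#' @param seed integer driving all perturbation randomness.
#' @return validated list of class `tm_perturbation_spec`.
#' @export
perturbation_spec <- function(boundary_jitter_max = 0L,
                              p_drop_helix = 0,
                              p_insert_helix = 0,
                              p_flip_orientation = 0,
                              p_merge_adjacent = 0,
                              seed = 1L) {
  p <- c(p_drop_helix, p_insert_helix, p_flip_orientation, p_merge_adjacent)
  stopifnot(boundary_jitter_max >= 0, all(p >= 0), all(p <= 1))
  structure(list(boundary_jitter_max = as.integer(boundary_jitter_max),
                 p_drop_helix = p_drop_helix,
                 p_insert_helix = p_insert_helix,
                 p_flip_orientation = p_flip_orientation,
                 p_merge_adjacent = p_merge_adjacent,
                 seed = as.integer(seed)),
            class = "tm_perturbation_spec")
}

# Draw a stream of sub-seeds from a master seed; the first n values are
# stable as n grows, which is what makes the generator splittable.
.sub_seeds <- function(master, n) {
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Build a deterministic topology from a helix-kind sequence
#'
#' Constructs a state string containing the given helices in order: the side
#' flips after every full transmembrane helix and repeats after every
#' half-membrane (re-entrant) helix. Useful for building fixtures with exact
#' helix counts, e.g. channel-family subsets.
#'
#' @param kinds character vector over `full_tm` / `half_membrane`.
#' @param helix_length,loop_length fixed lengths in residues.
#' @param first_side side of the N-terminal loop (`"i"` or `"o"`).
#' @return residue-state string.
#' @export
states_from_kinds <- function(kinds, helix_length = 20L, loop_length = 6L,
                              first_side = "i") {
  stopifnot(all(kinds %in% c("full_tm", "half_membrane")),
            first_side %in% c("i", "o"))
  side <- first_side
  states <- character(0)
  for (kind in kinds) {
    states <- c(states, rep(side, loop_length), rep("M", helix_length))
    if (kind == "full_tm") side <- if (side == "i") "o" else "i"
  }
  paste(c(states, rep(side, loop_length)), collapse = "")
}

# One helical topology: segments, kinds, states.
.gen_helical <- function(spec) {
  n_h <- .sample_range(spec$helix_count_range[1L], spec$helix_count_range[2L])
  kinds <- ifelse(stats::runif(n_h) < spec$p_half_membrane,
                  "half_membrane", "full_tm")
  h_len <- .sample_range(spec$helix_length_range[1L],
                         spec$helix_length_range[2L], n_h)
  l_len <- .sample_range(spec$loop_length_range[1L],
                         spec$loop_length_range[2L], n_h + 1L)
  side <- if (spec$n_terminal_side == "random")
    sample(c("i", "o"), 1L) else spec$n_terminal_side
  states <- character(0)
  for (k in seq_len(n_h)) {
    states <- c(states, rep(side, l_len[k]), rep("M", h_len[k]))
    if (kinds[k] == "full_tm") side <- if (side == "i") "o" else "i"
  }
  states <- c(states, rep(side, l_len[n_h + 1L]))
  paste(states, collapse = "")
}

.gen_sequence <- function(states) {
  v <- strsplit(states, "")[[1]]
  aa <- ifelse(v == "M",
               sample(.HYDROPHOBIC, length(v), replace = TRUE),
               sample(.POLAR, length(v), replace = TRUE))
  paste(aa, collapse = "")
}

#' Generate a synthetic benchmark dataset
#'
#' Produces protein records (sequence plus benchmark metadata) and reference
#' annotations satisfying all annotation invariants: helices are exactly the
#' maximal `M` runs, loops alternate sides across full transmembrane helices
#' and repeat the side around half-membrane helices, and decoy chains
#' contain no membrane state. Deterministic given `spec$seed`.
#'
#' @param spec `tm_generator_spec`.
#' @param convention convention tag for the generated references.
#' @return list with `records` (`tm_records`, including sequences),
#'   `references` (named list of `tm_annotation`), `spec`.
#' @export
generate_dataset <- function(spec, convention = "opm_adjusted") {
  n <- spec$n_proteins
  seeds <- .sub_seeds(spec$seed, n)
  recs <- vector("list", n)
  refs <- vector("list", n)
  ids <- sprintf("SYN%04d", seq_len(n))
  for (idx in seq_len(n)) {
    out <- .with_seed(seeds[idx], {
      cls <- sample(names(spec$class_mix), 1L, prob = spec$class_mix)
      if (cls == "helical_membrane") {
        states <- .gen_helical(spec)
        segs <- segments_from_states(states)
        kinds <- .kinds_from_flanks(states, segs)
        profile <- if (any(kinds == "half_membrane"))
          "has_half_membrane" else "tm_only"
        family <- sample(paste0("Fam", LETTERS[1:12]), 1L)
      } else {
        states <- paste(rep("U", sample(80:300, 1L)), collapse = "")
        profile <- "none"
        family <- if (cls == "beta_barrel") "BarrelFam" else "SolubleFam"
      }
      sequence <- .gen_sequence(states)
      method <- sample(c("xray", "nmr"), 1L, prob = c(0.9, 0.1))
      list(states = states, cls = cls, profile = profile, family = family,
           sequence = sequence, method = method,
           resolution = if (method == "xray")
             round(stats::runif(1, 1.2, 4.0), 2) else NA_real_,
           year = sample(1995:2012, 1L),
           kingdom = sample(c("Bacteria", "Eukaryota", "Archaea"), 1L,
                            prob = c(0.5, 0.4, 0.1)))
    })
    recs[[idx]] <- data.frame(id = ids[idx], chain_class = out$cls,
                              kingdom = out$kingdom, family = out$family,
                              exp_method = out$method,
                              resolution = out$resolution, year = out$year,
                              helix_profile = out$profile,
                              sequence = out$sequence)
    refs[[idx]] <- reference_annotation(ids[idx], out$states,
                                        convention = convention,
                                        sequence = out$sequence)
  }
  records <- if (n) protein_records(do.call(rbind, recs)) else
    protein_records(data.frame(id = character(0), chain_class = character(0),
                               kingdom = character(0), family = character(0),
                               exp_method = character(0),
                               resolution = numeric(0), year = integer(0),
                               helix_profile = character(0),
                               sequence = character(0)))
  names(refs) <- ids
  list(records = records, references = refs, spec = spec)
}

# Fill non-membrane positions with side labels: reference side where the
# reference has one, else the nearest side label to the left, else to the
# right, else U (chains without any sides, i.e. decoys).
.fill_sides <- function(ref_states) {
  v <- strsplit(ref_states, "")[[1]]
  sided <- v %in% c("i", "o")
  if (!any(sided)) return(rep("U", length(v)))
  fill <- v
  last <- NA_character_
  for (k in seq_along(v)) {
    if (sided[k]) last <- v[k] else fill[k] <- last
  }
  nxt <- NA_character_
  for (k in rev(seq_along(v))) {
    if (sided[k]) nxt <- v[k]
    else if (is.na(fill[k])) fill[k] <- nxt
  }
  fill
}

.states_from_mask <- function(mask, sides, flipped) {
  out <- sides
  if (flipped) {
    out[sides == "i"] <- "o"
    out[sides == "o"] <- "i"
  }
  out[mask] <- "M"
  paste(out, collapse = "")
}

#' Perturb a reference annotation into a prediction with a logged error model
#'
#' Applies, in order: per-helix drops, merges of adjacent surviving helices
#' (the loop between them is filled), boundary jitter on every helix end
#' (clamped so helices stay within the chain and never touch), at most one
#' spurious helix insertion, and a whole-chain orientation flip. Every
#' applied edit is logged with its realised magnitude, so the prediction can
#' be reproduced exactly by [replay_log()] and every downstream metric has a
#' computable expected value. With all probabilities 0 and jitter 0 the
#' prediction equals the reference.
#'
#' @param reference `tm_annotation`.
#' @param pspec `tm_perturbation_spec`.
#' @param seed optional override of `pspec$seed` (used by callers that drive
#'   many proteins from one master seed).
#' @return list with `prediction` (`tm_prediction`) and `log` (data frame
#'   `op`, `h`, `a`, `b`, `c`, `d`; see [replay_log()] for the op encoding).
#' @export
perturb <- function(reference, pspec, seed = NULL) {
  if (!inherits(reference, "tm_annotation"))
    stop("'reference' must be a tm_annotation")
  if (is.null(seed)) seed <- pspec$seed
  .with_seed(seed, {
    L <- nchar(reference$states)
    segs <- reference$helices
    log <- list()
    add <- function(op, h = NA_integer_, a = NA_integer_, b = NA_integer_,
                    c = NA_integer_, d = NA_integer_) {
      log[[length(log) + 1L]] <<- data.frame(op = op, h = h, a = a, b = b,
                                             c = c, d = d)
    }
    # 1. drops
    if (nrow(segs)) {
      dropped <- stats::runif(nrow(segs)) < pspec$p_drop_helix
      for (k in which(dropped)) add("drop", h = k)
      segs <- segs[!dropped, , drop = FALSE]
    }
    # 2. merges of adjacent surviving helices (fill the loop between them)
    k <- 1L
    while (k < nrow(segs)) {
      if (stats::runif(1) < pspec$p_merge_adjacent) {
        add("merge", a = segs$end[k] + 1L, b = segs$start[k + 1L] - 1L)
        segs$end[k] <- segs$end[k + 1L]
        segs <- segs[-(k + 1L), , drop = FALSE]
      } else {
        k <- k + 1L
      }
    }
    # 3. boundary jitter, clamped against neighbours and chain ends
    if (pspec$boundary_jitter_max > 0L && nrow(segs)) {
      jmax <- pspec$boundary_jitter_max
      for (k in seq_len(nrow(segs))) {
        old_s <- segs$start[k]; old_e <- segs$end[k]
        lo <- if (k == 1L) 1L else segs$end[k - 1L] + 2L
        hi <- if (k == nrow(segs)) L else segs$start[k + 1L] - 2L
        ns <- old_s + .sample1(-jmax:jmax)
        ns <- max(lo, min(ns, old_e))
        ne <- old_e + .sample1(-jmax:jmax)
        ne <- max(ns, min(ne, hi))
        if (ns != old_s || ne != old_e)
          add("jitter", h = k, a = old_s, b = old_e, c = ns, d = ne)
        segs$start[k] <- ns; segs$end[k] <- ne
      }
    }
    # 4. spurious helix insertion into a long enough non-membrane run
    if (stats::runif(1) < pspec$p_insert_helix) {
      bounds <- rbind(c(0L, 0L), cbind(segs$start, segs$end), c(L + 1L, L + 1L))
      gaps <- data.frame(from = bounds[-nrow(bounds), 2L] + 1L,
                         to = bounds[-1L, 1L] - 1L)
      gaps <- gaps[gaps$to - gaps$from + 1L >= 9L, , drop = FALSE]
      if (nrow(gaps)) {
        g <- gaps[sample(nrow(gaps), 1L), ]
        # keep >= 2 residues clear of both neighbours (or the chain end)
        avail <- (g$to - 2L) - (g$from + 2L) + 1L
        len <- .sample1(5L:min(15L, avail))
        start <- g$from + 2L + .sample1(0L:(avail - len))
        add("insert", a = start, b = start + len - 1L)
        segs <- rbind(segs[, c("start", "end")],
                      data.frame(start = start, end = start + len - 1L))
        segs <- segs[order(segs$start), , drop = FALSE]
      }
    }
    # 5. orientation flip (only meaningful when the chain has sides)
    flipped <- FALSE
    if (.has_sides(reference$states) &&
        stats::runif(1) < pspec$p_flip_orientation) {
      add("flip")
      flipped <- TRUE
    }
    mask <- rep(FALSE, L)
    for (k in seq_len(nrow(segs))) mask[segs$start[k]:segs$end[k]] <- TRUE
    states <- .states_from_mask(mask, .fill_sides(reference$states), flipped)
    log <- if (length(log)) do.call(rbind, log) else
      data.frame(op = character(0), h = integer(0), a = integer(0),
                 b = integer(0), c = integer(0), d = integer(0))
    list(prediction = prediction_record(reference$protein_id, "perturbed",
                                        states),
         log = log)
  })
}

#' Replay a perturbation log against its reference
#'
#' Reconstructs the predicted state string from the reference annotation and
#' an edit log, using membrane-mask arithmetic rather than the segment
#' transformations of [perturb()] (an independent route; the two must agree
#' exactly). Ops: `drop` removes reference helix `h`; `merge` and `insert`
#' set positions `a..b` to membrane; `jitter` clears old span `a..b` and sets
#' new span `c..d`; `flip` swaps all side labels.
#'
#' @param reference `tm_annotation`.
#' @param log perturbation log data frame.
#' @return predicted state string.
#' @export
replay_log <- function(reference, log) {
  L <- nchar(reference$states)
  mask <- strsplit(reference$states, "")[[1]] == "M"
  flipped <- FALSE
  for (r in seq_len(nrow(log))) {
    op <- log$op[r]
    if (op == "drop") {
      h <- log$h[r]
      if (h > nrow(reference$helices)) stop("log references missing helix ", h)
      mask[reference$helices$start[h]:reference$helices$end[h]] <- FALSE
    } else if (op %in% c("merge", "insert")) {
      mask[log$a[r]:log$b[r]] <- TRUE
    } else if (op == "jitter") {
      mask[log$a[r]:log$b[r]] <- FALSE
      mask[log$c[r]:log$d[r]] <- TRUE
    } else if (op == "flip") {
      flipped <- TRUE
    } else {
      stop("unknown log op: ", op)
    }
  }
  .states_from_mask(mask, .fill_sides(reference$states), flipped)
}

#' Perturb a whole reference set with per-protein sub-seeds
#'
#' @param references named list of `tm_annotation`.
#' @param pspec `tm_perturbation_spec`; its seed drives a per-protein seed
#'   stream.
#' @param method method name attached to the predictions.
#' @return list with `predictions` (named list of `tm_prediction`) and
#'   `logs` (named list of log data frames).
#' @export
perturb_dataset <- function(references, pspec, method = "perturbed") {
  seeds <- .sub_seeds(pspec$seed, length(references))
  preds <- vector("list", length(references))
  logs <- vector("list", length(references))
  for (k in seq_along(references)) {
    out <- perturb(references[[k]], pspec, seed = seeds[k])
    out$prediction$method <- method
    preds[[k]] <- out$prediction
    logs[[k]] <- out$log
  }
  names(preds) <- names(references)
  names(logs) <- names(references)
  list(predictions = preds, logs = logs)
}
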
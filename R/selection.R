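# Benchmark dataset selection: Hobohm algorithm-2 redundancy reduction over a
# supplied pairwise similarity matrix, attribute filters, similarity ladders,
# and least-similar-decile selection for soluble decoy sets.
#
# Alignment computation itself (EMBOSS global/local identities, BLAST
# E-values) is upstream of this package: only numeric matrices and scores
# are consumed.

#' Benchmark subset configuration
#'
#' Captures the sequence-selection attributes of a benchmark run. The
#' defaults mirror the standard configuration for this kind of benchmark:
#' helical membrane proteins only, 30% similarity threshold, resolution of
#' 3.5 Angstrom or better, x-ray or solution-NMR structures, references from
#' the curated OPM-adjusted convention.
#'
#' @param similarity_threshold percent on the 20..100 step-5 ladder, or `NA`
#'   to skip redundancy reduction.
#' @param classes subset of `helical_membrane`, `beta_barrel`, `soluble`.
#' @param kingdoms,families optional label filters (`NULL` = all).
#' @param helix_profile optional `tm_only` / `has_half_membrane` filter.
#' @param max_resolution maximum resolution in Angstrom; NMR entries carry no
#'   resolution and always pass this filter.
#' @param methods subset of `xray`, `nmr`, `other`.
#' @param min_year keep structures submitted in this year or later (`NULL` =
#'   all years).
#' @param reference_convention one of `opm`, `opm_adjusted`, `pdbtm`,
#'   `pdbtm_with_loops`.
#' @return validated list of class `tm_subset_config`.
#' @export
subset_config <- function(similarity_threshold = 30,
                          classes = "helical_membrane",
                          kingdoms = NULL, families = NULL,
                          helix_profile = NULL,
                          max_resolution = 3.5,
                          methods = c("xray", "nmr"),
                          min_year = NULL,
                          reference_convention = "opm_adjusted") {
  if (!is.null(similarity_threshold) && !is.na(similarity_threshold)) {
    if (!similarity_threshold %in% seq(20, 100, by = 5))
      stop("similarity_threshold must lie on the 20..100 step-5 ladder")
  } else {
    similarity_threshold <- NA_real_
  }
  if (!all(classes %in% .CHAIN_CLASSES))
    stop("unknown class token(s): ",
         paste(setdiff(classes, .CHAIN_CLASSES), collapse = ", "))
  if (!all(methods %in% .EXP_METHODS))
    stop("unknown method token(s): ",
         paste(setdiff(methods, .EXP_METHODS), collapse = ", "))
  if (!is.null(helix_profile) &&
      !helix_profile %in% c("tm_only", "has_half_membrane"))
    stop("helix_profile filter must be 'tm_only' or 'has_half_membrane'")
  if (!is.null(max_resolution) && !is.na(max_resolution) &&
      max_resolution <= 0)
    stop("max_resolution must be > 0")
  if (!reference_convention %in% .CONVENTIONS)
    stop("unknown reference convention: ", reference_convention)
  structure(list(similarity_threshold = similarity_threshold,
                 classes = classes, kingdoms = kingdoms, families = families,
                 helix_profile = helix_profile,
                 max_resolution = max_resolution, methods = methods,
                 min_year = min_year,
                 reference_convention = reference_convention),
            class = "tm_subset_config")
}

#' Hobohm algorithm-2 redundancy reduction
#'
#' Iteratively removes the sequence with the most neighbours (pairs with
#' similarity strictly greater than `threshold`) until no pair exceeds the
#' threshold. Ties on neighbour count are broken by removing the
#' lexicographically greatest id, making the reduction deterministic.
#'
#' @param matrix `tm_simmatrix` (see [read_similarity_matrix()]) or a
#'   symmetric numeric matrix with dimnames.
#' @param threshold percent similarity in (0, 100).
#' @return character vector of retained ids (in the matrix's id order). The
#'   no-similar-pair contract is asserted on every run.
#' @export
hobohm2_reduce <- function(matrix, threshold) {
  m <- if (inherits(matrix, "tm_simmatrix")) matrix$values else matrix
  if (is.null(rownames(m))) stop("similarity matrix must have id dimnames")
  if (threshold <= 0 || threshold >= 100)
    stop("'threshold' must be in (0, 100)")
  ids <- rownames(m)
  adj <- m > threshold
  diag(adj) <- FALSE
  alive <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    if (all(deg[alive] == 0)) break
    worst <- which(deg == max(deg))
    # lexicographically greatest id among the maximal-degree candidates
    drop <- worst[order(ids[worst], decreasing = TRUE)[1L]]
    alive[drop] <- FALSE
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  kept <- ids[alive]
  sub <- m[kept, kept, drop = FALSE]
  diag(sub) <- 0
  stopifnot(all(sub <= threshold))
  kept
}

#' Redundancy reduction across the similarity ladder
#'
#' Builds the family of retained sets for the 20%..100% step-5 ladder by
#' successive refinement: the full id set is retained at 100% (no pair can
#' strictly exceed 100), and each lower level applies [hobohm2_reduce()] to
#' the survivors of the level above. The sets are therefore nested, so the
#' retained-set size is non-decreasing in the threshold by construction, and
#' every level still satisfies the no-pair-above-threshold contract.
#'
#' @param matrix `tm_simmatrix` or symmetric numeric matrix with dimnames.
#' @param thresholds ladder levels (default `seq(20, 100, 5)`).
#' @return named list mapping threshold to retained id vectors.
#' @export
similarity_ladder <- function(matrix, thresholds = seq(20, 100, by = 5)) {
  m <- if (inherits(matrix, "tm_simmatrix")) matrix$values else matrix
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- vector("list", length(thresholds))
  names(out) <- as.character(thresholds)
  kept <- rownames(m)
  for (k in seq_along(thresholds)) {
    th <- thresholds[k]
    if (th < 100 && length(kept) > 1L)
      kept <- hobohm2_reduce(m[kept, kept, drop = FALSE], th)
    out[[k]] <- kept
  }
  out[order(as.numeric(names(out)))]
}

#' Filter protein records by benchmark attributes
#'
#' Applies the conjunction of all configured predicates: chain class,
#' kingdom, family, helix profile, experimental method, resolution cutoff
#' (skipped for NMR entries, which carry no resolution) and minimum
#' submission year. The similarity threshold is not applied here; combine
#' with [hobohm2_reduce()] on ids (see [run_benchmark()]).
#'
#' @param records `tm_records` data frame.
#' @param config `tm_subset_config`.
#' @return the filtered records.
#' @export
filter_records <- function(records, config) {
  keep <- records$chain_class %in% config$classes
  if (!is.null(config$kingdoms))
    keep <- keep & records$kingdom %in% config$kingdoms
  if (!is.null(config$families))
    keep <- keep & (records$chain_class != "helical_membrane" |
                      records$family %in% config$families)
  if (!is.null(config$helix_profile))
    keep <- keep & (records$chain_class != "helical_membrane" |
                      records$helix_profile %in% config$helix_profile)
  keep <- keep & records$exp_method %in% config$methods
  if (!is.null(config$max_resolution) && !is.na(config$max_resolution))
    keep <- keep & (records$exp_method == "nmr" | is.na(records$resolution) |
                      records$resolution <= config$max_resolution)
  if (!is.null(config$min_year))
    keep <- keep & !is.na(records$year) & records$year >= config$min_year
  records[keep, , drop = FALSE]
}

#' Least-similar decile selection for soluble decoys
#'
#' Given, for each candidate soluble sequence, its maximum percent similarity
#' to any sequence of the membrane dataset (0 when no significant match was
#' found upstream), retains the 10% of candidates least similar to the
#' membrane set: sort ascending by score with ascending id as tie-break and
#' keep the first `ceiling(0.10 * n)`.
#'
#' @param scores named numeric vector (id -> max similarity to membrane set).
#' @return character vector of selected ids.
#' @export
least_similar_decile <- function(scores) {
  if (!length(scores)) stop("empty input")
  if (is.null(names(scores))) stop("'scores' must be named by id")
  ord <- order(scores, names(scores))
  k <- ceiling(0.10 * length(scores))
  names(scores)[ord[seq_len(k)]]
}
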
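validate_hyper_table <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("argument error: N, K, n, k must be non-negative integers")
  if (K > N || n > N)
    stop("argument error: K and n must not exceed N")
  if (k > min(K, n))
    stop("argument error: k must not exceed min(K, n)")
  invisible(vals)
}

#' Hypergeometric tail probability for a 2x2 overlap table
#'
#' With X ~ Hypergeometric(N, K, n) — `k` category members among `n` draws
#' without replacement from a universe of `N` containing `K` category
#' members — returns the exact enrichment tail `P(X >= k)` or depletion
#' tail `P(X <= k)`.
#'
#' @param N universe size.
#' @param K category members in the universe.
#' @param n query list size.
#' @param k observed overlap.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower tail).
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  validate_hyper_table(N, K, n, k)
  if (direction == "enriched")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n, lower.tail = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} (p(j) * m / j)` on ascending p-values, mapped back
#' to the input order and capped at 1; the standard FDR-controlling
#' adjustment used throughout the pipeline.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (q-values) in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("argument error: p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("argument error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Haldane-Anscombe corrected log odds ratio
#'
#' `LR = log2[ ((k + 1/2) / (n - k + 1/2)) / ((K - k + 1/2) /
#' (N - n - K + k + 1/2)) ]` — the log2 odds ratio of the 2x2 membership
#' table with 1/2 added to every cell, which keeps it finite for empty
#' cells.
#'
#' @inheritParams hypergeom_tail
#' @return the log2 odds ratio.
#' @export
log_odds_ratio <- function(N, K, n, k) {
  validate_hyper_table(N, K, n, k)
  log2(((k + 0.5) / (n - k + 0.5)) /
         ((K - k + 0.5) / (N - n - K + k + 0.5)))
}

#' Hypergeometric enrichment and depletion of gene-set categories
#'
#' Tests each category for over- or under-representation in a query gene
#' list against a universe (by default the genes expressed in either
#' domain). Sets are intersected with the universe before testing; sets
#' with no universe members are skipped with a message. Both tails are
#' evaluated per set; the reported direction is the smaller tail, the
#' p-value is the two-sided doubled tail (capped at 1), and BH adjustment
#' runs across the collection.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param sets a `gene_set_collection` (see [read_gene_sets()]).
#' @param q_cutoff BH-adjusted significance cutoff used for the
#'   `significant` flag (conventions: 0.01 for GO, 0.05 for TF-family and
#'   hormone categories).
#' @return data.frame: set, N, K, n, k, LR, p, q, direction, significant.
#' @export
enrich_sets <- function(query, universe, sets, q_cutoff = 0.01) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("argument error: empty universe")
  query <- unique(as.character(query))
  if (length(setdiff(query, universe)))
    stop("argument error: query contains genes absent from the universe")
  stopifnot(inherits(sets, "gene_set_collection"))

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    if (K == 0) {
      message("skipping set '", nm, "': no members in universe")
      return(NULL)
    }
    k <- length(intersect(members, query))
    p_enr <- hypergeom_tail(N, K, n, k, "enriched")
    p_dep <- hypergeom_tail(N, K, n, k, "depleted")
    # two-sided by tail doubling: reporting the raw smaller tail would run
    # at twice the nominal level on null data
    data.frame(set = nm, N = N, K = K, n = n, k = k,
               LR = log_odds_ratio(N, K, n, k),
               p = min(1, 2 * min(p_enr, p_dep)),
               direction = if (p_enr <= p_dep) "enriched" else "depleted")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), N = integer(), K = integer(),
                      n = integer(), k = integer(), LR = numeric(),
                      p = numeric(), q = numeric(), direction = character(),
                      significant = logical()))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cutoff
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  out[c("set", "N", "K", "n", "k", "LR", "p", "q", "direction", "significant")]
}

#' Hypergeometric overlap test between two gene lists
#'
#' Tests whether two lists drawn from a common universe overlap more than
#' expected by chance: `k = |A intersect B|`, enrichment tail of
#' Hypergeometric(N = |universe|, K = |A|, n = |B|).
#'
#' @param list_a,list_b character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe background gene ids.
#' @return list with `k` (overlap size) and `p`.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(as.character(universe))
  list_a <- unique(as.character(list_a))
  list_b <- unique(as.character(list_b))
  if (length(setdiff(list_a, universe)) || length(setdiff(list_b, universe)))
    stop("argument error: lists must be subsets of the universe")
  k <- length(intersect(list_a, list_b))
  list(k = k,
       p = hypergeom_tail(length(universe), length(list_a),
                          length(list_b), k, "enriched"))
}

#' Gaussian kernel density curve of enrichment scores
#'
#' Used to examine gene abundance along the log2 fold-change axis, e.g. to
#' compare PDI-associated TFs with all expressed genes. Bandwidth defaults
#' to Silverman's rule of thumb; the default grid spans the data plus five
#' bandwidths on each side, so the trapezoid integral of the curve is ~1.
#'
#' @param values numeric vector (at least 2 values with positive variance).
#' @param grid evaluation points; defaults to 512 points spanning
#'   `range(values) +/- 5 * bandwidth`.
#' @param bandwidth Gaussian kernel s.d.; defaults to [stats::bw.nrd0()].
#' @return data.frame with columns `x` and `density`.
#' @export
kde_curve <- function(values, grid = NULL, bandwidth = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::var(values) == 0)
    stop("zero-variance input: bandwidth undefined under Silverman's rule")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(grid))
    grid <- seq(min(values) - 5 * bandwidth, max(values) + 5 * bandwidth,
                length.out = 512)
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = values, sd = bandwidth))
  }, numeric(1))
  data.frame(x = grid, density = dens)
}
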
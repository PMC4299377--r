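#' Assemble the bipartite TF-fragment regulatory network
#'
#' Nodes are the screened TFs (optionally annotated with their boundary
#' enrichment call) and the usable bait fragments; edges are validated
#' PDIs. The screen dimensions `T` (TFs screened) and `F` (usable
#' fragments) are carried for the null model of [hub_test()] and for the
#' percentages of [degree_summary()].
#'
#' @param pdis data.frame of PDIs with columns `tf` and `fragment`;
#'   duplicate rows are collapsed.
#' @param fragments data.frame of usable fragments (column `fragment`,
#'   optionally `gene`); auto-activating baits should already be excluded
#'   via [filter_autoactivating()].
#' @param tfs character vector of all screened TF ids.
#' @param tf_status optional named character vector (or enrichment-record
#'   data.frame from [differential_call()]) giving each TF's boundary call.
#' @return object of class `grn`: list with `edges`, `tfs`, `fragments`,
#'   `T`, `F`.
#' @export
build_network <- function(pdis, fragments, tfs, tf_status = NULL) {
  edges <- unique(as.data.frame(pdis)[c("tf", "fragment")])
  bad_f <- setdiff(edges$fragment, fragments$fragment)
  if (length(bad_f))
    stop("data error: edge references unknown fragment: ",
         paste(bad_f, collapse = ", "))
  bad_t <- setdiff(edges$tf, tfs)
  if (length(bad_t))
    stop("data error: edge references unscreened TF: ",
         paste(bad_t, collapse = ", "))
  status <- rep("neutral", length(tfs))
  names(status) <- tfs
  if (!is.null(tf_status)) {
    if (is.data.frame(tf_status))
      tf_status <- stats::setNames(tf_status$call, tf_status$gene)
    known <- intersect(names(tf_status), tfs)
    status[known] <- ifelse(tf_status[known] %in% c("enriched", "depleted"),
                            tf_status[known], "neutral")
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 tfs = data.frame(tf = tfs, status = unname(status)),
                 fragments = as.data.frame(fragments),
                 T = length(tfs), F = nrow(fragments)),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$edges), "PDIs between",
      length(unique(x$edges$tf)), "TFs and",
      length(unique(x$edges$fragment)), "fragments",
      sprintf("(screen: %d TFs x %d fragments)\n", x$T, x$F))
  invisible(x)
}

#' Round half up at a fixed number of decimals
#'
#' Presentation rounding for reported percentages (R's `round()` rounds
#' half to even, which is not how the summary percentages are printed).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Network summary statistics
#'
#' Counts and percentages describing the screen outcome: number of edges,
#' TFs and fragments bound, the screen size `F * T`, the percentage of
#' screened TFs bound at least once, the percentage of bound TFs binding
#' exactly one fragment, the percentage of fragments bound, and the share
#' of edges on the two most-bound fragments. Percentages are returned
#' unrounded; round only at presentation (see [round_half_up()]).
#'
#' @param grn a `grn` from [build_network()].
#' @return list of class `network_summary`.
#' @export
degree_summary <- function(grn) {
  stopifnot(inherits(grn, "grn"))
  if (grn$T == 0 || grn$F == 0)
    stop("argument error: screen dimensions must be positive")
  tf_deg <- table(grn$edges$tf)
  frag_deg <- table(grn$edges$fragment)
  n_edges <- nrow(grn$edges)
  top2 <- sum(sort(as.integer(frag_deg), decreasing = TRUE)[1:2], na.rm = TRUE)
  structure(list(
    n_edges = n_edges,
    n_tfs_bound = length(tf_deg),
    n_fragments_bound = length(frag_deg),
    screen_size = grn$F * grn$T,
    pct_tfs_bound = 100 * length(tf_deg) / grn$T,
    pct_tfs_bound_once = if (length(tf_deg))
      100 * sum(tf_deg == 1) / length(tf_deg) else 0,
    pct_fragments_bound = 100 * length(frag_deg) / grn$F,
    pct_edges_on_top2_regions = if (n_edges) 100 * top2 / n_edges else 0),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d PDIs | screen %d pairs | %.1f%% TFs bound (%.1f%% once) | %.1f%% fragments bound | top-2 regions hold %.1f%% of edges\n",
              x$n_edges, x$screen_size,
              round_half_up(x$pct_tfs_bound),
              round_half_up(x$pct_tfs_bound_once),
              round_half_up(x$pct_fragments_bound),
              round_half_up(x$pct_edges_on_top2_regions)))
  invisible(x)
}

#' Detect promoter-region hubs by hypergeometric test
#'
#' Under the gene-centered null, the observed edges fall uniformly over the
#' `F * T` fragment-TF pair population. For a fragment (or merged region)
#' carrying `k` edges, `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = F * T, K = T, n = n_edges)`; BH adjustment runs
#' across fragments and fragments are ranked by adjusted p. Adjacent
#' fragments of one promoter may be merged into regions through
#' `region_map` before testing (a hub can span two overlapping fragments).
#'
#' @param grn a `grn` (auto-activating baits already excluded upstream).
#' @param region_map optional named character vector mapping fragment id ->
#'   region id; unmapped fragments keep their own id.
#' @return data.frame: region, k, p, q, ordered by q then k.
#' @export
hub_test <- function(grn, region_map = NULL) {
  stopifnot(inherits(grn, "grn"))
  frag_ids <- grn$fragments$fragment
  region_of <- stats::setNames(frag_ids, frag_ids)
  n_units <- grn$F
  if (!is.null(region_map)) {
    known <- intersect(names(region_map), frag_ids)
    region_of[known] <- region_map[known]
    n_units <- length(unique(region_of))
  }
  regions <- unique(region_of)
  k <- table(factor(region_of[grn$edges$fragment], levels = regions))
  # a merged region's share of the pair population grows with the number
  # of fragments it covers
  K <- grn$T * as.integer(table(factor(region_of, levels = regions)))
  n_edges <- nrow(grn$edges)
  N <- grn$F * grn$T
  if (any(as.integer(k) > K))
    stop("data error: region degree exceeds its screened TF-pair count")
  p <- mapply(function(ki, Ki) {
    hypergeom_tail(N, Ki, n_edges, ki, "enriched")
  }, as.integer(k), K)
  out <- data.frame(region = names(k), k = as.integer(k), p = p)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, -out$k), ]
  rownames(out) <- NULL
  out
}
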
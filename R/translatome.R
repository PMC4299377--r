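#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM_gs = c_gs * 1e9 / (L_g * M_s)` where `c_gs` is the read count of
#' gene g in sample s, `L_g` the transcript length in bp and `M_s` the
#' sample's mapped-read total (column sum).
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of RPKM values, genes x samples.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  M <- colSums(cm$counts)
  if (any(M == 0))
    stop("sample with zero mapped reads: ",
         paste(colnames(cm$counts)[M == 0], collapse = ", "))
  sweep(cm$counts * 1e9 / cm$lengths, 2, M, "/")
}

#' Call genes expressed per domain
#'
#' A gene counts as expressed in a domain when its mean RPKM across that
#' domain's replicates is strictly above the detection threshold.
#'
#' @param rpkm matrix from [compute_rpkm()].
#' @param design design data.frame (columns `sample`, `domain`).
#' @param threshold detection threshold in RPKM units (default 0.5).
#' @return named list of character vectors of expressed gene ids, one per
#'   domain.
#' @export
call_expressed <- function(rpkm, design, threshold = 0.5) {
  domains <- unique(design$domain)
  out <- lapply(domains, function(d) {
    cols <- design$sample[design$domain == d]
    m <- rowMeans(rpkm[, cols, drop = FALSE])
    rownames(rpkm)[m > threshold]
  })
  stats::setNames(out, domains)
}

#' Boundary enrichment score
#'
#' `log2((RPKM_boundary + eps) / (RPKM_leaf + eps))`. Antisymmetric under
#' swapping the two domains. With `eps = 0` a zero denominator yields an
#' infinite score (permitted, flagged by a warning).
#'
#' @param rpkm_boundary,rpkm_leaf replicate-mean RPKM per gene.
#' @param eps pseudocount in RPKM units (default 0.1); used for scoring
#'   only, never inside significance tests.
#' @return numeric vector of log2 fold changes.
#' @export
enrichment_score <- function(rpkm_boundary, rpkm_leaf, eps = 0.1) {
  if (eps < 0) stop("eps must be >= 0")
  score <- log2((rpkm_boundary + eps) / (rpkm_leaf + eps))
  if (any(is.infinite(score)))
    warning("infinite enrichment score (zero expression with eps = 0)")
  score
}

# Median-of-ratios size factors (relative to the geometric-mean reference
# gene profile); falls back to total-count ratios when no gene has positive
# counts in every sample, so the medians would be undefined.
size_factors <- function(counts) {
  logs <- log(counts)
  ref <- rowMeans(logs)
  use <- is.finite(ref)
  if (any(use)) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
      stats::median(exp(log(cnt[cnt > 0]) - ref[use][cnt > 0]))
    })
    if (!any(is.na(sf)) && all(sf > 0)) return(sf / exp(mean(log(sf))))
  }
  tot <- colSums(counts)
  tot / exp(mean(log(tot)))
}

# Method-of-moments estimate of a common NB dispersion phi (variance =
# mu + phi mu^2) from within-domain means/variances of normalized counts.
# Each gene x domain with mean >= 5 contributes its excess squared
# coefficient of variation, v/m^2 - 1/m, with equal weight: averaging
# per-gene CV^2 terms keeps any single high-count gene from dominating
# the estimate, which matters with only a few replicates. Truncated at
# zero (Poisson).
common_dispersion <- function(norm_counts, design, min_mean = 5) {
  terms <- numeric(0)
  for (d in unique(design$domain)) {
    y <- norm_counts[, design$sample[design$domain == d], drop = FALSE]
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    keep <- m >= min_mean
    terms <- c(terms, v[keep] / m[keep]^2 - 1 / m[keep])
  }
  if (!length(terms)) return(0)
  max(0, mean(terms))
}

nb_loglik <- function(counts, mu, phi) {
  mu <- pmax(mu, 1e-8)
  if (phi <= 0) sum(stats::dpois(counts, mu, log = TRUE))
  else sum(stats::dnbinom(counts, size = 1 / phi, mu = mu, log = TRUE))
}

#' Call boundary-enriched and boundary-depleted genes
#'
#' The differential engine: a per-gene negative-binomial likelihood-ratio
#' test of the domain effect under a single common dispersion estimated by
#' method of moments on normalized counts, library normalization by
#' median-of-ratios (total-count fallback), Benjamini-Hochberg adjustment
#' across tested genes, and a joint fold-change + adjusted-p filter. Genes
#' not expressed in either domain (replicate-mean RPKM at or below
#' `expressed_threshold` in both) are excluded from testing.
#'
#' @param cm a [count_matrix()] with at least 2 replicates per domain.
#' @param fold_cutoff minimum fold change for a call (default 2).
#' @param q_cutoff strict BH-adjusted p cutoff (default 0.001).
#' @param expressed_threshold RPKM detection threshold (default 0.5).
#' @param eps pseudocount for the reported log2 fold change (default 0.1).
#' @return data.frame of enrichment records: gene, rpkm_boundary, rpkm_leaf
#'   (replicate means), log2fc, p, q, expressed_boundary, expressed_leaf,
#'   call (enriched / depleted / unchanged / not_expressed).
#' @export
differential_call <- function(cm, fold_cutoff = 2, q_cutoff = 0.001,
                              expressed_threshold = 0.5, eps = 0.1) {
  stopifnot(inherits(cm, "count_matrix"))
  design <- cm$design
  reps <- table(design$domain)
  if (length(reps) < 2 || any(reps < 2))
    stop("at least 2 replicates per domain are required (dispersion not estimable)")

  rpkm <- compute_rpkm(cm)
  b_cols <- design$sample[design$domain == "boundary"]
  l_cols <- design$sample[design$domain == "leaf"]
  rpkm_b <- rowMeans(rpkm[, b_cols, drop = FALSE])
  rpkm_l <- rowMeans(rpkm[, l_cols, drop = FALSE])
  expr_b <- rpkm_b > expressed_threshold
  expr_l <- rpkm_l > expressed_threshold
  tested <- expr_b | expr_l

  sf <- size_factors(cm$counts)
  norm <- sweep(cm$counts, 2, sf, "/")
  phi <- common_dispersion(norm[tested, , drop = FALSE], design)

  p <- rep(NA_real_, nrow(cm$counts))
  names(p) <- rownames(cm$counts)
  sf_b <- sf[match(b_cols, colnames(cm$counts))]
  sf_l <- sf[match(l_cols, colnames(cm$counts))]
  for (g in which(tested)) {
    cb <- cm$counts[g, b_cols]
    cl <- cm$counts[g, l_cols]
    q_b <- sum(cb) / sum(sf_b)
    q_l <- sum(cl) / sum(sf_l)
    q_0 <- sum(cb, cl) / sum(sf_b, sf_l)
    ll_alt <- nb_loglik(cb, q_b * sf_b, phi) + nb_loglik(cl, q_l * sf_l, phi)
    ll_null <- nb_loglik(c(cb, cl), q_0 * c(sf_b, sf_l), phi)
    lrt <- max(0, 2 * (ll_alt - ll_null))
    p[g] <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])

  log2fc <- enrichment_score(rpkm_b, rpkm_l, eps = eps)
  lfc_cut <- log2(fold_cutoff)
  call <- rep("unchanged", length(p))
  call[!tested] <- "not_expressed"
  sig <- tested & !is.na(q) & q < q_cutoff
  call[sig & log2fc >= lfc_cut] <- "enriched"
  call[sig & log2fc <= -lfc_cut] <- "depleted"

  data.frame(gene = rownames(cm$counts),
             rpkm_boundary = unname(rpkm_b), rpkm_leaf = unname(rpkm_l),
             log2fc = unname(log2fc), p = unname(p), q = unname(q),
             expressed_boundary = unname(expr_b),
             expressed_leaf = unname(expr_l),
             call = call, row.names = NULL)
}
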
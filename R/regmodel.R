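#' Weighted least squares fit of target vs. TF expression
#'
#' Fits `y = a + b x` across genotype series (wild type, loss-of-function
#' mutant, over-expressor) by weighted least squares. The slope's sign
#' suggests activation or repression, its magnitude the regulatory
#' strength, and the two-sided t-test on the slope (df = points - 2) the
#' confidence of the regulation. Default weights are inverse within-
#' genotype replicate variances of the target, with the variance floored
#' at `(0.05 * mean(y))^2` so near-noiseless genotypes cannot dominate the
#' fit; on perfectly collinear data the fit is weight-invariant.
#'
#' @param points data.frame with columns `genotype`, `x`, `y` (see
#'   [read_genotype_table()]); at least 3 points with non-constant `x`.
#' @param weights optional named numeric vector of per-genotype weights
#'   (> 0), overriding the variance-based default.
#' @return list of class `wls_fit`: `b`, `a`, `se_b`, `p`, `df`,
#'   `weights`, `n`.
#' @export
wls_fit <- function(points, weights = NULL) {
  points <- as.data.frame(points)
  stopifnot(all(c("genotype", "x", "y") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points")
  if (length(unique(points$x)) < 2)
    stop("all x identical: slope unidentifiable")
  if (is.null(weights)) {
    floor_var <- (0.05 * mean(points$y))^2
    v <- tapply(points$y, points$genotype, stats::var)
    v[is.na(v)] <- 0
    weights <- 1 / pmax(v, floor_var)
  } else {
    if (any(weights <= 0)) stop("weights must be > 0")
    missing <- setdiff(unique(points$genotype), names(weights))
    if (length(missing))
      stop("no weight for genotype(s): ", paste(missing, collapse = ", "))
  }
  w <- unname(weights[as.character(points$genotype)])
  fit <- stats::lm(y ~ x, data = points, weights = w)
  # noiseless series fit exactly; summary.lm warns about that, harmlessly
  cf <- suppressWarnings(summary(fit)$coefficients)
  structure(list(b = unname(cf["x", "Estimate"]),
                 a = unname(cf["(Intercept)", "Estimate"]),
                 se_b = unname(cf["x", "Std. Error"]),
                 p = unname(cf["x", "Pr(>|t|)"]),
                 df = fit$df.residual,
                 weights = weights,
                 n = nrow(points)),
            class = "wls_fit")
}

#' Turn a WLS fit into an activation/repression call
#'
#' A positive significant slope is `activation`, a negative significant
#' slope `repression`, anything else `no_effect`.
#'
#' @param fit a [wls_fit()].
#' @param alpha significance level on the slope (default 0.05, matching
#'   the single-asterisk convention).
#' @param tf,target optional ids carried into the record.
#' @return one-row data.frame: tf, target, b, a, se_b, p, call.
#' @export
regulatory_call <- function(fit, alpha = 0.05, tf = NA_character_,
                            target = NA_character_) {
  stopifnot(inherits(fit, "wls_fit"))
  call <- if (!is.na(fit$p) && fit$p < alpha) {
    if (fit$b > 0) "activation" else if (fit$b < 0) "repression" else "no_effect"
  } else "no_effect"
  data.frame(tf = tf, target = target, b = fit$b, a = fit$a,
             se_b = fit$se_b, p = fit$p, call = call)
}

#' Fit and call every TF-target pair of a genotype expression table
#'
#' @param genotypes data.frame from [read_genotype_table()] or
#'   [simulate_genotype_expression()].
#' @param alpha significance level for [regulatory_call()].
#' @return data.frame of regulatory calls, one row per pair.
#' @export
model_edges <- function(genotypes, alpha = 0.05) {
  keys <- unique(genotypes[c("tf", "target")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    pts <- genotypes[genotypes$tf == keys$tf[i] &
                       genotypes$target == keys$target[i], ]
    regulatory_call(wls_fit(pts), alpha = alpha,
                    tf = keys$tf[i], target = keys$target[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group genotype contrast with star annotation
#'
#' Welch two-sample t-test between wild-type and mutant/over-expression
#' replicate values, annotated with the printed-figure convention:
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise. When both groups
#' have zero variance the test degenerates: equal means give p = 1,
#' different means p = 0.
#'
#' @param wt_reps,alt_reps numeric replicate vectors (>= 2 each).
#' @return list with `p` and `stars`.
#' @export
genotype_contrast <- function(wt_reps, alt_reps) {
  if (length(wt_reps) < 2 || length(alt_reps) < 2)
    stop("need at least 2 replicates per group")
  if (stats::var(wt_reps) == 0 && stats::var(alt_reps) == 0) {
    p <- if (mean(wt_reps) == mean(alt_reps)) 1 else 0
  } else {
    p <- stats::t.test(wt_reps, alt_reps, var.equal = FALSE)$p.value
  }
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(p = p, stars = stars)
}

# The classification rule table. A regulation reinforces the target's
# boundary expression (regenerative) when an enriched TF activates or a
# depleted TF represses; it opposes it (degenerative) when an enriched TF
# represses or a depleted TF activates. No-effect calls and TFs without a
# boundary status are neutral.
edge_class_rule <- function(status, call) {
  ok_status <- c("enriched", "depleted", "neutral")
  ok_call <- c("activation", "repression", "no_effect")
  if (any(!status %in% ok_status))
    stop("argument error: unknown status token: ",
         paste(setdiff(status, ok_status), collapse = ", "))
  if (any(!call %in% ok_call))
    stop("argument error: unknown call token: ",
         paste(setdiff(call, ok_call), collapse = ", "))
  ifelse(call == "no_effect" | status == "neutral", "neutral",
         ifelse((status == "enriched" & call == "activation") |
                  (status == "depleted" & call == "repression"),
                "regenerative", "degenerative"))
}

#' Classify regulatory edges as regenerative or degenerative
#'
#' Combines each edge's activation/repression call with its TF's boundary
#' status: (enriched, activation) and (depleted, repression) are
#' regenerative; (enriched, repression) and (depleted, activation) are
#' degenerative; any no-effect call or neutral TF status is neutral.
#'
#' @param calls data.frame of regulatory calls (columns `tf`, `call`, see
#'   [model_edges()]).
#' @param tf_status named character vector TF id -> status (`enriched` /
#'   `depleted` / `neutral`), or an enrichment-record data.frame from
#'   [differential_call()]. TFs absent from it are treated as neutral.
#' @return `calls` with added columns `tf_status` and `class`.
#' @export
classify_edges <- function(calls, tf_status) {
  if (is.data.frame(tf_status))
    tf_status <- stats::setNames(tf_status$call, tf_status$gene)
  status <- unname(tf_status[calls$tf])
  status[is.na(status) | !status %in% c("enriched", "depleted")] <- "neutral"
  calls$tf_status <- status
  calls$class <- edge_class_rule(status, calls$call)
  calls
}

#' Summarize regulatory calls and edge classes
#'
#' Counts and percentages per activation/repression/no-effect call and, if
#' classified edges are supplied, per regenerative/degenerative/neutral
#' class. Percentages are unrounded.
#'
#' @param calls data.frame with a `call` column (non-empty).
#' @param classes optional data.frame with a `class` column (e.g. the
#'   output of [classify_edges()]).
#' @return list with data.frames `calls` (call, n, pct) and, when given,
#'   `classes` (class, n, pct).
#' @export
summarize_regulation <- function(calls, classes = NULL) {
  if (!nrow(calls)) stop("calls must be non-empty")
  tab_of <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    data.frame(level = names(t), n = as.integer(t),
               pct = 100 * as.integer(t) / length(x))
  }
  out <- list(calls = tab_of(calls$call,
                             c("activation", "repression", "no_effect")))
  names(out$calls)[1] <- "call"
  if (!is.null(classes)) {
    out$classes <- tab_of(classes$class,
                          c("regenerative", "degenerative", "neutral"))
    names(out$classes)[1] <- "class"
  }
  out
}
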
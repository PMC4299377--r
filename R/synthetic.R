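#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the simulators with defaults matching the study
#' conditions the pipeline was designed for: three biological replicates per
#' cell domain, a small minority of boundary-enriched (1.7%) and
#' boundary-depleted (3.2%) genes, negative-binomial counts, pools of four
#' activation-domain TF plasmids in the yeast one-hybrid screen, and a hub
#' promoter fragment concentrating about half of the true protein-DNA
#' interactions. Library size, gene, TF and fragment numbers are desk-scale
#' stand-ins for the genome-scale experiment (2e5 reads vs ~2e7; 120 TFs and
#' 12 fragments vs 1,184 and 34); all can be raised by configuration.
#'
#' @param n_genes number of genes in the simulated translatome.
#' @param n_replicates biological replicates per domain (default 3).
#' @param library_size expected mapped reads per sample.
#' @param fraction_enriched,fraction_depleted fractions of genes planted as
#'   boundary-enriched / boundary-depleted; must sum to < 1.
#' @param effect_log2fc planted absolute log2 fold change for enriched and
#'   depleted genes.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2).
#' @param n_tfs,n_fragments size of the Y1H screen (prey TFs x bait
#'   fragments).
#' @param pool_size number of AD-TF plasmids mixed per transformation
#'   (default 4).
#' @param n_true_pdis number of planted true TF-fragment interactions.
#' @param hub_share share of true PDIs placed on the hub fragment.
#' @param fp_rate,fn_rate per-observation false-positive / false-negative
#'   rates of the growth assay.
#' @param control_fail_rate probability that a transformation control fails
#'   (the pool is invalid and queued for one repeat).
#' @param n_autoactive number of bait fragments flagged auto-activating
#'   (excluded from screening).
#' @param n_pairs number of TF-target pairs modeled by qPCR genotype series.
#' @param pair_class_probs probabilities of a modeled pair being planted as
#'   activation / repression / no-effect.
#' @param slope_magnitude absolute planted regression slope for
#'   activating/repressing pairs.
#' @param sigma replicate noise s.d. of target expression (relative units).
#' @param oe_factor TF expression in the over-expression genotype, as a
#'   multiple of wild type.
#' @param mutant_expression residual TF expression in the loss-of-function
#'   genotype (relative to WT = 1).
#' @param promoter_length length of simulated upstream regions in bp.
#' @param base_probs background base composition (A, C, G, T).
#' @param n_promoters_query,n_promoters_background sizes of the two promoter
#'   groups.
#' @param motif_rate_query,motif_rate_background Poisson rate of planted
#'   motif occurrences per promoter in each group.
#' @param seed global seed; each generator draws from its own fixed
#'   substream derived from it, so modules can be regenerated in isolation.
#' @return A classed list of settings (`sim_config`).
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates = 3,
                       library_size = 2e5,
                       fraction_enriched = 0.017,
                       fraction_depleted = 0.032,
                       effect_log2fc = 2,
                       dispersion = 0.05,
                       n_tfs = 120,
                       n_fragments = 12,
                       pool_size = 4,
                       n_true_pdis = 40,
                       hub_share = 0.5,
                       fp_rate = 0.01,
                       fn_rate = 0.05,
                       control_fail_rate = 0.02,
                       n_autoactive = 1,
                       n_pairs = 30,
                       pair_class_probs = c(activation = 0.50,
                                            repression = 0.23,
                                            no_effect = 0.27),
                       slope_magnitude = 2,
                       sigma = 0.1,
                       oe_factor = 4,
                       mutant_expression = 0.02,
                       promoter_length = 2000,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       n_promoters_query = 50,
                       n_promoters_background = 200,
                       motif_rate_query = 3,
                       motif_rate_background = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$library_size <= 0) stop("config error: library size must be > 0")
  fr <- c(cfg$fraction_enriched, cfg$fraction_depleted)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1)
    stop("config error: fractions must lie in [0,1] and sum to < 1")
  rates <- c(cfg$fp_rate, cfg$fn_rate, cfg$control_fail_rate)
  if (any(rates < 0) || any(rates > 1))
    stop("config error: rates must lie in [0,1]")
  if (cfg$pool_size < 1) stop("config error: pool size must be >= 1")
  if (cfg$hub_share < 0 || cfg$hub_share > 1)
    stop("config error: hub share must lie in [0,1]")
  if (cfg$sigma < 0) stop("config error: sigma must be >= 0")
  if (cfg$dispersion < 0) stop("config error: dispersion must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Only keys known to [sim_config()] are accepted; everything else is an
#' error, so typos never silently fall back to a default.
#'
#' @param path YAML file of `sim_config` overrides.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("config error: unknown setting(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

# Each generator seeds its own substream so regenerating one module does not
# perturb the others. Offsets are arbitrary fixed small integers.
substream_seed <- function(config, offset) {
  (as.integer(config$seed) + offset) %% .Machine$integer.max
}

#' Simulate a translatome count matrix with planted enrichment
#'
#' Counts are negative binomial (variance mu + phi mu^2) around gene means
#' scaled to the library size, with boundary-domain means multiplied by
#' `2^effect_log2fc` for planted enriched genes and `2^-effect_log2fc` for
#' planted depleted genes. Baseline relative abundances are log-normal.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (list with
#'   `enriched`, `depleted` gene ids and the planted `effect_log2fc`).
#' @export
simulate_translatome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config, 101L))
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))

  rel <- stats::rlnorm(n, meanlog = 0, sdlog = 1.5)
  rel <- rel / sum(rel)
  n_enr <- round(config$fraction_enriched * n)
  n_dep <- round(config$fraction_depleted * n)
  picked <- sample(gene_ids, n_enr + n_dep)
  enriched <- picked[seq_len(n_enr)]
  depleted <- setdiff(picked, enriched)

  fold <- rep(1, n)
  names(fold) <- gene_ids
  fold[enriched] <- 2^config$effect_log2fc
  fold[depleted] <- 2^(-config$effect_log2fc)

  mu_leaf <- config$library_size * rel
  mu_boundary <- mu_leaf * fold
  reps <- config$n_replicates
  samples <- c(sprintf("boundary_%d", seq_len(reps)),
               sprintf("leaf_%d", seq_len(reps)))
  mu <- cbind(matrix(mu_boundary, n, reps), matrix(mu_leaf, n, reps))
  counts <- matrix(rnbinom_phi(length(mu), mu = as.vector(mu),
                               phi = config$dispersion),
                   n, 2 * reps, dimnames = list(gene_ids, samples))
  lengths <- stats::setNames(sample(500:3000, n, replace = TRUE), gene_ids)
  design <- data.frame(
    sample = samples,
    domain = rep(c("boundary", "leaf"), each = reps),
    replicate = rep(seq_len(reps), 2))
  list(counts = count_matrix(counts, lengths, design),
       truth = list(enriched = enriched, depleted = depleted,
                    effect_log2fc = config$effect_log2fc))
}

# NB draw parameterized by dispersion phi; phi = 0 degenerates to Poisson.
rnbinom_phi <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate promoter collections with planted cis-elements
#'
#' Background bases are i.i.d. at the configured composition; motif
#' occurrences are planted at a Poisson rate per promoter that differs
#' between the query and background groups, at uniform random positions
#' (overwriting the background, possibly overlapping each other). IUPAC
#' ambiguity codes are instantiated uniformly over their allowed letters.
#'
#' @param config a [sim_config()].
#' @param motifs data.frame with columns `name` and `iupac` (see
#'   [default_motifs()]).
#' @return list with `promoters` (list of two named character vectors,
#'   `query` and `background`) and `truth` (data.frame of planted
#'   placements: group, promoter, motif, start).
#' @export
simulate_promoters <- function(config = sim_config(), motifs = default_motifs()) {
  stopifnot(inherits(config, "sim_config"))
  if (any(nchar(motifs$iupac) > config$promoter_length))
    stop("config error: motif longer than promoter")
  set.seed(substream_seed(config, 202L))
  gen_group <- function(n, prefix, rate) {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(names(config$base_probs), config$promoter_length,
                   replace = TRUE, prob = config$base_probs), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
    placements <- list()
    for (i in seq_len(n)) {
      n_plant <- stats::rpois(nrow(motifs), rate)
      for (m in seq_len(nrow(motifs))) {
        if (n_plant[m] == 0) next
        w <- nchar(motifs$iupac[m])
        starts <- sample(config$promoter_length - w + 1, n_plant[m],
                         replace = TRUE)
        for (s in starts) {
          inst <- instantiate_iupac(motifs$iupac[m])
          substr(seqs[i], s, s + w - 1) <- inst
          placements[[length(placements) + 1]] <-
            data.frame(promoter = names(seqs)[i], motif = motifs$name[m],
                       start = s)
        }
      }
    }
    list(seqs = seqs, placements = placements)
  }
  q <- gen_group(config$n_promoters_query, "q", config$motif_rate_query)
  b <- gen_group(config$n_promoters_background, "b", config$motif_rate_background)
  placements <- do.call(rbind, c(
    lapply(q$placements, function(d) cbind(group = "query", d)),
    lapply(b$placements, function(d) cbind(group = "background", d))))
  if (is.null(placements))
    placements <- data.frame(group = character(), promoter = character(),
                             motif = character(), start = integer())
  list(promoters = list(query = q$seqs, background = b$seqs),
       truth = list(placements = placements))
}

# Draw one concrete sequence compatible with an IUPAC pattern.
instantiate_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- IUPAC_SETS[[l]]
    if (is.null(opts)) stop("invalid IUPAC letter: ", l)
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Simulate a pooled yeast one-hybrid screen
#'
#' Plants a set of true TF-fragment interactions with the hub fragment
#' receiving its configured share, then emulates the screening protocol:
#' TFs are partitioned into pools of `pool_size` per fragment; a pool grows
#' if any member truly binds and survives the false-negative rate, or
#' spuriously at the false-positive rate; each member of a growing pool is
#' then screened individually, and positive individuals are retested, both
#' with the same error model. Pools whose transformation control fails are
#' invalid and repeated once. Auto-activating fragments are excluded from
#' screening and carry no planted interactions.
#'
#' @param config a [sim_config()].
#' @return list with `table` (Y1H observation data.frame), `fragments`
#'   (annotation data.frame) and `truth` (list with `pdis` data.frame and
#'   `hub_fragment`).
#' @export
simulate_y1h <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config, 303L))
  tfs <- sprintf("TF%04d", seq_len(config$n_tfs))
  frag_ids <- sprintf("F%02d", seq_len(config$n_fragments))
  parent <- sprintf("TARGET%02d", 1 + (seq_len(config$n_fragments) - 1) %/% 4)
  len <- sample(180:320, config$n_fragments, replace = TRUE)
  start <- -sample(200:2000, config$n_fragments, replace = TRUE)
  auto <- rep(FALSE, config$n_fragments)
  if (config$n_autoactive > 0)
    auto[sample.int(config$n_fragments, config$n_autoactive)] <- TRUE
  fragments <- data.frame(fragment = frag_ids, gene = parent,
                          start = start, end = start + len,
                          length = len, auto_activating = auto)

  usable <- frag_ids[!auto]
  hub <- usable[1]
  n_hub <- round(config$hub_share * config$n_true_pdis)
  if (n_hub > config$n_tfs || config$n_true_pdis - n_hub >
      config$n_tfs * (length(usable) - 1))
    stop("config error: more true PDIs than available TF-fragment pairs")
  hub_pdis <- data.frame(tf = sample(tfs, n_hub),
                         fragment = rep(hub, n_hub))
  other_pairs <- expand.grid(tf = tfs, fragment = setdiff(usable, hub),
                             stringsAsFactors = FALSE)
  other_pdis <- other_pairs[sample.int(nrow(other_pairs),
                                       config$n_true_pdis - n_hub), ]
  pdis <- rbind(hub_pdis, other_pdis)
  rownames(pdis) <- NULL

  pool_of <- ceiling(seq_along(tfs) / config$pool_size)
  pools <- split(tfs, pool_of)

  grows <- function(members, fragment) {
    binders <- members[paste(members, fragment) %in%
                         paste(pdis$tf, pdis$fragment)]
    detected <- any(stats::runif(length(binders)) >= config$fn_rate)
    detected || (stats::runif(1) < config$fp_rate)
  }

  rows <- list()
  add_row <- function(fragment, pool, members, stage, growth, control) {
    rows[[length(rows) + 1]] <<- list(fragment = fragment, pool = pool,
                                      members = members, stage = stage,
                                      growth = growth,
                                      control_growth = control)
  }

  for (f in usable) {
    for (p in seq_along(pools)) {
      members <- pools[[p]]
      pool_id <- sprintf("%s_P%03d", f, p)
      # one repeat round for failed transformation controls
      for (attempt in 1:2) {
        control_ok <- stats::runif(1) >= config$control_fail_rate
        g <- if (control_ok) grows(members, f) else (stats::runif(1) < 0.5)
        add_row(f, pool_id, members, "pool",
                if (g) "yes" else "no", if (control_ok) "yes" else "no")
        if (control_ok) break
      }
      if (!control_ok || !g) next
      for (tf in members) {
        ig <- grows(tf, f)
        add_row(f, pool_id, tf, "individual", if (ig) "yes" else "no", "yes")
        if (ig) {
          rg <- grows(tf, f)
          add_row(f, pool_id, tf, "retest", if (rg) "yes" else "no", "yes")
        }
      }
    }
  }
  table <- data.frame(
    fragment = vapply(rows, `[[`, character(1), "fragment"),
    pool = vapply(rows, `[[`, character(1), "pool"),
    stage = vapply(rows, `[[`, character(1), "stage"),
    growth = vapply(rows, `[[`, character(1), "growth"),
    control_growth = vapply(rows, `[[`, character(1), "control_growth"))
  table$members <- lapply(rows, `[[`, "members")
  table <- validate_y1h_table(table, pool_size = config$pool_size)
  list(table = table, fragments = fragments,
       truth = list(pdis = pdis, hub_fragment = hub))
}

#' Plant regulatory truth for a set of TF-target pairs
#'
#' Assigns each modeled pair a planted regulatory mode (activation with
#' slope `+slope_magnitude`, repression with `-slope_magnitude`, or
#' no-effect with slope 0) at the configured class probabilities, a TF
#' boundary status (enriched / depleted / neutral), and the implied
#' regenerative / degenerative / neutral class label.
#'
#' @param config a [sim_config()].
#' @param pdis optional data.frame of PDIs (`tf`, `fragment`) to draw pairs
#'   from (e.g. from [simulate_y1h()] truth); targets default to synthetic
#'   ids when absent.
#' @return data.frame: tf, target, a (intercept), b (slope), tf_status,
#'   planted_call, planted_class.
#' @export
simulate_regulatory_truth <- function(config = sim_config(), pdis = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config, 404L))
  n <- config$n_pairs
  if (!is.null(pdis)) {
    idx <- sample.int(nrow(pdis), min(n, nrow(pdis)))
    tf <- pdis$tf[idx]
    target <- paste0("gene_of_", pdis$fragment[idx])
    n <- length(idx)
  } else {
    tf <- sprintf("TF%04d", seq_len(n))
    target <- sprintf("TARGET%04d", seq_len(n))
  }
  call <- sample(names(config$pair_class_probs), n, replace = TRUE,
                 prob = config$pair_class_probs)
  b <- ifelse(call == "activation", config$slope_magnitude,
              ifelse(call == "repression", -config$slope_magnitude, 0))
  # boundary status is a property of the TF, shared by all its pairs
  tf_unique <- unique(tf)
  status_of <- stats::setNames(
    sample(c("enriched", "depleted", "neutral"), length(tf_unique),
           replace = TRUE, prob = c(0.4, 0.3, 0.3)), tf_unique)
  tf_status <- unname(status_of[tf])
  # intercept keeps target expression non-negative across the x range
  a <- ifelse(b < 0, 1 + abs(b) * config$oe_factor, 1)
  data.frame(tf = tf, target = target, a = a, b = b,
             tf_status = tf_status,
             planted_call = call,
             planted_class = edge_class_rule(tf_status, call))
}

#' Simulate genotype expression series for regulatory modeling
#'
#' For each planted TF-target pair, emits replicate observations in three
#' genotypes: wild type (TF expression around 1), a loss-of-function mutant
#' (TF expression near zero) and an over-expressor (TF expression around
#' `oe_factor`). Target expression is `a + b x` plus Gaussian noise of s.d.
#' `sigma`; values are truncated at zero, matching relative qPCR units.
#'
#' @param truth data.frame from [simulate_regulatory_truth()] (needs
#'   columns tf, target, a, b).
#' @param config a [sim_config()].
#' @return data.frame: tf, target, genotype, replicate, x, y.
#' @export
simulate_genotype_expression <- function(truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$sigma < 0) stop("config error: sigma must be >= 0")
  set.seed(substream_seed(config, 505L))
  gmeans <- c(WT = 1, mutant = config$mutant_expression, OE = config$oe_factor)
  reps <- config$n_replicates
  out <- lapply(seq_len(nrow(truth)), function(i) {
    g <- rep(names(gmeans), each = reps)
    x <- pmax(0, rep(gmeans, each = reps) *
                (1 + stats::rnorm(length(g), 0, 0.05)))
    y <- pmax(0, truth$a[i] + truth$b[i] * x +
                stats::rnorm(length(g), 0, config$sigma))
    data.frame(tf = truth$tf[i], target = truth$target[i],
               genotype = g, replicate = rep(seq_len(reps), 3),
               x = x, y = y)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write one full synthetic study to a directory
#'
#' Emits `counts.tsv`, `design.tsv`, `promoters_query.fasta`,
#' `promoters_background.fasta`, `y1h.tsv`, `fragments.tsv`,
#' `genotypes.tsv` and `truth.json`. All files pass the package's readers
#' unchanged; the truth file is emitted alongside the data but is never an
#' input to any pipeline stage.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
simulate_study <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tl <- simulate_translatome(config)
  write_count_table(tl$counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "design.tsv"))
  pr <- simulate_promoters(config)
  write_promoters(pr$promoters$query, file.path(dir, "promoters_query.fasta"))
  write_promoters(pr$promoters$background,
                  file.path(dir, "promoters_background.fasta"))
  y <- simulate_y1h(config)
  write_y1h_table(y$table, file.path(dir, "y1h.tsv"))
  utils::write.table(y$fragments, file.path(dir, "fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- simulate_regulatory_truth(config, pdis = y$truth$pdis)
  gx <- simulate_genotype_expression(rt, config)
  utils::write.table(gx, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(translatome = tl$truth,
                promoters = pr$truth,
                y1h = y$truth,
                regulation = rt)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
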
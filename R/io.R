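#' Construct a count matrix with its experimental design
#'
#' The container for gene-level read counts from a two-domain translatome
#' experiment (organ boundary vs. developing leaf), together with per-gene
#' transcript lengths and the sample design. All downstream quantification
#' (RPKM, enrichment scoring, differential calling) starts from this object.
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames. All entries must be non-negative integers.
#' @param lengths numeric vector of transcript lengths in bp, one per gene,
#'   named by gene id (or in row order). All lengths must be positive.
#' @param design data.frame with columns `sample`, `domain` (one of
#'   `"boundary"`, `"leaf"`) and `replicate`; one row per sample.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `lengths` and `design`.
#' @export
count_matrix <- function(counts, lengths, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique gene ids as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample ids as colnames")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(names(lengths))) names(lengths) <- rownames(counts)
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every gene needs a positive transcript length")
  design <- validate_design(design, colnames(counts))
  structure(list(counts = counts, lengths = lengths, design = design),
            class = "count_matrix")
}

validate_design <- function(design, samples) {
  design <- as.data.frame(design)
  need <- c("sample", "domain", "replicate")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  design$sample <- as.character(design$sample)
  design$domain <- as.character(design$domain)
  if (anyDuplicated(design$sample))
    stop("design error: duplicated sample id in design")
  bad <- setdiff(design$sample, samples)
  if (length(bad))
    stop("design error: unknown sample in design: ", paste(bad, collapse = ", "))
  missing <- setdiff(samples, design$sample)
  if (length(missing))
    stop("design error: sample absent from design: ",
         paste(missing, collapse = ", "))
  if (!all(design$domain %in% c("boundary", "leaf")))
    stop("design error: domain must be 'boundary' or 'leaf'")
  rownames(design) <- NULL
  design[match(samples, design$sample), , drop = FALSE]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("domains:", paste(sprintf("%s (%d)", names(table(x$design$domain)),
                                table(x$design$domain)), collapse = ", "), "\n")
  invisible(x)
}

read_tsv_commented <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}

#' Read a gene-level count table and its design
#'
#' The canonical dialect is tab-separated with `#` comment lines: the count
#' file has columns `gene_id`, `length`, then one column per sample; the
#' design file has columns `sample`, `domain`, `replicate`.
#'
#' @param path path to the count TSV.
#' @param design_path path to the companion design TSV.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, design_path) {
  tab <- read_tsv_commented(path)
  if (!all(c("gene_id", "length") %in% names(tab)))
    stop("format error: count table needs 'gene_id' and 'length' columns")
  sample_cols <- setdiff(names(tab), c("gene_id", "length"))
  if (!length(sample_cols)) stop("format error: no sample columns found")
  cm <- as.matrix(tab[sample_cols])
  bad <- which(is.na(cm) | cm < 0 | cm != round(cm), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("format error: non-integer or negative count at gene '%s', sample '%s'",
                 tab$gene_id[bad[1, 1]], sample_cols[bad[1, 2]]))
  rownames(cm) <- tab$gene_id
  design <- read_tsv_commented(design_path)
  count_matrix(cm, stats::setNames(tab$length, tab$gene_id), design)
}

#' Write a count matrix and its design to TSV
#'
#' Inverse of [read_count_table()]: `read_count_table()` on the emitted pair
#' of files reproduces the object exactly.
#'
#' @param cm a [count_matrix()].
#' @param path output path for the count TSV.
#' @param design_path output path for the design TSV.
#' @export
write_count_table <- function(cm, path, design_path) {
  tab <- data.frame(gene_id = rownames(cm$counts),
                    length = unname(cm$lengths),
                    cm$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Duplicate members within a set are collapsed.
#'
#' @param path path to a GMT file.
#' @param category label for the collection, e.g. `"GO"`, `"TF_family"`,
#'   `"hormone"` or `"custom"`.
#' @return A `gene_set_collection`: list with `category` and named list `sets`.
#' @export
read_gene_sets <- function(path, category = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("format error: GMT line %d has fewer than 3 fields", i))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("format error: GMT line %d ('%s') has no members", i, fields[1]))
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets, category)
}

#' @rdname read_gene_sets
#' @param sets named list of character vectors of member gene ids.
#' @export
gene_set_collection <- function(sets, category = "custom") {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(category = category, sets = sets),
            class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Upstream regions (up to 2 kb, 5'->3' toward the translation start), one
#' record per gene. The alphabet is restricted to A/C/G/T/N.
#'
#' @param path FASTA path.
#' @param max_length maximum allowed promoter length; longer records trigger
#'   a warning (they are kept).
#' @return Named character vector of upper-case sequences (a promoter
#'   collection), names = gene ids.
#' @export
read_promoters <- function(path, max_length = 2000) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out)))
    stop("format error: duplicated promoter id in FASTA")
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("format error: non-ACGTN character in promoter '",
         names(out)[which(bad)[1]], "'")
  long <- nchar(out) > max_length
  if (any(long))
    warning(sum(long), " promoter(s) longer than ", max_length, " bp")
  out
}

#' Write promoter sequences to FASTA
#' @param promoters named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}

#' Read a pooled yeast one-hybrid observation table
#'
#' Tab-separated with columns `fragment`, `pool`, `members` (comma-separated
#' TF ids), `stage` (`pool`/`individual`/`retest`), `growth` and
#' `control_growth` (`yes`/`no`).
#'
#' @param path TSV path.
#' @return data.frame with `members` as a list-column of character vectors.
#' @export
read_y1h_table <- function(path) {
  tab <- read_tsv_commented(path)
  need <- c("fragment", "pool", "members", "stage", "growth", "control_growth")
  if (!all(need %in% names(tab)))
    stop("format error: Y1H table needs columns: ", paste(need, collapse = ", "))
  tab$members <- strsplit(as.character(tab$members), ",", fixed = TRUE)
  validate_y1h_table(tab)
}

validate_y1h_table <- function(tab, pool_size = NULL) {
  if (!all(tab$stage %in% c("pool", "individual", "retest")))
    stop("format error: stage must be pool/individual/retest")
  if (!all(tab$growth %in% c("yes", "no")) ||
      !all(tab$control_growth %in% c("yes", "no")))
    stop("format error: growth fields must be 'yes' or 'no'")
  n_members <- lengths(tab$members)
  solo <- tab$stage %in% c("individual", "retest")
  if (any(n_members[solo] != 1))
    stop("format error: individual/retest rows must have exactly one member")
  if (!is.null(pool_size) && any(n_members[tab$stage == "pool"] > pool_size))
    stop("format error: pool row exceeds pool size")
  rownames(tab) <- NULL
  tab
}

#' Write a Y1H observation table to TSV
#' @param tab data.frame as returned by [read_y1h_table()] or
#'   [simulate_y1h()].
#' @param path output path.
#' @export
write_y1h_table <- function(tab, path) {
  out <- tab
  out$members <- vapply(tab$members, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a promoter-fragment annotation table
#'
#' Columns: `fragment`, `gene`, `start`, `end` (offsets relative to the
#' translation start, negative = upstream), `auto_activating` (TRUE/FALSE).
#' Fragment lengths outside the 180-320 bp design window trigger a warning.
#'
#' @param path TSV path.
#' @return data.frame with an added `length` column.
#' @export
read_fragments <- function(path) {
  tab <- read_tsv_commented(path)
  need <- c("fragment", "gene", "start", "end", "auto_activating")
  if (!all(need %in% names(tab)))
    stop("format error: fragment table needs columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab$fragment))
    stop("format error: duplicated fragment id")
  tab$auto_activating <- as.logical(tab$auto_activating)
  tab$length <- tab$end - tab$start
  if (any(tab$length < 180 | tab$length > 320))
    warning("fragment length outside the expected 180-320 bp window")
  tab
}

#' Read a genotype expression table for regulatory modeling
#'
#' Columns: `tf`, `target`, `genotype` (`WT`/`mutant`/`OE`), `replicate`,
#' `x` (TF relative expression), `y` (target relative expression).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genotype_table <- function(path) {
  tab <- read_tsv_commented(path)
  need <- c("tf", "target", "genotype", "replicate", "x", "y")
  if (!all(need %in% names(tab)))
    stop("format error: genotype table needs columns: ",
         paste(need, collapse = ", "))
  if (any(tab$x < 0) || any(tab$y < 0))
    stop("format error: relative expression must be non-negative")
  tab
}

#' Export a protein-DNA interaction network
#'
#' @param edges data.frame with columns `tf` and `fragment` (one row per
#'   PDI); extra columns are carried into the TSV output.
#' @param path output path.
#' @param format `"tsv"` (round-trips exactly via [read_network_tsv()]),
#'   `"sif"` (relation token `binds`) or `"graphml"`.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- as.data.frame(edges)
  if (!all(c("tf", "fragment") %in% names(edges)))
    stop("edges need 'tf' and 'fragment' columns")
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s binds %s", edges$tf, edges$fragment), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[c("tf", "fragment")], directed = TRUE)
    igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% edges$tf,
                                "TF", "fragment")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_tsv <- function(path) {
  tab <- read_tsv_commented(path)
  if (!all(c("tf", "fragment") %in% names(tab)))
    stop("format error: network TSV needs 'tf' and 'fragment' columns")
  tab
}
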
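# IUPAC nucleotide ambiguity codes. N expands to ACGT in a *pattern*;
# an N in the scanned *sequence* never matches (it is not a concrete base).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

validate_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("motif pattern must be non-empty")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC letter(s): ", paste(unique(bad), collapse = ", "))
  pattern
}

#' Reverse complement of an IUPAC pattern
#' @param pattern IUPAC string.
#' @return the reverse-complemented pattern.
#' @export
iupac_reverse_complement <- function(pattern) {
  pattern <- validate_iupac(pattern)
  paste(rev(IUPAC_COMPLEMENT[strsplit(pattern, "")[[1]]]), collapse = "")
}

iupac_to_regex <- function(pattern) {
  pattern <- validate_iupac(pattern)
  paste(vapply(strsplit(pattern, "")[[1]], function(l) {
    opts <- IUPAC_SETS[[l]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Overlap-tolerant start positions of an IUPAC pattern in a sequence
# (forward strand only). N in the sequence never matches because the
# character classes contain concrete bases only.
iupac_match_starts <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, toupper(sequence), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Count occurrences of an IUPAC motif on both strands
#'
#' Counts start positions where either the pattern or its reverse
#' complement matches the forward-strand sequence. A position where both
#' match (a palindromic site) is counted once. Overlapping occurrences all
#' count; `N` in the sequence never matches.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param pattern IUPAC motif string (or a one-row entry of a motif table).
#' @return integer occurrence count.
#' @export
scan_motif <- function(sequence, pattern) {
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence must be over ACGTN")
  if (nchar(pattern) > nchar(sequence)) return(0L)
  fwd <- iupac_match_starts(sequence, pattern)
  rev <- iupac_match_starts(sequence, iupac_reverse_complement(pattern))
  length(union(fwd, rev))
}

#' The shipped cis-element dictionary
#'
#' A small editable table of well-known plant promoter elements (G-box,
#' ABA-responsive element, GATA box). Users extend it by passing their own
#' data.frame with columns `name` and `iupac` to [motif_enrichment()].
#'
#' @return data.frame with columns `name` and `iupac`.
#' @export
default_motifs <- function() {
  data.frame(name = c("G-box", "ABRE", "GATA-box"),
             iupac = c("CACGTG", "ACGTGKC", "WGATAR"))
}

#' Read a motif table (columns: name, IUPAC pattern)
#' @param path TSV path with columns `name` and `iupac`.
#' @return validated data.frame.
#' @export
read_motifs <- function(path) {
  tab <- read_tsv_commented(path)
  if (!all(c("name", "iupac") %in% names(tab)))
    stop("format error: motif table needs columns 'name' and 'iupac'")
  tab$iupac <- vapply(tab$iupac, validate_iupac, character(1))
  tab
}

#' Enumerative cis-element enrichment over promoter collections
#'
#' For each motif, the background occurrence rate per scannable position is
#' estimated from the background promoter collection (scannable positions
#' per promoter = length - motif length + 1, strands collapsed by the
#' palindrome rule of [scan_motif()]); the query's total occurrence count
#' is then tested against an upper-tail binomial at that rate, and the
#' p-value is Bonferroni-scaled into an expect value
#' `E = p * number of motifs tested`. Motifs never seen in the background
#' get their rate floored at `1 / (2 * background positions)` (logged).
#'
#' @param query,background named character vectors of promoter sequences
#'   (see [read_promoters()]); the background should cover a representative
#'   promoter universe.
#' @param motifs data.frame with columns `name`, `iupac`
#'   (default [default_motifs()]).
#' @param e_cutoff expect-value cutoff for the `flagged` column
#'   (default 1e-4).
#' @return data.frame: motif, observed, positions, rate, expected, p, E,
#'   flagged.
#' @export
motif_enrichment <- function(query, background, motifs = default_motifs(),
                             e_cutoff = 1e-4) {
  if (!length(query) || !length(background))
    stop("argument error: both promoter collections must be non-empty")
  n_motifs <- nrow(motifs)
  rows <- lapply(seq_len(n_motifs), function(i) {
    w <- nchar(motifs$iupac[i])
    pos_q <- sum(pmax(0L, nchar(query) - w + 1L))
    pos_b <- sum(pmax(0L, nchar(background) - w + 1L))
    obs_q <- sum(vapply(query, scan_motif, integer(1),
                        pattern = motifs$iupac[i]))
    obs_b <- sum(vapply(background, scan_motif, integer(1),
                        pattern = motifs$iupac[i]))
    if (obs_b == 0) {
      message("motif '", motifs$name[i],
              "' unseen in background; rate floored")
      rate <- 1 / (2 * pos_b)
    } else rate <- obs_b / pos_b
    p <- stats::pbinom(obs_q - 1, pos_q, rate, lower.tail = FALSE)
    data.frame(motif = motifs$name[i], observed = obs_q, positions = pos_q,
               rate = rate, expected = rate * pos_q, p = p,
               E = p * n_motifs)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$E < e_cutoff
  out[order(out$E), ]
}
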
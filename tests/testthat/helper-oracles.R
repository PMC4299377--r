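# Independent oracles used across the suite. These deliberately use
# brute-force enumeration / naive loops, not the code paths they check.

# Exact hypergeometric tail by enumerating all C(N, n) draws from a
# universe 1..N whose category members are 1..K.
enum_hyper_tail <- function(N, K, n, k, direction) {
  if (n == 0) {
    overlaps <- 0L
  } else {
    draws <- utils::combn(N, n)
    overlaps <- colSums(draws <= K)
  }
  if (direction == "enriched") mean(overlaps >= k) else mean(overlaps <= k)
}

# Position-by-position IUPAC scanner: both strands, palindromes deduped,
# N in the sequence never matches.
naive_scan <- function(sequence, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  seq_l <- strsplit(toupper(sequence), "")[[1]]
  pat_l <- strsplit(toupper(pattern), "")[[1]]
  rc_l <- rev(unname(comp[pat_l]))
  w <- length(pat_l)
  if (w > length(seq_l)) return(0L)
  hits <- 0L
  for (s in seq_len(length(seq_l) - w + 1)) {
    window <- seq_l[s:(s + w - 1)]
    fwd <- all(mapply(function(b, p) b %in% sets[[p]], window, pat_l))
    rev_ <- all(mapply(function(b, p) b %in% sets[[p]], window, rc_l))
    if (fwd || rev_) hits <- hits + 1L
  }
  hits
}

# Weighted least squares by direct normal-equation solve.
solve_wls <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  resid <- y - X %*% beta
  s2 <- sum(w * resid^2) / (length(y) - 2)
  cov_b <- s2 * solve(t(X) %*% (w * X))
  list(a = beta[1], b = beta[2], se_b = sqrt(cov_b[2, 2]))
}

# Hand-written classification rule oracle (independent of the package's
# vectorized rule).
class_oracle <- function(status, call) {
  if (call == "no_effect" || status == "neutral") return("neutral")
  if (status == "enriched" && call == "activation") return("regenerative")
  if (status == "depleted" && call == "repression") return("regenerative")
  "degenerative"
}

# Small count matrix for translatome tests.
make_cm <- function(counts, lengths = NULL, reps = ncol(counts) / 2) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- c(sprintf("b%d", seq_len(reps)),
                        sprintf("l%d", seq_len(reps)))
  if (is.null(lengths))
    lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  design <- data.frame(sample = colnames(counts),
                       domain = rep(c("boundary", "leaf"), each = reps),
                       replicate = rep(seq_len(reps), 2))
  count_matrix(counts, lengths, design)
}
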
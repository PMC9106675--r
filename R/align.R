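# BLOSUM62 (Henikoff & Henikoff 1992, PNAS 89:10915), half-bit units.
# X is scored 0 against everything, as the alignment contract requires.
.blosum62_order <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
.BLOSUM62 <- matrix(c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,  0,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,  0,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,  0,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,  0,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,  0,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,  0,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,  0,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,  0,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,  0,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,  0,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,  0,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,  0,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,  0,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,  0,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,  0,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,  0,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,  0,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4,  0,
   0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0,  0
), nrow = 21, byrow = TRUE, dimnames = list(.blosum62_order, .blosum62_order))

#' Substitution matrices shipped with the package
#'
#' @param name matrix name; currently only `"BLOSUM62"`.
#' @return integer substitution matrix over the 20 amino acids plus `X`
#'   (scored 0 against everything).
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (!identical(toupper(name), "BLOSUM62")) {
    .err("ppidrugg_invalid", paste("unknown substitution matrix:", name))
  }
  .BLOSUM62
}

#' Global sequence alignment with affine gap penalties
#'
#' Needleman-Wunsch / Gotoh global alignment. A gap of length `k` costs
#' `gap_open + k * gap_extend`. Tie-breaking is deterministic: at every
#' traceback step a match/mismatch is preferred over a gap, and a gap in
#' `seq_a` over a gap in `seq_b`, so identical inputs always yield the
#' identical alignment.
#'
#' @param seq_a,seq_b amino-acid strings over the 20-letter alphabet
#'   (`X` allowed, scored 0).
#' @param substitution substitution matrix name (see
#'   [substitution_matrix()]) or a numeric matrix.
#' @param gap_open,gap_extend non-negative gap penalties (default 10 / 1).
#' @return object of class `alignment_map`: list with `pairs` (two-column
#'   integer matrix of aligned positions, strictly increasing in both
#'   columns), `score`, and the two gapped alignment strings.
#' @examples
#' global_align("ACDE", "ACE")
#' @export
global_align <- function(seq_a, seq_b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) .err("ppidrugg_invalid", "empty sequence")
  S <- if (is.matrix(substitution)) substitution else substitution_matrix(substitution)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  bad <- setdiff(c(a, b), rownames(S))
  if (length(bad)) .err("ppidrugg_invalid", paste("letters not in matrix:", paste(bad, collapse = "")))
  n <- length(a); m <- length(b)
  if (identical(a, b)) {
    # gap-free self-alignment is optimal (diagonal scores are the matrix
    # maxima and gaps only subtract); skip the quadratic DP
    pairs <- cbind(a = seq_len(n), b = seq_len(n))
    return(structure(list(
      pairs = pairs, score = sum(S[cbind(a, a)]),
      aligned_a = seq_a, aligned_b = seq_b, identity = 1
    ), class = "alignment_map"))
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # a[i] aligned to b[j]
  Ix <- matrix(NEG, n + 1, m + 1) # gap in A (consumes b[j])
  Iy <- matrix(NEG, n + 1, m + 1) # gap in B (consumes a[i])
  M[1, 1] <- 0
  if (m > 0) Ix[1, 2:(m + 1)] <- -(gap_open + gap_extend * seq_len(m))
  if (n > 0) Iy[2:(n + 1), 1] <- -(gap_open + gap_extend * seq_len(n))
  for (i in seq_len(n)) {
    si <- S[a[i], b]
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- si[j] + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(
        M[i + 1, j] - gap_open - gap_extend,
        Ix[i + 1, j] - gap_extend,
        Iy[i + 1, j] - gap_open - gap_extend
      )
      Iy[i + 1, j + 1] <- max(
        M[i, j + 1] - gap_open - gap_extend,
        Iy[i, j + 1] - gap_extend,
        Ix[i, j + 1] - gap_open - gap_extend
      )
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback; preference order M > Ix > Iy is the documented tie-break
  state <- c("M", "Ix", "Iy")[which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))]
  i <- n; j <- m
  pa <- character(0); pb <- character(0)
  pairs <- matrix(integer(0), ncol = 2)
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      pairs <- rbind(c(i, j), pairs)
      pa <- c(a[i], pa); pb <- c(b[j], pb)
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- c("M", "Ix", "Iy")[which(prev >= max(prev) - tol)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      pa <- c("-", pa); pb <- c(b[j], pb)
      cand <- c(
        M[i + 1, j] - gap_open - gap_extend,
        Ix[i + 1, j] - gap_extend,
        Iy[i + 1, j] - gap_open - gap_extend
      )
      state <- c("M", "Ix", "Iy")[which(cand >= max(cand) - tol)[1]]
      j <- j - 1
    } else {
      pa <- c(a[i], pa); pb <- c("-", pb)
      cand <- c(
        M[i, j + 1] - gap_open - gap_extend,
        Iy[i, j + 1] - gap_extend,
        Ix[i, j + 1] - gap_open - gap_extend
      )
      state <- c("M", "Iy", "Ix")[which(cand >= max(cand) - tol)[1]]
      i <- i - 1
    }
  }
  colnames(pairs) <- c("a", "b")
  structure(list(
    pairs = pairs, score = score,
    aligned_a = paste(pa, collapse = ""), aligned_b = paste(pb, collapse = ""),
    identity = if (nrow(pairs)) mean(a[pairs[, 1]] == b[pairs[, 2]]) else 0
  ), class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf(
    "<alignment_map> score %.0f, %d aligned pairs, %.1f%% identity\n%s\n%s\n",
    x$score, nrow(x$pairs), 100 * x$identity, x$aligned_a, x$aligned_b
  ))
  invisible(x)
}
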
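# Gamete-type machinery for one four-marker window A-B-C-D.
#
# A gamete type is the crossover-indicator triple (i_AB, i_BC, i_CD): i = 1
# when the gamete is recombinant across that interval. Each type contains the
# two complementary gametes (e.g. ABCD and abcd both have indicator 000),
# which are equifrequent by meiotic symmetry, so the 16 concrete gametes
# carry probability g_t / 2 each.

# 8 x 3 matrix of crossover indicators; row t+1 encodes t in binary
# (i_AB, i_BC, i_CD), so row order is 000, 001, 010, ..., 111.
.type_bits <- local({
  t <- 0:7
  m <- cbind(AB = t %/% 4L %% 2L, BC = t %/% 2L %% 2L, CD = t %% 2L)
  storage.mode(m) <- "integer"
  m
})

.gamete_type_names <-
  paste0("g", .type_bits[, 1], .type_bits[, 2], .type_bits[, 3])

# 16 x 4 allele matrix; allele 1 = the parental "ABCD" phase, 0 = "abcd".
# Rows 2t-1 and 2t are the complementary pair of type t.
.gamete_alleles <- local({
  m <- matrix(0L, 16L, 4L)
  for (t in 1:8) {
    for (s in 1:2) {
      h <- integer(4)
      h[1] <- if (s == 1L) 1L else 0L
      for (k in 1:3) h[k + 1] <- (h[k] + .type_bits[t, k]) %% 2L
      m[2L * (t - 1L) + s, ] <- h
    }
  }
  m
})

.gamete_type_of <- rep(1:8, each = 2L)

# All 256 ordered (maternal gamete, paternal gamete) combinations with the
# genotype class each produces. Class index is 27a + 9b + 3c + d + 1 over
# the per-locus codes a,b,c,d in {0,1,2} (code = number of parental-phase
# alleles), i.e. class 1 = "0000", class 81 = "2222".
.pair_table <- local({
  mg <- rep(1:16, times = 16L)
  pg <- rep(1:16, each = 16L)
  codes <- .gamete_alleles[mg, , drop = FALSE] + .gamete_alleles[pg, , drop = FALSE]
  list(
    mg = mg, pg = pg,
    m_type = .gamete_type_of[mg],
    p_type = .gamete_type_of[pg],
    class = as.integer(codes %*% c(27, 9, 3, 1)) + 1L
  )
})

.class_names <- local({
  i <- 0:80
  paste0(i %/% 27 %% 3, i %/% 9 %% 3, i %/% 3 %% 3, i %% 3)
})

# 256 x 8: number of gametes of each type contributed by each ordered pair
# (0, 1 or 2). Used by the EM M-step.
.type_count_matrix <- local({
  A <- matrix(0, 256L, 8L)
  A[cbind(seq_len(256L), .pair_table$m_type)] <-
    A[cbind(seq_len(256L), .pair_table$m_type)] + 1
  A[cbind(seq_len(256L), .pair_table$p_type)] <-
    A[cbind(seq_len(256L), .pair_table$p_type)] + 1
  A
})

#' Construct and validate a gamete-type frequency vector
#'
#' The eight gamete-type frequencies g000, ..., g111 at four ordered markers
#' A-B-C-D. The subscript is the crossover-indicator triple over the three
#' intervals (A-B, B-C, C-D); each type is the total frequency of a
#' complementary gamete pair (e.g. ABCD/abcd for g000).
#'
#' @param g Numeric vector of length 8, in subscript order
#'   `g000, g001, g010, g011, g100, g101, g110, g111` (i.e. the subscript
#'   read as a binary number). Names, if present, must match that order.
#' @param tol Tolerance for the sum-to-one check and for negative rounding
#'   error (entries in `[-tol, 0)` are clamped to 0).
#' @return A named numeric vector of length 8 summing to 1.
#' @examples
#' gamete_frequencies(c(1, 0, 0, 0, 0, 0, 0, 0))       # no crossovers
#' independence_gametes(0.1, 0.2, 0.1)
#' @export
gamete_frequencies <- function(g, tol = 1e-9) {
  if (!is.numeric(g) || length(g) != 8L) {
    stop("gamete frequencies must be a numeric vector of length 8")
  }
  if (!is.null(names(g)) && !identical(names(g), .gamete_type_names)) {
    g <- g[.gamete_type_names]
    if (anyNA(g)) stop("gamete frequency names must be g000 ... g111")
  }
  g <- as.numeric(g)
  if (anyNA(g) || any(!is.finite(g))) stop("gamete frequencies must be finite")
  if (any(g < -tol)) {
    bad <- .gamete_type_names[which(g < -tol)]
    stop("negative gamete frequency: ", paste(bad, collapse = ", "))
  }
  g[g < 0] <- 0
  if (abs(sum(g) - 1) > tol) {
    stop(sprintf("gamete frequencies must sum to 1 (got %.12g)", sum(g)))
  }
  stats::setNames(g, .gamete_type_names)
}

#' Names of the 81 identifiable four-marker genotype classes
#'
#' Classes are indexed 1..81 by the per-locus genotype codes `(a, b, c, d)`
#' in `{0, 1, 2}` (2 = homozygous parental-phase, 1 = heterozygous,
#' 0 = homozygous alternate), ordered as the base-3 number `abcd`: class 1 is
#' `"0000"`, class 81 is `"2222"`.
#'
#' @return Character vector of length 81, e.g. `"2221"` for the class usually
#'   written \eqn{n_{2221}}.
#' @export
genotype_class_names <- function() .class_names

#' Map four-marker genotype codes to their class index
#'
#' Bijection between code quadruples `(a, b, c, d)` in `{2, 1, 0}^4` and the
#' class indices `1..81` of [genotype_class_names()]. Individuals with a
#' missing call get `NA`, signalling the caller to exclude them from the
#' window.
#'
#' @param calls Integer vector of length 4, or an n x 4 matrix of calls
#'   (one row per individual), with entries in `{0, 1, 2}` or `NA`.
#' @return Integer class index (or vector of indices for a matrix input);
#'   `NA` where any call is missing.
#' @examples
#' classify_offspring(c(2, 2, 2, 2))  # 81, class "2222"
#' classify_offspring(c(0, 0, 0, 0))  # 1,  class "0000"
#' @export
classify_offspring <- function(calls) {
  if (is.matrix(calls)) {
    if (ncol(calls) != 4L) stop("calls must have 4 columns")
    m <- calls
  } else {
    if (length(calls) != 4L) stop("calls must have length 4")
    m <- matrix(calls, 1L, 4L)
  }
  ok <- !is.na(m)
  if (any(!(m[ok] %in% 0:2))) stop("genotype calls must be 0, 1, 2 or NA")
  idx <- as.integer(m %*% c(27, 9, 3, 1)) + 1L
  idx[rowSums(!ok) > 0L] <- NA_integer_
  if (is.matrix(calls)) idx else idx[[1L]]
}
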
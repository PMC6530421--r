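# The 81-class four-marker genotype distribution of a full-sib family,
# built by exhaustive enumeration of the 16 x 16 ordered gamete pairings.

#' Expected frequencies of the 81 identifiable four-marker genotype classes
#'
#' Expands each parent's eight gamete types into the 16 concrete gametes
#' (each complementary gamete at \eqn{g_t/2}), forms all 256 ordered
#' maternal x paternal pairings, maps each pairing to its genotype class in
#' `{2,1,0}^4` coding, and accumulates probability. Heterozygous classes are
#' mixtures of several gamete-type products; the mixture structure (which
#' ordered gamete pair contributes which mass to which class) is returned in
#' `components` and drives the EM E-step.
#'
#' @param g_maternal,g_paternal Gamete-type frequencies for the two F1
#'   parents (see [gamete_frequencies()]); by default shared, as the
#'   symmetric products of a full-sib design imply.
#' @return An object of class `genotype_class_table`: a list with
#'   * `freq` — named numeric vector of 81 class probabilities (sums to 1),
#'     named as [genotype_class_names()];
#'   * `components` — data frame with one row per ordered gamete pairing
#'     (256 rows): `class`, `class_name`, `m_gamete`, `p_gamete` (1..16),
#'     `m_type`, `p_type` (gamete-type names), `prob`.
#' @examples
#' g <- gamete_frequencies(c(1, 0, 0, 0, 0, 0, 0, 0))
#' tab <- genotype_class_table(g)
#' tab$freq[c("2222", "1111", "0000")]  # 1/4, 1/2, 1/4
#' @export
genotype_class_table <- function(g_maternal, g_paternal = g_maternal) {
  gm <- gamete_frequencies(g_maternal)
  gp <- gamete_frequencies(g_paternal)
  pt <- .pair_table
  prob <- gm[pt$m_type] * gp[pt$p_type] / 4
  freq <- as.vector(rowsum(prob, pt$class))
  names(freq) <- .class_names
  components <- data.frame(
    class = pt$class,
    class_name = .class_names[pt$class],
    m_gamete = pt$mg,
    p_gamete = pt$pg,
    m_type = .gamete_type_names[pt$m_type],
    p_type = .gamete_type_names[pt$p_type],
    prob = as.numeric(prob),
    stringsAsFactors = FALSE
  )
  structure(list(freq = freq, components = components),
            class = "genotype_class_table")
}

#' @export
print.genotype_class_table <- function(x, ...) {
  cat("Four-marker genotype class table: 81 classes,",
      nrow(x$components), "ordered gamete pairings\n")
  nz <- sum(x$freq > 0)
  cat(sprintf("  classes with positive probability: %d; sum = %.6f\n",
              nz, sum(x$freq)))
  invisible(x)
}
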
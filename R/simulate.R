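# Meiosis simulator: full-sib F2 families with known four-locus
# interference structure, window by window.

#' Draw concrete gametes from gamete-type frequencies
#'
#' Expands the eight types into the 16 concrete gametes (each complementary
#' gamete at \eqn{g_t/2}) and samples `n` of them.
#'
#' @param g Gamete-type frequencies.
#' @param n Number of gametes.
#' @return An `n x 4` integer matrix of alleles (1 = parental "ABCD" phase,
#'   0 = alternate), with attribute `"type"` giving each gamete's type index
#'   (1..8). Uses the current RNG state.
#' @export
draw_gametes <- function(g, n) {
  g <- gamete_frequencies(g)
  idx <- sample.int(16L, n, replace = TRUE, prob = rep(g, each = 2L) / 2)
  out <- .gamete_alleles[idx, , drop = FALSE]
  attr(out, "type") <- .gamete_type_of[idx]
  out
}

#' Encode informative-parent gametes as testcross offspring genotypes
#'
#' At testcross-informative markers (`lm_ll`, `nn_np`) the uninformative
#' parent contributes a constant allele, so the offspring call is decided by
#' the informative parent's gamete alone: code 2 (homozygous) when it
#' carries the parental-phase allele, code 1 (heterozygous) otherwise.
#' Code 0 never occurs in a testcross window.
#'
#' @param gametes An `n x 4` allele matrix as from [draw_gametes()].
#' @param seg_type `"lm_ll"` or `"nn_np"` (both encode identically; the
#'   argument validates intent).
#' @return An `n x 4` integer genotype-code matrix with values in `{1, 2}`.
#' @export
testcross_encode <- function(gametes, seg_type = c("lm_ll", "nn_np")) {
  seg_type <- match.arg(seg_type)
  codes <- gametes + 1L
  attr(codes, "type") <- NULL
  codes
}

#' Simulate one four-marker window of a full-sib family
#'
#' Each offspring receives one maternal and one paternal gamete drawn from
#' the 16-gamete expansions of the parental type frequencies. For `hk_hk`
#' windows the genotype code at each marker is the number of parental-phase
#' alleles (0/1/2); for testcross windows only the informative parent's
#' gamete is visible (codes 1/2).
#'
#' @param g_maternal,g_paternal Parental gamete-type frequencies.
#' @param n Family size.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param seg_type Segregation type of the window's markers.
#' @param markers Column (marker) names.
#' @param ids Row (individual) ids.
#' @return An `n x 4` integer genotype matrix; attributes
#'   `"maternal_type"` and `"paternal_type"` record the drawn gamete types.
#' @export
simulate_family <- function(g_maternal, g_paternal = g_maternal, n,
                            seed = 20190515L,
                            seg_type = c("hk_hk", "lm_ll", "nn_np"),
                            markers = paste0("M", 1:4),
                            ids = sprintf("ind%04d", seq_len(n))) {
  seg_type <- match.arg(seg_type)
  if (n < 1L) stop("family size must be at least 1")
  set.seed(seed)
  hm <- draw_gametes(g_maternal, n)
  hp <- draw_gametes(g_paternal, n)
  codes <- switch(seg_type,
                  hk_hk = hm + hp,
                  lm_ll = testcross_encode(hm, "lm_ll"),
                  nn_np = testcross_encode(hp, "nn_np"))
  mt <- attr(hm, "type"); pt <- attr(hp, "type")
  attributes(codes) <- NULL
  codes <- matrix(as.integer(codes), n, 4L, dimnames = list(ids, markers))
  attr(codes, "maternal_type") <- mt
  attr(codes, "paternal_type") <- pt
  codes
}

#' Default configuration of a simulated full-sib study
#'
#' The defaults emulate the geometry of a forest-tree full-sib linkage
#' study: 19 linkage groups spanning 530 down to 130 cM, a family of 408
#' offspring, windows cycling through the three segregation types, and
#' per-window true gamete frequencies drawn from a Dirichlet distribution
#' concentrated on the non-recombinant type (small interval recombination
#' fractions, coincidence coefficients scattered above and below 1).
#'
#' @param n_lg Number of linkage groups.
#' @param markers_per_lg Markers per linkage group (equally spaced).
#' @param lg_lengths Genetic lengths in cM, one per linkage group.
#' @param family_size Offspring per family.
#' @param seg_pattern Segregation types cycled over consecutive windows.
#' @param truth Per-window truth: `NULL` (Dirichlet draws with
#'   `truth_alpha`), a single gamete-frequency vector used everywhere, or a
#'   function `function(lg, window, region, length_cM)` returning one.
#' @param truth_alpha Dirichlet concentration for the default truth draws.
#' @param k_regions Number of regions per linkage group (used to label
#'   windows in the truth file).
#' @param seed Study seed.
#' @return A config list for [simulate_study()].
#' @export
study_config <- function(n_lg = 19L,
                         markers_per_lg = 40L,
                         lg_lengths = round(seq(530, 130,
                                                length.out = n_lg), 1),
                         family_size = 408L,
                         seg_pattern = c("hk_hk", "lm_ll", "nn_np"),
                         truth = NULL,
                         truth_alpha = c(g000 = 100, g001 = 3, g010 = 3,
                                         g011 = 0.5, g100 = 3, g101 = 0.5,
                                         g110 = 0.5, g111 = 0.15),
                         k_regions = 3L,
                         seed = 20190515L) {
  stopifnot(length(lg_lengths) == n_lg, markers_per_lg >= 4L,
            family_size >= 1L, all(seg_pattern %in% .seg_types))
  list(n_lg = as.integer(n_lg), markers_per_lg = as.integer(markers_per_lg),
       lg_lengths = lg_lengths, family_size = as.integer(family_size),
       seg_pattern = seg_pattern, truth = truth, truth_alpha = truth_alpha,
       k_regions = as.integer(k_regions), seed = as.integer(seed))
}

#' Simulate a full-sib interference study
#'
#' Builds a genetic map (equally spaced markers on each linkage group, one
#' segregation type per four-marker window), draws per-window true gamete
#' frequencies, simulates the family window by window, and records the
#' truth (g, r, C per window). Windows are simulated independently: the
#' analysis unit is the disjoint four-marker quadruple, and no between-
#' window interference process is imposed. Trailing markers that complete
#' no window are left unscored (`NA`).
#'
#' @param config Configuration from [study_config()].
#' @param dir Optional directory; when given, writes `map.tsv`,
#'   `genotypes.tsv` and `truth.json` there via the package's writers.
#' @return A list with `map` (genetic map data frame), `geno` (genotype
#'   matrix) and `truth` (list with per-window `lg`, `markers`, `region`,
#'   `g`, `r`, `C`, plus `seed`, `n` and the map geometry). Two runs with
#'   the same config are identical.
#' @export
simulate_study <- function(config = study_config(), dir = NULL) {
  set.seed(config$seed)
  n_win_lg <- config$markers_per_lg %/% 4L
  if (n_win_lg < 1L) stop("markers_per_lg must allow at least one window")
  ids <- sprintf("ind%04d", seq_len(config$family_size))

  map_rows <- list()
  windows <- list()
  geno_cols <- list()
  win_id <- 0L
  lg_names <- as.character(seq_len(config$n_lg))
  # build in the map's canonical order (linkage groups sort as character)
  # so windows, genotype columns and truth records line up with a re-read map
  for (j in order(lg_names)) {
    lg <- lg_names[j]
    L <- config$lg_lengths[j]
    pos <- round(seq(0, L, length.out = config$markers_per_lg), 4)
    seg_marker <- rep("lm_ll", config$markers_per_lg)
    br <- seq(0, L, length.out = config$k_regions + 1L)
    for (w in seq_len(n_win_lg)) {
      win_id <- win_id + 1L
      idx <- (4L * (w - 1L) + 1L):(4L * w)
      seg <- config$seg_pattern[(w - 1L) %% length(config$seg_pattern) + 1L]
      seg_marker[idx] <- seg
      names_w <- sprintf("%s_lg%s_%03d", seg, lg, idx)
      region <- .region_of((pos[idx[1]] + pos[idx[4]]) / 2, br)
      g <- tryCatch(
        .window_truth(config, lg, w, region, L),
        error = function(e) {
          stop(sprintf("invalid truth for window %d of linkage group %s: %s",
                       w, lg, conditionMessage(e)), call. = FALSE)
        })
      codes <- matrix(NA_integer_, config$family_size, 4L)
      hm <- draw_gametes(g$maternal, config$family_size)
      hp <- draw_gametes(g$paternal, config$family_size)
      codes[] <- switch(seg,
                        hk_hk = hm + hp,
                        lm_ll = testcross_encode(hm, "lm_ll"),
                        nn_np = testcross_encode(hp, "nn_np"))
      colnames(codes) <- names_w
      geno_cols[[win_id]] <- codes
      r <- recombination_fractions(g$maternal)
      C <- coincidence_coefficients(g$maternal, r)
      windows[[win_id]] <- list(lg = lg, markers = names_w, region = region,
                                seg_type = seg, g = g$maternal, r = r, C = C)
    }
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      name = sprintf("%s_lg%s_%03d", seg_marker, lg,
                     seq_len(config$markers_per_lg)),
      linkage_group = lg, position_cM = pos, seg_type = seg_marker,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_rows)
  rownames(map) <- NULL

  geno <- do.call(cbind, geno_cols)
  rem <- setdiff(map$name, colnames(geno))
  if (length(rem)) {
    pad <- matrix(NA_integer_, config$family_size, length(rem),
                  dimnames = list(NULL, rem))
    geno <- cbind(geno, pad)
  }
  rownames(geno) <- ids
  geno <- geno[, map$name, drop = FALSE]

  truth <- list(windows = windows, seed = config$seed,
                n = config$family_size,
                n_lg = config$n_lg, markers_per_lg = config$markers_per_lg,
                lg_lengths = config$lg_lengths,
                k_regions = config$k_regions)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    hdr <- c(sprintf("fourpoint simulate_study seed=%d n=%d",
                     config$seed, config$family_size))
    write_genetic_map(map, file.path(dir, "map.tsv"), comments = hdr)
    write_genotype_matrix(geno, file.path(dir, "genotypes.tsv"),
                          comments = hdr)
    write_truth_json(truth, file.path(dir, "truth.json"))
  }
  list(map = map, geno = geno, truth = truth)
}

.window_truth <- function(config, lg, w, region, length_cM) {
  tr <- config$truth
  if (is.null(tr)) {
    x <- stats::rgamma(8L, shape = config$truth_alpha)
    if (sum(x) <= 0) x <- c(1, rep(0, 7))
    g <- gamete_frequencies(x / sum(x))
    return(list(maternal = g, paternal = g))
  }
  if (is.function(tr)) {
    g <- tr(lg = lg, window = w, region = region, length_cM = length_cM)
    if (is.list(g) && !is.null(g$maternal)) {
      return(list(maternal = gamete_frequencies(g$maternal),
                  paternal = gamete_frequencies(g$paternal)))
    }
    g <- gamete_frequencies(g)
    return(list(maternal = g, paternal = g))
  }
  g <- gamete_frequencies(tr)
  list(maternal = g, paternal = g)
}
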
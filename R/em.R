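# Estimating gamete-type frequencies from offspring genotypes: EM over the
# 81-class mixture for intercross-informative (hk_hk) windows, direct gamete
# counting for testcross-informative (lm_ll / nn_np) windows.

#' Count four-marker genotype classes in a window
#'
#' Each individual with four non-missing calls contributes to exactly one of
#' the 81 classes; individuals with any missing call in the window are
#' dropped (window-wise, not file-wise).
#'
#' @param geno Genotype matrix, see [read_genotype_matrix()].
#' @param window Character vector of 4 marker names, in map order.
#' @return A list of class `genotype_count_table` with `counts` (named
#'   integer vector of length 81), `n_used` and `n_dropped`.
#' @export
count_genotypes <- function(geno, window) {
  if (length(window) != 4L) stop("window must name 4 markers")
  absent <- setdiff(window, colnames(geno))
  if (length(absent)) {
    stop("window marker(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  calls <- geno[, window, drop = FALSE]
  idx <- classify_offspring(calls)
  counts <- tabulate(idx, nbins = 81L)
  names(counts) <- .class_names
  structure(list(counts = counts,
                 n_used = sum(!is.na(idx)),
                 n_dropped = sum(is.na(idx))),
            class = "genotype_count_table")
}

#' EM estimation of gamete-type frequencies from genotype class counts
#'
#' For intercross-informative (hk_hk) windows the parental origin of alleles
#' is partially confounded: each genotype class is a mixture of several
#' ordered gamete pairings. The E-step distributes each class count over its
#' contributing (maternal, paternal) gamete pairs in proportion to their
#' current probabilities; the M-step sets each type frequency to its
#' expected share of the 2n parental gamete draws. A single gamete-frequency
#' vector is shared by both parents (the symmetric full-sib design).
#'
#' The log-likelihood is non-decreasing across iterations; iteration stops
#' when the largest change in any frequency drops below `tol` or after
#' `max_iter` iterations. If some observed class acquires vanishing model
#' probability (possible after a boundary excursion), the estimate is
#' jittered once toward the interior (seeded) rather than letting the
#' likelihood degenerate. Boundary estimates (some \eqn{\hat g = 0}) are
#' legitimate — they indicate complete interference — and are reported
#' as converged.
#'
#' @param counts A `genotype_count_table` from [count_genotypes()], or a
#'   numeric vector of 81 class counts.
#' @param init `"uniform"` (each type 1/8, the phase-agnostic default) or a
#'   numeric vector of 8 starting frequencies.
#' @param tol Convergence tolerance on `max |change in g|` per iteration.
#' @param max_iter Maximum number of EM iterations.
#' @param seed Seed for the (rarely used) interior jitter.
#' @return A list of class `em_result`: `g_hat` (named length-8 vector),
#'   `loglik_trace`, `n_iter`, `converged`, `n_used`.
#' @export
em_estimate <- function(counts, init = "uniform", tol = 1e-8,
                        max_iter = 5000L, seed = 20190515L) {
  n <- if (inherits(counts, "genotype_count_table")) counts$counts else counts
  if (length(n) != 81L || any(n < 0)) {
    stop("counts must be 81 non-negative class counts")
  }
  N <- sum(n)
  if (N == 0) stop("all genotype class counts are zero")

  g <- if (identical(init, "uniform")) {
    rep(1 / 8, 8L)
  } else {
    unname(gamete_frequencies(init))
  }
  pt <- .pair_table
  A <- .type_count_matrix
  obs <- n > 0
  ratio <- numeric(81L)

  ll_trace <- numeric(max_iter)
  jittered <- FALSE
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pp <- g[pt$m_type] * g[pt$p_type] / 4
    pc <- as.vector(rowsum(pp, pt$class))
    if (any(obs & pc < 1e-300)) {
      if (jittered) stop("non-finite likelihood: observed class with zero model probability")
      set.seed(seed)
      u <- stats::runif(8L)
      g <- 0.9 * g + 0.1 * u / sum(u)
      jittered <- TRUE
      it <- it - 1L
      next
    }
    ll_trace[it] <- sum(n[obs] * log(pc[obs]))
    ratio[] <- 0
    ratio[obs] <- n[obs] / pc[obs]
    w <- pp * ratio[pt$class]
    g_new <- as.vector(crossprod(A, w)) / (2 * N)
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    g_hat = stats::setNames(g, .gamete_type_names),
    loglik_trace = ll_trace[seq_len(it)],
    n_iter = it,
    converged = converged,
    n_used = N
  ), class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM gamete-frequency estimate (n = %d, %d iteration(s), %s)\n",
              x$n_used, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$g_hat, 6))
  invisible(x)
}

#' Direct gamete counting for testcross-informative windows
#'
#' At markers heterozygous in only one parent (`lm_ll`: first parent;
#' `nn_np`: second parent) the offspring genotype reveals the informative
#' parent's gamete directly: calls are `2` (homozygous, informative parent
#' transmitted the parental-phase allele) or `1` (heterozygous). Each
#' offspring's four calls decode to one of the 16 concrete gametes, which
#' collapses to its complementary-pair type; frequencies are the type counts
#' over the individuals used.
#'
#' Individuals with a missing call are dropped silently (counted in
#' `n_dropped`); individuals with a call inconsistent with a testcross
#' (code 0) are dropped with a warning (counted in `n_invalid`).
#'
#' @param geno Genotype matrix.
#' @param window Character vector of 4 marker names.
#' @param informative_parent `"maternal"` or `"paternal"`; recorded in the
#'   result (the decoding itself is identical).
#' @return A list of class `direct_result`: `g_hat`, `n_used`, `n_dropped`,
#'   `n_invalid`, `informative_parent`.
#' @export
direct_gamete_estimate <- function(geno, window,
                                   informative_parent = c("maternal",
                                                          "paternal")) {
  informative_parent <- match.arg(informative_parent)
  if (length(window) != 4L) stop("window must name 4 markers")
  absent <- setdiff(window, colnames(geno))
  if (length(absent)) {
    stop("window marker(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  calls <- geno[, window, drop = FALSE]
  missing <- rowSums(is.na(calls)) > 0L
  invalid <- !missing & rowSums(calls == 0L, na.rm = TRUE) > 0L
  if (any(invalid)) {
    warning(sprintf(
      "%d individual(s) dropped: homozygous-alternate call (0) is inconsistent with a testcross window",
      sum(invalid)))
  }
  h <- calls[!missing & !invalid, , drop = FALSE] - 1L
  n_used <- nrow(h)
  if (n_used == 0L) stop("no usable individuals in testcross window")
  t_idx <- 4L * ((h[, 1] + h[, 2]) %% 2L) +
    2L * ((h[, 2] + h[, 3]) %% 2L) +
    ((h[, 3] + h[, 4]) %% 2L) + 1L
  counts <- tabulate(t_idx, nbins = 8L)
  structure(list(
    g_hat = stats::setNames(counts / n_used, .gamete_type_names),
    n_used = n_used,
    n_dropped = sum(missing),
    n_invalid = sum(invalid),
    informative_parent = informative_parent
  ), class = "direct_result")
}

#' Estimate gamete frequencies for one window, dispatching on segregation
#' type
#'
#' hk_hk windows go through [em_estimate()] on the 81-class counts; lm_ll
#' and nn_np windows through [direct_gamete_estimate()] (informative parent
#' maternal resp. paternal). Windows mixing segregation types carry no
#' single four-point likelihood and are skipped with a reason.
#'
#' @param geno Genotype matrix.
#' @param window Character vector of 4 marker names (must lie on one
#'   linkage group).
#' @param map Genetic map.
#' @param em_control Optional list of arguments passed to [em_estimate()]
#'   (`init`, `tol`, `max_iter`, `seed`).
#' @return A list with `method` (`"em"`, `"direct"` or `"skipped"`),
#'   `g_hat` (`NULL` when skipped), `n_used`, `n_dropped`, `reason` (for
#'   skipped windows) and `detail` (the underlying estimator result).
#' @export
estimate_window <- function(geno, window, map, em_control = list()) {
  i <- match(window, map$name)
  if (anyNA(i)) {
    stop("window marker(s) not in map: ",
         paste(window[is.na(i)], collapse = ", "))
  }
  rows <- map[i, , drop = FALSE]
  if (length(unique(rows$linkage_group)) > 1L) {
    stop("window spans more than one linkage group")
  }
  st <- unique(rows$seg_type)
  if (length(st) > 1L) {
    return(list(method = "skipped", g_hat = NULL, n_used = NA_integer_,
                n_dropped = NA_integer_,
                reason = paste0("mixed segregation types: ",
                                paste(st, collapse = ", ")),
                detail = NULL))
  }
  if (st == "hk_hk") {
    ct <- count_genotypes(geno, window)
    fit <- do.call(em_estimate, c(list(counts = ct), em_control))
    list(method = "em", g_hat = fit$g_hat, n_used = ct$n_used,
         n_dropped = ct$n_dropped, reason = NA_character_, detail = fit)
  } else {
    parent <- if (st == "lm_ll") "maternal" else "paternal"
    fit <- direct_gamete_estimate(geno, window, parent)
    list(method = "direct", g_hat = fit$g_hat, n_used = fit$n_used,
         n_dropped = fit$n_dropped + fit$n_invalid, reason = NA_character_,
         detail = fit)
  }
}
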
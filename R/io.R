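# Readers and writers for the fixed TSV/JSON dialects: genetic maps,
# genotype matrices, scan tables, and simulation truth files. Lines starting
# with "#" are treated as comments in all TSV files.

.seg_types <- c("hk_hk", "lm_ll", "nn_np")

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "")
}

.write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read a genetic map
#'
#' The map TSV has header columns `name`, `linkage_group`, `position_cM`,
#' `seg_type` (segregation type, one of `hk_hk`, `lm_ll`, `nn_np`). Markers
#' are returned sorted by (linkage group, position, name); all validation
#' problems are reported together.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `name` (character, unique),
#'   `linkage_group` (character), `position_cM` (numeric), `seg_type`.
#' @export
read_genetic_map <- function(path) {
  df <- .read_tsv(path)
  need <- c("name", "linkage_group", "position_cM", "seg_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("genetic map is missing column(s): ", paste(miss, collapse = ", "))
  }
  probs <- character()
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup)) {
    probs <- c(probs, paste0("duplicate marker name(s): ",
                             paste(dup, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(df$position_cM))
  bad_pos <- which(is.na(pos))
  if (length(bad_pos)) {
    probs <- c(probs, paste0("non-numeric position_cM in row(s): ",
                             paste(bad_pos, collapse = ", ")))
  }
  bad_seg <- which(!(df$seg_type %in% .seg_types))
  if (length(bad_seg)) {
    probs <- c(probs, paste0(
      "unknown seg_type in row(s) ", paste(bad_seg, collapse = ", "),
      " (field seg_type: ",
      paste(unique(df$seg_type[bad_seg]), collapse = ", "),
      "); expected one of ", paste(.seg_types, collapse = ", ")))
  }
  if (length(probs)) {
    stop("invalid genetic map:\n  ", paste(probs, collapse = "\n  "))
  }
  out <- data.frame(name = df$name, linkage_group = df$linkage_group,
                    position_cM = pos, seg_type = df$seg_type,
                    stringsAsFactors = FALSE)
  out <- out[order(out$linkage_group, out$position_cM, out$name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a genetic map
#'
#' @param map Data frame as returned by [read_genetic_map()].
#' @param path Output path.
#' @param comments Optional character vector of header comment lines
#'   (written "# "-prefixed).
#' @export
write_genetic_map <- function(map, path, comments = NULL) {
  .write_tsv(map[, c("name", "linkage_group", "position_cM", "seg_type")],
             path, comments)
  invisible(path)
}

#' Read a genotype matrix
#'
#' TSV with one row per individual: first column the individual id, the
#' remaining columns one per marker, with calls coded `2` (homozygous for
#' the parental-phase alleles), `1` (heterozygous), `0` (homozygous
#' alternate). `NA`, `-` and the empty string denote a missing call. The
#' column set must equal the map's marker set; columns are returned in map
#' order.
#'
#' @param path Path to the TSV file.
#' @param map Genetic map, see [read_genetic_map()].
#' @return Integer matrix (individuals x markers) with `NA` for missing
#'   calls; rownames are individual ids, colnames marker names.
#' @export
read_genotype_matrix <- function(path, map) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop("genotype file needs an id column plus markers")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate individual id(s) in genotype file")
  markers <- names(df)[-1L]
  probs <- character()
  unknown <- setdiff(markers, map$name)
  if (length(unknown)) {
    probs <- c(probs, paste0("marker column(s) not in map: ",
                             paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(map$name, markers)
  if (length(absent)) {
    probs <- c(probs, paste0("map marker(s) missing from genotype file: ",
                             paste(absent, collapse = ", ")))
  }
  if (length(probs)) {
    stop("invalid genotype matrix:\n  ", paste(probs, collapse = "\n  "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m %in% c("NA", "-", "")] <- NA_character_
  bad <- which(!is.na(m) & !(m %in% c("0", "1", "2")), arr.ind = TRUE)
  if (nrow(bad)) {
    ex <- bad[1L, ]
    stop(sprintf(
      "invalid genotype call \"%s\" at individual %s, marker %s (%d bad cell(s); allowed: 0, 1, 2, NA, -, empty)",
      m[ex[1L], ex[2L]], ids[ex[1L]], markers[ex[2L]], nrow(bad)))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(ids, markers)
  m[, map$name, drop = FALSE]
}

#' Write a genotype matrix
#'
#' @param geno Integer matrix as returned by [read_genotype_matrix()].
#' @param path Output path.
#' @param comments Optional header comment lines.
#' @export
write_genotype_matrix <- function(geno, path, comments = NULL) {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, comments)
  invisible(path)
}

.scan_lead_cols <- c("r_AB", "r_BC", "r_CD", "r_AC", "r_BD", "r_AD",
                     "C1", "C2", "C3", "C4", "lg",
                     "marker1", "marker2", "marker3", "marker4")
.scan_extra_cols <- c("method", "n_used", "pos_mid")

#' Write a genome-scan table
#'
#' Columns follow the conventional scan-table layout: the six recombination
#' fractions, the four coincidence coefficients, the linkage group and the
#' four marker names, then `method`, `n_used` and `pos_mid`. Undefined
#' coefficients are written as `NA`.
#'
#' @param scan Scan data frame from [scan_interference()]; an empty data
#'   frame yields a header-only file.
#' @param path Output path.
#' @param comments Optional header comment lines.
#' @export
write_scan_table <- function(scan, path, comments = NULL) {
  cols <- c(.scan_lead_cols, intersect(.scan_extra_cols, names(scan)))
  if (nrow(scan) == 0L) {
    df <- scan[, cols, drop = FALSE]
  } else {
    df <- scan[, cols, drop = FALSE]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), NA_character_, format(x, digits = 15, trim = TRUE,
                                             scientific = FALSE))
    })
  }
  .write_tsv(df, path, comments)
  invisible(path)
}

#' Read a genome-scan table
#'
#' @param path Path to a TSV written by [write_scan_table()].
#' @return Data frame with the scan columns; `NA` for undefined
#'   coefficients.
#' @export
read_scan_table <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(.scan_lead_cols, names(df))
  if (length(miss)) {
    stop("scan table is missing column(s): ", paste(miss, collapse = ", "))
  }
  num <- setdiff(names(df), c("lg", "marker1", "marker2", "marker3",
                              "marker4", "method"))
  for (cn in num) {
    df[[cn]] <- suppressWarnings(as.numeric(ifelse(df[[cn]] == "NA", NA,
                                                   df[[cn]])))
  }
  if ("n_used" %in% names(df)) df$n_used <- as.integer(df$n_used)
  df
}

#' Write a simulation truth file
#'
#' JSON with the per-window true gamete frequencies, recombination fractions
#' and coincidence coefficients of a simulated study, plus the seed and
#' family size.
#'
#' @param truth Truth object from [simulate_study()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a simulation truth file
#'
#' @param path Path to a JSON written by [write_truth_json()].
#' @return The truth list; per-window `g`, `r`, `C` are named numeric
#'   vectors.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  x$windows <- lapply(x$windows, function(w) {
    w$g <- stats::setNames(as.numeric(w$g), .gamete_type_names)
    w$r <- stats::setNames(as.numeric(w$r),
                           c("r_AB", "r_BC", "r_CD", "r_AC", "r_BD", "r_AD"))
    w$C <- stats::setNames(as.numeric(w$C), c("C1", "C2", "C3", "C4"))
    w$markers <- as.character(w$markers)
    w
  })
  x
}
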
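#' Trait matrices, language metadata and phylogenies
#'
#' The canonical in-memory containers: a `trait_matrix` is an integer matrix
#' of 0/1 with `NA` marking missing cells (languages in rows, features in
#' columns, both named); `language_records` is a data.frame with columns
#' `id`, `name`, `lat`, `lon`, `family_path`; a `phylogeny` is a rooted
#' forest (list of `ape::phylo` trees) plus a tip label -> language id map.
#'
#' @name glossarea-containers
NULL

new_trait_matrix <- function(values) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("trait matrix must have language row names and feature column names")
  if (anyDuplicated(rownames(values))) stop("duplicate language id")
  if (anyDuplicated(colnames(values))) stop("duplicate feature id")
  ok <- is.na(values) | values == 0L | values == 1L
  if (!all(ok)) stop("non-binary value in trait matrix")
  if (any(colSums(!is.na(values)) == 0)) stop("empty feature column")
  storage.mode(values) <- "integer"
  structure(values, class = c("trait_matrix", "matrix"))
}

#' Read a binary trait matrix
#'
#' Reads a CSV/TSV table with a header of feature ids, one row per language
#' and the language id in the first column. Cells equal to `missing_token`
#' become missing; any other value outside \{0, 1\} is an error.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   override with `sep`).
#' @param missing_token string marking a missing cell, default `"NA"`.
#' @param sep field separator; default `","`, or `"\t"` for `.tsv` files.
#' @return a `trait_matrix` (integer matrix with NA for missing).
#' @export
read_trait_matrix <- function(path, missing_token = "NA", sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0))
  if (anyDuplicated(tab[[1]])) stop("duplicate language id in ", path)
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  vals[vals == missing_token] <- NA
  bad <- !is.na(vals) & !(vals %in% c("0", "1"))
  if (any(bad)) stop("non-binary value in trait matrix: ",
                     paste(unique(vals[bad]), collapse = ", "))
  m <- matrix(as.integer(vals), nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  new_trait_matrix(m)
}

#' Write a trait matrix
#'
#' Inverse of [read_trait_matrix()]: round-trips cell values and the
#' missing mask exactly.
#'
#' @param tm a `trait_matrix`.
#' @param path output file.
#' @param missing_token token written for missing cells.
#' @export
write_trait_matrix <- function(tm, path, missing_token = "NA") {
  vals <- matrix(as.character(tm), nrow(tm), ncol(tm))
  vals[is.na(vals)] <- missing_token
  df <- data.frame(language = rownames(tm), vals, check.names = FALSE)
  colnames(df) <- c("language", colnames(tm))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read language metadata
#'
#' CSV with columns `id`, `name`, `lat`, `lon`, `family_path` (the
#' classification path as `/`-separated node labels; empty for isolates).
#'
#' @param path CSV file.
#' @return data.frame of class `language_records`.
#' @export
read_language_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "lat", "lon", "family_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  validate_language_records(df)
}

validate_language_records <- function(df) {
  if (anyDuplicated(df$id)) stop("duplicate language id in metadata")
  if (!all(is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90))
    stop("latitude out of range")
  if (!all(is.finite(df$lon)) || any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range")
  class(df) <- c("language_records", "data.frame")
  df
}

#' Read a phylogenetic forest from Newick
#'
#' Parses one or more rooted trees (one Newick string per line or a
#' multi-tree file). Trees without branch lengths get unit length on every
#' edge, a deterministic fallback for classification trees that carry no
#' length information. Isolates may be supplied as single-tip trees.
#'
#' @param path Newick file.
#' @param tip_map optional data.frame with columns `tip`, `id` mapping tip
#'   labels to language ids; defaults to the identity map.
#' @param language_ids optional character vector of known language ids;
#'   mapped tips not in it are an error, unmatched ids are reported.
#' @return object of class `phylogeny`: list with `trees` (a `multiPhylo`)
#'   and `tip_map` (named character: tip label -> language id).
#' @export
read_phylogeny <- function(path, tip_map = NULL, language_ids = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  trees <- lapply(txt, function(s) {
    tr <- tryCatch(read_single_newick(s), error = function(e)
      stop("unparseable Newick: ", conditionMessage(e)))
    tr
  })
  phylogeny_from_trees(trees, tip_map, language_ids)
}

# ape::read.tree rejects single-tip trees like "A:1;"; handle them directly.
read_single_newick <- function(s) {
  s <- trimws(s)
  if (!grepl("\\(", s)) {
    lab <- sub(";$", "", s)
    len <- 1
    if (grepl(":", lab)) {
      len <- as.numeric(sub("^.*:", "", lab))
      lab <- sub(":.*$", "", lab)
    }
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = lab, edge.length = len, Nnode = 1L),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- suppressWarnings(ape::read.tree(text = s))
  if (is.null(tr)) stop("not a valid tree")
  tr
}

phylogeny_from_trees <- function(trees, tip_map = NULL, language_ids = NULL) {
  trees <- lapply(trees, function(tr) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    if (any(tr$edge.length < 0)) stop("negative branch length")
    tr
  })
  tips <- unlist(lapply(trees, `[[`, "tip.label"))
  if (anyDuplicated(tips)) stop("tip label appears in more than one tree")
  if (is.null(tip_map)) {
    map <- stats::setNames(tips, tips)
  } else {
    map <- stats::setNames(as.character(tip_map$id), as.character(tip_map$tip))
    if (anyDuplicated(map)) stop("language id mapped to more than one tip")
    map <- map[tips[tips %in% names(map)]]
  }
  if (!is.null(language_ids)) {
    unknown <- setdiff(map, language_ids)
    if (length(unknown)) stop("tip mapped to unknown language id: ",
                              paste(unknown, collapse = ", "))
    unmatched <- setdiff(language_ids, map)
    if (length(unmatched))
      ga_log("io_core", "info", paste("languages without a tip:",
                                      paste(unmatched, collapse = ", ")))
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, tip_map = map), class = "phylogeny")
}

#' @export
print.phylogeny <- function(x, ...) {
  nt <- length(x$trees)
  cat(sprintf("<phylogeny: %d tree%s, %d mapped tips>\n",
              nt, if (nt == 1) "" else "s", length(x$tip_map)))
  invisible(x)
}

#' Inter-rater reliability summary
#'
#' From double-coded datapoint counts, computes the percentage of
#' codability disagreements (one coder declines to assign a value) and of
#' value disagreements (both code, values differ), each as
#' `100 * count / n` rounded half-up to one decimal.
#'
#' @param n_datapoints number of double-coded datapoints.
#' @param n_codability_disagreements count of codability disagreements.
#' @param n_value_disagreements count of value disagreements.
#' @return named list: `codability_pct`, `value_pct`.
#' @examples
#' interrater_stats(154, 19, 13)  # 12.3, 8.4
#' @export
interrater_stats <- function(n_datapoints, n_codability_disagreements,
                             n_value_disagreements) {
  if (n_datapoints <= 0) stop("zero datapoints")
  cnt <- c(n_codability_disagreements, n_value_disagreements)
  if (any(cnt < 0) || any(cnt > n_datapoints))
    stop("disagreement counts must be in [0, n_datapoints]")
  list(codability_pct = round_half_up(100 * cnt[1] / n_datapoints, 1),
       value_pct = round_half_up(100 * cnt[2] / n_datapoints, 1))
}
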
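# Gene-set over-representation: an explicit one-sided hypergeometric test
# with BH correction (replacing an external web-tool workflow), plus the
# simple cross-list overlap statistic.

#' Gene set collection
#'
#' @param sets named list of character vectors (set name -> member gene
#'   ids).
#' @param universe character vector of gene ids; set members outside the
#'   universe are dropped during harmonization.
#' @return object of class `rp_gene_sets`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe), class = "rp_gene_sets")
}

#' @export
print.rp_gene_sets <- function(x, ...) {
  cat(sprintf(
    "riboTE gene sets: %d sets over a universe of %d genes\n",
    length(x$sets), length(x$universe)
  ))
  invisible(x)
}

#' Read a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>member...`. Duplicated members
#' on a line are removed with a warning; malformed lines (fewer than 3
#' fields) are reported with their line numbers.
#'
#' @param path GMT file.
#' @param universe optional universe; defaults to the union of all members.
#' @return an `rp_gene_sets` collection.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line(s) (fewer than 3 fields): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  sets <- list()
  for (f in fields) {
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicated member(s) in set '", f[1L], "'; deduplicated")
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  gene_set_collection(sets, universe)
}

#' Write a GMT file
#' @param collection an `rp_gene_sets` (or named list of sets).
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "rp_gene_sets")) collection$sets else collection
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else {
      "na"
    }
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each set, the p-value is the upper-tail hypergeometric probability
#' of observing at least the realized overlap between the query and the set
#' when drawing `|query|` genes from the universe. Plain one-sided
#' hypergeometric with BH correction across sets (no EASE-style score
#' deflation). Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of gene ids.
#' @param collection an `rp_gene_sets`.
#' @return data.frame with set_name, overlap, set_size, query_size,
#'   universe_size, fold_enrichment, p_value, q_value, ordered by p.
#' @export
hypergeometric_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "rp_gene_sets"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(
      length(outside),
      " query gene(s) outside the universe dropped"
    )
    query <- setdiff(query, outside)
  }
  if (!length(query)) {
    stop("query is empty after harmonization with the universe", call. = FALSE)
  }
  N <- length(collection$universe)
  q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    k <- length(intersect(query, s))
    K <- length(s)
    p <- phyper(k - 1L, K, N - K, q, lower.tail = FALSE)
    fe <- if (k == 0L) 0 else (k / q) / (K / N)
    data.frame(
      set_name = nm, overlap = k, set_size = K, query_size = q,
      universe_size = N, fold_enrichment = fe, p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap fraction and Jaccard index of two gene lists
#'
#' @param list_a,list_b character vectors; `list_a` must be nonempty.
#' @return list with `fraction_a_in_b` (|a intersect b| / |a|) and
#'   `jaccard` (|a intersect b| / |a union b|).
#' @export
#' @examples
#' overlap_fraction(c("a", "b"), c("b", "c"))
overlap_fraction <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  if (!length(a)) stop("list_a must be nonempty", call. = FALSE)
  inter <- length(intersect(a, b))
  list(
    fraction_a_in_b = inter / length(a),
    jaccard = inter / length(union(a, b))
  )
}
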
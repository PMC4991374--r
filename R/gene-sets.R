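#' Construct a named gene set
#'
#' Identifiers are normalized by whitespace trimming and case folding to
#' lower case (the *C. elegans* gene-name convention); duplicates after
#' normalization are dropped with a message. No alias or ortholog
#' resolution is attempted.
#'
#' @param members Character vector of gene identifiers.
#' @param name Label for the set.
#' @return An object of class `gene_set`: list with `name` and the sorted
#'   unique `members`.
#' @examples
#' gene_set(c("daf-2", "DAF-2", "mtl-1"), name = "example")
#' @export
gene_set <- function(members, name = "gene_set") {
  if (!is.character(members)) stop("'members' must be character", call. = FALSE)
  ids <- tolower(trimws(members))
  ids <- ids[nzchar(ids)]
  dup <- sum(duplicated(ids))
  if (dup > 0) {
    message("gene_set '", name, "': dropped ", dup,
            " duplicate identifier(s) after normalization")
  }
  structure(list(name = as.character(name)[1], members = sort(unique(ids))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d identifiers\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a gene list from a plain-text file
#'
#' One identifier per line; lines starting with `#` and blank lines are
#' ignored. Identifiers are normalized as in [gene_set()].
#'
#' @param path Path to the file.
#' @param name Set label; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("gene list is empty after filtering: ", path, call. = FALSE)
  }
  gene_set(lines, name = name)
}

#' Write a gene set to a plain-text file
#'
#' One identifier per line, the format read back by [read_gene_list()].
#'
#' @param set A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$members, path)
  invisible(path)
}

#' Overlap enrichment between two gene sets
#'
#' Intersects two sets, optionally after removing an exclusion list from
#' both (the treatment used when part of a comparison list was derived
#' from the target collection itself and must not count as independent
#' evidence), and evaluates the overlap against the hypergeometric null:
#' observed `k`, chance expectation `m * n / N`, and the upper-tail
#' p-value `P(X >= k)`.
#'
#' @param set1,set2 [gene_set()] objects.
#' @param N Universe size; 20000 is the conventional *C. elegans* genome
#'   approximation.
#' @param exclude Optional [gene_set()] removed from both sets before
#'   sizing and intersecting.
#' @return An object of class `overlap_report`: list with `name1`,
#'   `name2`, `k`, `m`, `n`, `N`, `overlap_ids`, `expected`, `p_value`.
#' @examples
#' a <- gene_set(c("daf-2", "mtl-1", "sod-3"), "a")
#' b <- gene_set(c("mtl-1", "hsp-16.2"), "b")
#' compute_overlap(a, b, N = 20000)
#' @export
compute_overlap <- function(set1, set2, N = 20000, exclude = NULL) {
  stopifnot(inherits(set1, "gene_set"), inherits(set2, "gene_set"))
  m1 <- set1$members
  m2 <- set2$members
  if (!is.null(exclude)) {
    stopifnot(inherits(exclude, "gene_set"))
    m1 <- setdiff(m1, exclude$members)
    m2 <- setdiff(m2, exclude$members)
  }
  m <- length(m1)
  n <- length(m2)
  if (m > N || n > N) {
    stop("universe too small: set sizes exceed N = ", N, call. = FALSE)
  }
  ids <- sort(intersect(m1, m2))
  k <- length(ids)
  structure(list(name1 = set1$name, name2 = set2$name,
                 k = k, m = m, n = n, N = N, overlap_ids = ids,
                 expected = expected_overlap(m, n, N),
                 p_value = hypergeom_upper_tail(N = N, m = m, n = n, k = k)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "overlap '%s' (m = %d) vs '%s' (n = %d), N = %d:\n  k = %d observed, %.3g expected by chance, p = %.3g\n",
    x$name1, x$m, x$name2, x$n, x$N, x$k, x$expected, x$p_value))
  invisible(x)
}

#' Tabulate overlap reports
#'
#' One row per comparison. Full numeric precision is retained; the print
#' method displays `expected` to 2 significant figures and `p_value` in
#' scientific notation with 3 significant digits.
#'
#' @param reports A list of [compute_overlap()] results (a single report
#'   is accepted).
#' @return A `data.frame` of class `enrichment_table` with columns
#'   `name1`, `name2`, `k`, `m`, `n`, `N`, `expected`, `p_value`.
#' @export
enrichment_table <- function(reports) {
  if (inherits(reports, "overlap_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("need at least one report", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "overlap_report")))
  out <- do.call(rbind, lapply(reports, function(r) {
    data.frame(name1 = r$name1, name2 = r$name2, k = r$k, m = r$m, n = r$n,
               N = r$N, expected = r$expected, p_value = r$p_value,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$expected <- signif(shown$expected, 2)
  shown$p_value <- sprintf("%.3g", shown$p_value)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' Tab-delimited, UTF-8, `.` decimal separator, full precision (numbers
#' serialized with 17 significant digits so the table round-trips
#' losslessly through [read_enrichment_table()]).
#'
#' @param table An [enrichment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  out <- as.data.frame(table)
  out$expected <- sprintf("%.17g", out$expected)
  out$p_value <- sprintf("%.17g", out$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an enrichment table written by [write_enrichment_table()]
#'
#' @param path Path to the TSV.
#' @return An `enrichment_table` data frame.
#' @export
read_enrichment_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(out) <- c("enrichment_table", "data.frame")
  out
}
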
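GO_NAMESPACES <- c("BP", "CC", "MF")
GO_CATEGORIES <- c("all", "BP", "CC", "MF")

normalize_namespace <- function(x) {
  up <- toupper(as.character(x))
  map <- c(
    "BP" = "BP", "P" = "BP", "BIOLOGICAL_PROCESS" = "BP",
    "CC" = "CC", "C" = "CC", "CELLULAR_COMPONENT" = "CC",
    "MF" = "MF", "F" = "MF", "MOLECULAR_FUNCTION" = "MF"
  )
  out <- unname(map[up])
  if (anyNA(out))
    stop("unknown GO namespace value(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Construct a gene-to-GO-term annotation map
#'
#' Stores gene/term pairs with each term tagged by one of the three GO
#' namespaces (biological process, cellular component, molecular
#' function). Term identifiers are opaque; no ancestor propagation over
#' the GO graph is performed — terms are used exactly as annotated.
#'
#' @param gene Character vector of gene identifiers.
#' @param term Character vector of term identifiers (same length).
#' @param namespace Namespace per annotation; accepts `BP`/`CC`/`MF`, GAF
#'   aspect codes `P`/`C`/`F`, or the long names.
#' @return Object of class `go_annotation`: a deduplicated data frame with
#'   columns `gene`, `term`, `namespace`.
#' @export
go_annotation <- function(gene, term, namespace) {
  stopifnot(length(gene) == length(term))
  if (length(namespace) == 1) namespace <- rep(namespace, length(gene))
  stopifnot(length(namespace) == length(gene))
  df <- data.frame(
    gene = as.character(gene),
    term = as.character(term),
    namespace = normalize_namespace(namespace),
    stringsAsFactors = FALSE
  )
  df <- unique(df)
  df <- df[order(df$gene, df$namespace, df$term), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("go_annotation", "data.frame")
  df
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf(
    "<go_annotation: %d annotations, %d genes, %d terms (BP %d / CC %d / MF %d)>\n",
    nrow(x), length(unique(x$gene)), length(unique(x$term)),
    sum(x$namespace == "BP"), sum(x$namespace == "CC"), sum(x$namespace == "MF")
  ))
  invisible(x)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Uses columns 2 (object identifier), 5 (GO term) and 9 (aspect,
#' `P`/`C`/`F`); `!` comment lines are skipped.
#'
#' @param path Path to the GAF file (uncompressed).
#' @return A [go_annotation()].
#' @export
read_gaf <- function(path) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  if (length(lines) == 0) stop("GAF file contains no annotation rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9)
  if (length(short) > 0)
    stop(sprintf("GAF file '%s': row %d has fewer than 9 columns", path, short[1]))
  go_annotation(
    gene = vapply(fields, `[[`, character(1), 2L),
    term = vapply(fields, `[[`, character(1), 5L),
    namespace = vapply(fields, `[[`, character(1), 9L)
  )
}

#' Read GO annotations from a gene/term TSV
#'
#' Expects two columns (gene, term — supply `namespace`) or three columns
#' (gene, term, namespace). `#` comments ignored; no header.
#'
#' @param path Path to the TSV file.
#' @param namespace Namespace used when the file has only two columns.
#' @return A [go_annotation()].
#' @export
read_go_tsv <- function(path, namespace = "BP") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(
    path, sep = "\t", header = FALSE, comment.char = "#",
    stringsAsFactors = FALSE, quote = ""
  )
  if (ncol(df) == 2) {
    go_annotation(df[[1]], df[[2]], namespace)
  } else if (ncol(df) >= 3) {
    go_annotation(df[[1]], df[[2]], df[[3]])
  } else {
    stop("annotation TSV must have 2 or 3 columns: ", path)
  }
}

# sparse binary incidence matrix (network nodes x terms) for one category
go_incidence <- function(net, ann, category = "all") {
  category <- match.arg(category, GO_CATEGORIES)
  sub <- if (category == "all") ann else ann[ann$namespace == category, , drop = FALSE]
  sub <- sub[sub$gene %in% net$nodes, , drop = FALSE]
  terms <- sort(unique(sub$term))
  n <- length(net$nodes)
  if (nrow(sub) == 0) {
    return(list(
      M = Matrix::sparseMatrix(
        i = integer(), j = integer(), x = numeric(),
        dims = c(n, 0), dimnames = list(net$nodes, character())
      ),
      terms = character()
    ))
  }
  M <- Matrix::sparseMatrix(
    i = match(sub$gene, net$nodes),
    j = match(sub$term, terms),
    x = 1,
    dims = c(n, length(terms)),
    dimnames = list(net$nodes, terms)
  )
  M@x[] <- 1   # collapse duplicates
  list(M = M, terms = terms)
}
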
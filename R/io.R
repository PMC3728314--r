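#' Read and write contact networks as delimited text
#'
#' Two dialects are supported. `"edgelist"` is delimited text with columns
#' `source`, `target`, `rate` (a header row is detected and skipped; `#`
#' lines are comments); node names may be arbitrary strings and are kept as
#' labels. `"matrix"` is a square delimited rate matrix, optionally with
#' row/column names. Recovery rates come from a separate two-column
#' `node<delim>rate` table, or a scalar default.
#'
#' `write_network()` followed by `read_network()` reproduces a network
#' exactly: rates are written with full (17 significant digit) precision.
#'
#' @param path File to read or write.
#' @param dialect `"edgelist"` or `"matrix"`.
#' @param delim Field delimiter, default tab.
#' @param recovery Either a scalar default recovery rate or the path to a
#'   two-column recovery table. Entries for unknown node labels are an
#'   error.
#' @param net A `contact_network`.
#' @param recovery_path Optional path for the recovery table written
#'   alongside the network file.
#' @return `read_network()` returns a `contact_network`; `write_network()`
#'   returns `net` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_network(complete_network(3, beta = 0.5), f)
#' read_network(f)
#' @export
read_network <- function(path, dialect = c("edgelist", "matrix"),
                         delim = "\t", recovery = 1) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) abort(sprintf("%s: no data lines found.", path))

  if (dialect == "edgelist") {
    parts <- strsplit(trimws(lines[rows]), delim, fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) {
      abort(sprintf("%s: line %d: expected 3 fields, found %d.",
                    path, rows[bad[1]], lengths(parts)[bad[1]]))
    }
    m <- do.call(rbind, parts)
    src <- m[, 1]; tgt <- m[, 2]
    rate <- suppressWarnings(as.numeric(m[, 3]))
    first <- 1L
    if (is.na(rate[1]) && nrow(m) > 1) first <- 2L  # header row
    bad <- which(is.na(rate[seq(first, length(rate))])) + first - 1L
    if (length(bad)) {
      abort(sprintf("%s: line %d: rate '%s' is not a number.",
                    path, rows[bad[1]], m[bad[1], 3]))
    }
    sel <- seq(first, nrow(m))
    src <- src[sel]; tgt <- tgt[sel]; rate <- rate[sel]
    lineno <- rows[sel]
    if (any(rate < 0)) {
      k <- which(rate < 0)[1]
      abort(sprintf("%s: line %d: negative rate %g.", path, lineno[k], rate[k]))
    }
    if (any(src == tgt)) {
      k <- which(src == tgt)[1]
      abort(sprintf("%s: line %d: self-loop on node '%s'.",
                    path, lineno[k], src[k]))
    }
    dup <- duplicated(paste(src, tgt, sep = "\r"))
    if (any(dup)) {
      k <- which(dup)[1]
      abort(sprintf("%s: line %d: duplicate edge %s -> %s.",
                    path, lineno[k], src[k], tgt[k]))
    }
    labels <- sort(unique(c(src, tgt)))
    edges <- tibble(from = src, to = tgt, rate = rate)
  } else {
    parts <- strsplit(trimws(lines[rows]), delim, fixed = TRUE)
    w <- lengths(parts)
    has_header <- anyNA(suppressWarnings(as.numeric(parts[[1]])))
    labels <- NULL
    if (has_header) {
      labels <- parts[[1]]
      parts <- parts[-1]
      rows <- rows[-1]
    }
    n <- length(parts)
    if (n == 0) abort(sprintf("%s: matrix has no rows.", path))
    mat <- matrix(0, n, n)
    for (k in seq_len(n)) {
      p <- parts[[k]]
      if (length(p) == n + 1) p <- p[-1]  # leading row name
      if (length(p) != n) {
        abort(sprintf("%s: line %d: expected %d numeric fields, found %d.",
                      path, rows[k], n, length(p)))
      }
      v <- suppressWarnings(as.numeric(p))
      if (anyNA(v)) {
        abort(sprintf("%s: line %d: non-numeric entry '%s'.",
                      path, rows[k], p[which(is.na(v))[1]]))
      }
      mat[k, ] <- v
    }
    if (is.null(labels)) labels <- as.character(seq_len(n))
    if (length(labels) == n + 1) labels <- labels[-1]
    if (length(labels) != n) {
      abort(sprintf("%s: header has %d labels for %d columns.",
                    path, length(labels), n))
    }
    if (any(diag(mat) != 0)) {
      abort(sprintf("%s: nonzero diagonal entry (self-loop) at node '%s'.",
                    path, labels[which(diag(mat) != 0)[1]]))
    }
    if (any(mat < 0)) abort(sprintf("%s: negative rate in matrix.", path))
    return(contact_network_from_matrix(
      mat, recovery = read_recovery(recovery, labels, delim), labels = labels
    ))
  }

  recovery <- read_recovery(recovery, labels, delim)
  contact_network(edges, recovery = recovery, nodes = labels)
}

read_recovery <- function(recovery, labels, delim) {
  if (is.numeric(recovery)) return(recovery)
  path <- recovery
  lines <- readr::read_lines(path)
  rows <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(trimws(lines[rows]), delim, fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("%s: line %d: expected 2 fields.", path, rows[bad[1]]))
  }
  m <- do.call(rbind, parts)
  rate <- suppressWarnings(as.numeric(m[, 2]))
  first <- 1L
  if (is.na(rate[1]) && nrow(m) > 1) first <- 2L
  sel <- seq(first, nrow(m))
  node <- m[sel, 1]; rate <- rate[sel]; lineno <- rows[sel]
  if (anyNA(rate)) {
    k <- which(is.na(rate))[1]
    abort(sprintf("%s: line %d: rate is not a number.", path, lineno[k]))
  }
  unknown <- !(node %in% labels)
  if (any(unknown)) {
    abort(sprintf("%s: line %d: unknown node label '%s' in recovery table.",
                  path, lineno[which(unknown)[1]], node[which(unknown)[1]]))
  }
  tibble(node = node, rate = rate)
}

#' @rdname read_network
#' @export
write_network <- function(net, path, dialect = c("edgelist", "matrix"),
                          delim = "\t", recovery_path = NULL) {
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (dialect == "edgelist") {
    ed <- tidy(net)
    lines <- c(
      paste("source", "target", "rate", sep = delim),
      paste(ed$from, ed$to, fmt(ed$rate), sep = delim)
    )
  } else {
    mat <- as.matrix(net$weights)
    body <- vapply(seq_len(net$n),
                   function(i) paste(fmt(mat[i, ]), collapse = delim),
                   character(1))
    # a label header is only written (and detectable) when labels are not
    # the default 1..n, which would be indistinguishable from data
    default_labels <- identical(net$labels, as.character(seq_len(net$n)))
    lines <- if (default_labels) body
             else c(paste(net$labels, collapse = delim), body)
  }
  readr::write_lines(lines, path)
  if (!is.null(recovery_path)) {
    readr::write_lines(
      c(paste("node", "rate", sep = delim),
        paste(net$labels, fmt(net$recovery), sep = delim)),
      recovery_path
    )
  }
  invisible(net)
}
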
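# Readers and writers for delimited morphometry tables, the FreeSurfer
# "stats" dialect, and directed network files.  All numeric output is
# written with 17 significant digits so write-then-read is lossless.

#' Read a morphometry table
#'
#' Reads a subjects-x-columns (or structures-x-columns) table in one of
#' three dialects.  For `freesurfer_stats`, lines beginning `#` are
#' metadata; only the column names declared on the `# ColHeaders` line are
#' honoured, and the remaining lines are whitespace-delimited records.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"tsv"` or `"freesurfer_stats"`.
#' @return a data.frame with resolved column names and type-converted
#'   columns.  The first column (subject or structure id) must be unique.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# Measure stuff", "# ColHeaders StructName Volume_mm3",
#'              "Left-Pallidum 2049.19"), f)
#' read_morphometry_table(f, "freesurfer_stats")
read_morphometry_table <- function(path,
                                   dialect = c("csv", "tsv",
                                               "freesurfer_stats")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop_fmt("format error: empty file: %s", path)
  }
  if (dialect %in% c("csv", "tsv")) {
    sep <- if (dialect == "csv") "," else "\t"
    tab <- utils::read.csv(path, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  } else {
    ch <- grep("^#\\s*ColHeaders\\b", lines)
    if (!length(ch)) {
      stop_fmt("format error: no '# ColHeaders' line in %s", path)
    }
    headers <- strsplit(trimws(sub("^#\\s*ColHeaders\\s*", "", lines[ch[1]])),
                        "\\s+")[[1]]
    if (!length(headers)) {
      stop_fmt("format error: '# ColHeaders' declares no columns (line %d)",
               ch[1])
    }
    body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    if (!length(body_idx)) {
      stop_fmt("format error: no data records in %s", path)
    }
    recs <- strsplit(trimws(lines[body_idx]), "\\s+")
    bad <- which(lengths(recs) != length(headers))
    if (length(bad)) {
      stop_fmt("format error: line %d has %d fields, ColHeaders declares %d",
               body_idx[bad[1]], lengths(recs)[bad[1]], length(headers))
    }
    tab <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
    names(tab) <- headers
    tab[] <- lapply(tab, function(col) {
      utils::type.convert(col, as.is = TRUE)
    })
  }
  if (anyDuplicated(tab[[1]])) {
    stop_fmt("uniqueness error: duplicate id(s) in first column: %s",
             paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  }
  tab
}

#' Write a morphometry table
#'
#' Writes `table` in the chosen dialect with full (17 significant digit)
#' numeric precision, so that reading it back reproduces the values exactly.
#'
#' @param table data.frame.
#' @param path output path.
#' @param dialect `"csv"`, `"tsv"` or `"freesurfer_stats"` (whitespace
#'   records under a `# ColHeaders` declaration).
#' @return `path`, invisibly.
#' @export
write_morphometry_table <- function(table, path,
                                    dialect = c("csv", "tsv",
                                                "freesurfer_stats")) {
  dialect <- match.arg(dialect)
  cols <- lapply(table, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  m <- do.call(cbind, cols)
  if (dialect %in% c("csv", "tsv")) {
    sep <- if (dialect == "csv") "," else "\t"
    out <- c(paste(names(table), collapse = sep),
             apply(m, 1, paste, collapse = sep))
  } else {
    out <- c("# Table written by cascnet",
             paste("# ColHeaders", paste(names(table), collapse = " ")),
             apply(m, 1, paste, collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

# Canonical "<Name>.<Hemisphere>" naming; FreeSurfer aseg-style labels use
# "Left-<Name>"/"Right-<Name>" prefixes instead.
#' Canonicalise FreeSurfer-style structure names
#'
#' Maps `Left-X`/`Right-X` to `X.L`/`X.R`; names already in canonical
#' `<Name>.<L|R>` form pass through unchanged.
#' @param x character vector of structure names.
#' @return character vector of canonical names.
#' @export
canonical_structure_name <- function(x) {
  out <- sub("^Left-(.+)$", "\\1.L", x)
  out <- sub("^Right-(.+)$", "\\1.R", out)
  out
}

#' Write a causal network to file
#'
#' Serialises a directed weighted network.  `edge_list` writes one line per
#' directed edge (`from to weight`) after a `# nodes:` header that preserves
#' isolated nodes; `graphml` writes GraphML with full-precision weights;
#' `dot` writes Graphviz DOT (write-only).
#'
#' @param network a `causal_network`.
#' @param path output path.
#' @param format `"graphml"`, `"dot"` or `"edge_list"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "dot", "edge_list")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "causal_network"))
  nodes <- network$nodes
  W <- network$weights
  ed <- which(!is.na(W) & W != 0, arr.ind = TRUE)
  if (format == "edge_list") {
    lines <- c(paste0("# nodes: ", paste(nodes, collapse = ",")),
               "# from\tto\tweight")
    if (nrow(ed)) {
      lines <- c(lines, sprintf("%s\t%s\t%s", nodes[ed[, 1]], nodes[ed[, 2]],
                                fmt_num(W[ed])))
    }
    writeLines(lines, path)
  } else if (format == "graphml") {
    esc <- function(s) {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      gsub(">", "&gt;", s, fixed = TRUE)
    }
    head <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="label" for="node" attr.name="name" attr.type="string"/>',
      '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
      '  <graph id="cascn" edgedefault="directed">')
    nl <- sprintf('    <node id="n%d"><data key="label">%s</data></node>',
                  seq_along(nodes) - 1L, esc(nodes))
    el <- if (nrow(ed)) {
      sprintf('    <edge source="n%d" target="n%d"><data key="w">%s</data></edge>',
              ed[, 1] - 1L, ed[, 2] - 1L, fmt_num(W[ed]))
    } else character(0)
    writeLines(c(head, nl, el, "  </graph>", "</graphml>"), path)
  } else {
    lines <- c("digraph cascn {")
    lines <- c(lines, sprintf('  "%s";', nodes))
    if (nrow(ed)) {
      lines <- c(lines, sprintf('  "%s" -> "%s" [weight=%s];',
                                nodes[ed[, 1]], nodes[ed[, 2]], fmt_num(W[ed])))
    }
    writeLines(c(lines, "}"), path)
  }
  invisible(path)
}

#' Read a causal network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge_list"` (`dot` is write-only and
#'   raises a usage error).
#' @return a `causal_network` with nodes and weight matrix restored to full
#'   stored precision (adjacency/degrees are not serialised; re-derive with
#'   [threshold_network()]).
#' @export
read_network <- function(path, format = c("graphml", "edge_list", "dot")) {
  format <- match.arg(format)
  if (format == "dot") {
    stop_fmt("usage error: dot is a write-only format")
  }
  if (format == "edge_list") {
    lines <- readLines(path, warn = FALSE)
    nline <- grep("^# nodes:", lines, value = TRUE)
    if (!length(nline)) stop_fmt("format error: missing '# nodes:' header")
    nodes <- strsplit(sub("^# nodes:\\s*", "", nline[1]), ",")[[1]]
    nodes <- nodes[nzchar(nodes)]
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    diag(W) <- NA
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    for (ln in body) {
      f <- strsplit(ln, "\t")[[1]]
      W[f[1], f[2]] <- as.numeric(f[3])
    }
    return(causal_network(nodes, W))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(W) <- NA
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el)) W[el] <- igraph::edge_attr(g, "weight")
  causal_network(nodes, W)
}
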
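# Readers and writers for the tool's plain-text formats: triplet TSV
# networks, newline-separated protein lists, protein-to-term annotation
# tables, alias maps, and JSON/CSV subgraph export.

.readLinesAny <- function(path) {
  # gzfile() transparently reads both plain and gzip-compressed text
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a network in triplet tab-delimited format
#'
#' Each data line is `proteinID1 <tab> proteinID2 <tab> score`. Lines
#' starting with `#` and blank lines are skipped. The file describes an
#' undirected network: `a b w` and `b a w` denote the same edge.
#' Gzip-compressed files are read transparently.
#'
#' @param path path to the file (optionally `.gz`).
#' @param name name to give the network (defaults to the file name).
#' @return a [WeightedNetwork].
#' @export
readTripletNetwork <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", .readLinesAny(path))
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0)
    stop("no data lines in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("malformed line ", lineno[which(nf != 3L)[1]], " in ", path,
         ": expected 3 tab-separated fields, found ", nf[nf != 3L][1])
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, `[`, character(1), 2L)
  wtxt <- trimws(vapply(parts, `[`, character(1), 3L))
  weight <- suppressWarnings(as.numeric(wtxt))
  if (anyNA(weight))
    stop("malformed line ", lineno[which(is.na(weight))[1]], " in ", path,
         ": weight '", wtxt[is.na(weight)][1], "' is not a number")
  if (any(weight < 0))
    stop("malformed line ", lineno[which(weight < 0)[1]], " in ", path,
         ": negative weights are not allowed")
  weightedNetwork(data.frame(from = from, to = to, weight = weight,
                             stringsAsFactors = FALSE), name = name)
}

#' Write a network in triplet tab-delimited format
#'
#' One line per edge, endpoints in lexicographic order, weights rendered
#' with full precision so that `readTripletNetwork(writeTripletNetwork(x))`
#' reproduces the edge set and weights exactly. Isolated vertices are listed
#' as `# vertex:` comment lines (ignored on read).
#'
#' @param network a [WeightedNetwork].
#' @param path output path; a path ending in `.gz` is gzip-compressed.
#' @return `path`, invisibly.
#' @export
writeTripletNetwork <- function(network, path) {
  et <- edgeTable(network)
  isolated <- setdiff(vertexIds(network), c(et$from, et$to))
  lines <- c(
    if (length(isolated)) paste0("# vertex: ", isolated),
    if (nrow(et)) sprintf("%s\t%s\t%.17g", et$from, et$to, et$weight))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  tryCatch(writeLines(lines, con), finally = close(con))
  invisible(path)
}

#' Read a newline-separated protein list
#'
#' One ID per non-blank line; surrounding whitespace is stripped, order is
#' preserved, duplicates are removed with a warning.
#'
#' @param path path to the file.
#' @return character vector of protein IDs.
#' @export
readProteinList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(.readLinesAny(path))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) stop("empty protein list: ", path)
  if (anyDuplicated(ids)) {
    warning("duplicate protein IDs removed from ", path)
    ids <- unique(ids)
  }
  ids
}

#' Read the positives of one term from a protein-to-term table
#'
#' Two-column tab-separated file (protein, term), no header. Returns the
#' distinct proteins annotated with exactly the requested term.
#'
#' @param path path to the two-column TSV.
#' @param term term identifier to select.
#' @return character vector of protein IDs.
#' @export
readTermAnnotations <- function(path, term) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    col.names = c("protein", "term"))
  hits <- unique(tab$protein[tab$term == term])
  if (length(hits) == 0)
    stop("term '", term, "' has no annotated proteins in ", path)
  hits
}

#' Read an alias map (foreign ID to canonical ID)
#'
#' Two-column tab-separated file, no header: foreign identifier (e.g. gene
#' symbol), canonical protein ID (e.g. Ensembl gene ID). Exact duplicate
#' rows are collapsed; a foreign ID mapped to two different canonical IDs is
#' an error.
#'
#' @param path path to the two-column TSV.
#' @return named character vector: `names()` are foreign IDs, values
#'   canonical IDs.
#' @export
readAliasMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- unique(read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("foreign", "canonical")))
  if (anyDuplicated(tab$foreign))
    stop("foreign ID(s) mapped to multiple canonical IDs: ",
         paste(unique(tab$foreign[duplicated(tab$foreign)]), collapse = ", "))
  setNames(tab$canonical, tab$foreign)
}

#' Translate a network's protein IDs through an alias map
#'
#' Every endpoint is replaced by its canonical ID. Edges with an unmapped
#' endpoint are dropped and reported — never silently lost. When the report
#' is empty, node and edge counts are preserved. Two foreign IDs mapping to
#' the same canonical ID can create self-pairs, which are dropped (zero
#' diagonal) and counted in the report.
#'
#' @param network a [WeightedNetwork] with foreign IDs.
#' @param aliasMap named character vector as returned by [readAliasMap()].
#' @return list with elements `network` (the mapped [WeightedNetwork]) and
#'   `report` (list: `unmapped` character vector, `droppedEdges` count,
#'   `selfLoops` count).
#' @export
applyAliasMap <- function(network, aliasMap) {
  ids <- vertexIds(network)
  mapped <- unname(aliasMap[ids])
  unmapped <- ids[is.na(mapped)]
  et <- edgeTable(network)
  ok <- !(et$from %in% unmapped) & !(et$to %in% unmapped)
  dropped <- sum(!ok)
  et <- et[ok, , drop = FALSE]
  from <- unname(aliasMap[et$from])
  to <- unname(aliasMap[et$to])
  loops <- from == to
  mappedVertices <- unique(mapped[!is.na(mapped)])
  net <- suppressWarnings(weightedNetwork(
    data.frame(from = from[!loops], to = to[!loops],
               weight = et$weight[!loops], stringsAsFactors = FALSE),
    vertices = mappedVertices, name = network@name))
  list(network = net,
       report = list(unmapped = unmapped, droppedEdges = dropped,
                     selfLoops = sum(loops)))
}

## ---- subgraph export ------------------------------------------------------

.exportTables <- function(subgraph, aliases = NULL) {
  stopifnot(is(subgraph, "NetworkSubgraph"))
  nd <- subgraph@nodeData
  aliasList <- lapply(nd$id, function(id) {
    a <- aliases[[id]]
    if (is.null(a)) character() else as.character(a)
  })
  nodes <- data.frame(id = nd$id, annotated = nd$annotated,
                      score = nd$phi, predicted = nd$predicted,
                      stringsAsFactors = FALSE)
  nodes$aliases <- aliasList
  ed <- subgraph@edges
  prov <- edgeProvenance(subgraph@parent)
  key <- paste(prov$from, prov$to, sep = "\t")
  idx <- match(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\t"),
               key)
  edges <- data.frame(source = ed$from, target = ed$to, weight = ed$weight,
                      stringsAsFactors = FALSE)
  edges$provenance <- lapply(idx, function(i)
    if (is.na(i)) character() else prov$sources[[i]])
  list(nodes = nodes, edges = edges)
}

#' Export a subgraph as JSON or CSV
#'
#' JSON: a single document with `nodes` and `edges` arrays; each node
#' carries `id`, `aliases`, `annotated`, `score`, `predicted`; each edge
#' carries `source`, `target`, `weight` and `provenance` (source network
#' names). CSV: an edge table (`source,target,weight,provenance` with
#' provenance semicolon-joined) and a node table
#' (`id,annotated,score,predicted`) written to `<stem>-edges.csv` and
#' `<stem>-nodes.csv`. Paths ending in `.gz` are gzip-compressed.
#'
#' @param subgraph a [NetworkSubgraph] (see [egoSubgraph()],
#'   [decorateSubgraph()]).
#' @param path output path; for CSV, the stem used to derive the two files.
#' @param format `"json"` or `"csv"`.
#' @param aliases optional named list mapping protein IDs to character
#'   vectors of alias identifiers.
#' @return invisibly, the path(s) written.
#' @export
exportSubgraph <- function(subgraph, path, format = c("json", "csv"),
                           aliases = NULL) {
  format <- match.arg(format)
  tabs <- .exportTables(subgraph, aliases)
  if (format == "json") {
    nodes <- lapply(seq_len(nrow(tabs$nodes)), function(i) list(
      id = tabs$nodes$id[i],
      aliases = as.list(tabs$nodes$aliases[[i]]),
      annotated = tabs$nodes$annotated[i],
      score = if (is.na(tabs$nodes$score[i])) NULL else tabs$nodes$score[i],
      predicted = if (is.na(tabs$nodes$predicted[i])) NULL
                  else tabs$nodes$predicted[i]))
    edges <- lapply(seq_len(nrow(tabs$edges)), function(i) list(
      source = tabs$edges$source[i],
      target = tabs$edges$target[i],
      weight = tabs$edges$weight[i],
      provenance = as.list(tabs$edges$provenance[[i]])))
    jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  stem <- sub("(\\.csv)?(\\.gz)?$", "", path)
  gz <- grepl("\\.gz$", path)
  ext <- if (gz) ".csv.gz" else ".csv"
  edgePath <- paste0(stem, "-edges", ext)
  nodePath <- paste0(stem, "-nodes", ext)
  ed <- tabs$edges
  ed$provenance <- vapply(ed$provenance, paste, character(1), collapse = ";")
  nd <- tabs$nodes[, c("id", "annotated", "score", "predicted")]
  writeCsv <- function(df, p) {
    con <- if (gz) gzfile(p, "wt") else file(p, "wt")
    tryCatch(write.table(df, con, sep = ",", row.names = FALSE,
                         quote = FALSE), finally = close(con))
  }
  writeCsv(ed, edgePath)
  writeCsv(nd, nodePath)
  invisible(c(edges = edgePath, nodes = nodePath))
}

#' Re-import a JSON subgraph export
#'
#' Inverse of [exportSubgraph()] with `format = "json"`: returns the node
#' and edge tables of the exported document (the in-memory exchange
#' representation, not the parent consensus object).
#'
#' @param path path to the JSON file.
#' @return list with data.frames `nodes` (`id`, `annotated`, `score`,
#'   `predicted`, list-column `aliases`) and `edges` (`source`, `target`,
#'   `weight`, list-column `provenance`).
#' @export
importSubgraphJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- data.frame(
    id = vapply(doc$nodes, function(n) n$id, character(1)),
    annotated = vapply(doc$nodes, function(n) isTRUE(n$annotated),
                       logical(1)),
    score = vapply(doc$nodes, function(n)
      if (is.null(n$score)) NA_real_ else as.numeric(n$score), numeric(1)),
    predicted = vapply(doc$nodes, function(n)
      if (is.null(n$predicted)) NA else isTRUE(n$predicted), logical(1)),
    stringsAsFactors = FALSE)
  nodes$aliases <- lapply(doc$nodes, function(n)
    as.character(unlist(n$aliases)))
  edges <- data.frame(
    source = vapply(doc$edges, function(e) e$source, character(1)),
    target = vapply(doc$edges, function(e) e$target, character(1)),
    weight = vapply(doc$edges, function(e) as.numeric(e$weight), numeric(1)),
    stringsAsFactors = FALSE)
  edges$provenance <- lapply(doc$edges, function(e)
    as.character(unlist(e$provenance)))
  list(nodes = nodes, edges = edges)
}
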
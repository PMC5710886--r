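# Readers and writers for the pipeline's file formats: expression TSV and
# the GEO series-matrix dialect, gene lists, GMT gene sets, neighbor-list
# tables, result tables, GraphML summary graphs and the JSON run summary.
# All tables are tab-delimited UTF-8 with a header row; general floating
# point is written with 6 significant digits, p-values in scientific
# notation with 6 digits.

fmtNum <- function(x) formatC(x, digits = 6, format = "g")
fmtP <- function(x) formatC(x, digits = 6, format = "e")

stopAtLine <- function(path, line, what) {
  stop("parse error in ", path, " at line ", line, ": ", what, call. = FALSE)
}

# Parse a tab-separated expression table given as raw lines (1-based line
# offsets for diagnostics refer to positions within `lines` plus `offset`).
parseExpressionLines <- function(lines, path, offset = 0L) {
  if (length(lines) < 2L) stopAtLine(path, offset + 1L, "no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- gsub('^"|"$', "", header[-1L])
  if (anyDuplicated(samples))
    stopAtLine(path, offset + 1L, "duplicate sample identifiers")
  ncol_exp <- length(header)
  genes <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, length(lines) - 1L, length(samples))
  for (r in seq_along(lines)[-1L]) {
    f <- fields[[r]]
    if (length(f) != ncol_exp)
      stopAtLine(path, offset + r,
                 paste0("expected ", ncol_exp, " fields, got ", length(f)))
    g <- gsub('^"|"$', "", f[1L])
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stopAtLine(path, offset + r, "non-numeric expression value")
    genes[r - 1L] <- g
    vals[r - 1L, ] <- v
  }
  dup <- which(duplicated(genes))
  if (length(dup))
    stopAtLine(path, offset + dup[1L] + 1L,
               paste0("duplicated gene id '", genes[dup[1L]], "'"))
  dimnames(vals) <- list(genes, samples)
  vals
}

# Extract the quoted payloads of a "!"-prefixed series-matrix metadata line.
seriesMatrixField <- function(lines, key) {
  hit <- grep(paste0("^!", key, "\\b"), lines, value = TRUE)
  if (length(hit) == 0L) return("")
  vals <- sub("^![^\t]*\t?", "", hit)
  paste(gsub('^"|"$', "", vals), collapse = " ")
}

#' Read an expression series from file
#'
#' Two dialects are supported. \code{"tsv"}: a tab-delimited table whose
#' first column holds gene identifiers and whose header row holds sample
#' identifiers. \code{"series_matrix"}: the GEO series-matrix layout —
#' "!"-prefixed metadata lines (title, summary and accession are captured),
#' with the expression table between the table-begin and table-end markers
#' and ID_REF as the gene column. Ragged rows, duplicate identifiers and
#' non-numeric cells raise an error naming the offending line.
#'
#' @param path file to read.
#' @param dialect "tsv" or "series_matrix".
#' @param seriesId identifier to assign; defaults to the accession for the
#'   series-matrix dialect and the base file name otherwise.
#' @return an \linkS4class{ExpressionSeries}.
#' @export
readExpression <- function(path, dialect = c("tsv", "series_matrix"),
                           seriesId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "tsv") {
    vals <- parseExpressionLines(lines, path)
    id <- if (is.null(seriesId))
      sub("\\.[^.]*$", "", basename(path)) else seriesId
    ExpressionSeries(id, vals)
  } else {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin)
      stop("series-matrix table markers missing or malformed in ", path)
    vals <- parseExpressionLines(lines[(begin + 1L):(end - 1L)], path,
                                 offset = begin)
    acc <- seriesMatrixField(lines, "Series_geo_accession")
    id <- if (!is.null(seriesId)) seriesId
          else if (nzchar(acc)) acc
          else sub("\\.[^.]*$", "", basename(path))
    ExpressionSeries(id, vals,
                     title = seriesMatrixField(lines, "Series_title"),
                     summary = seriesMatrixField(lines, "Series_summary"))
  }
}

#' Write an expression series as TSV
#'
#' @param series an \linkS4class{ExpressionSeries}.
#' @param path output file.
#' @export
writeExpression <- function(series, path) {
  m <- exprsMatrix(series)
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(r)
    paste(c(rownames(m)[r], sprintf("%.17g", m[r, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an expression series in the series-matrix dialect
#'
#' Emits the annotation as "!"-prefixed metadata lines followed by the
#' expression table between the standard table markers.
#'
#' @inheritParams writeExpression
#' @export
writeSeriesMatrix <- function(series, path) {
  m <- exprsMatrix(series)
  meta <- c(paste0("!Series_title\t\"", seriesTitle(series), "\""),
            paste0("!Series_geo_accession\t\"", seriesId(series), "\""),
            paste0("!Series_summary\t\"", seriesSummary(series), "\""))
  header <- paste(c("ID_REF", colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(r)
    paste(c(rownames(m)[r], sprintf("%.17g", m[r, ])), collapse = "\t"),
    character(1))
  writeLines(c(meta, "!series_matrix_table_begin", header, rows,
               "!series_matrix_table_end"), path)
  invisible(path)
}

#' Read / write a gene-list file (one identifier per line)
#'
#' @param path file path.
#' @return character vector of gene identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- trimws(readLines(path, warn = FALSE))
  g <- g[nzchar(g)]
  if (anyDuplicated(g)) stop("duplicate identifiers in ", path)
  g
}

#' @param genes character vector (or \linkS4class{GeneSignature}).
#' @rdname readGeneList
#' @export
writeGeneList <- function(genes, path) {
  if (is(genes, "GeneSignature")) genes <- signatureGenes(genes)
  writeLines(genes, path)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated as term id, description,
#' then member genes. Trailing empty fields are ignored; lines with fewer
#' than three fields or no members raise a parse error.
#'
#' @param path file path.
#' @return list of gene sets, each a list with \code{$termId},
#'   \code{$termName}, \code{$genes}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopAtLine(path, i, "GMT line needs term, description and members")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stopAtLine(path, i, "empty member list")
    list(termId = f[1L], termName = f[2L], genes = genes)
  })
}

#' @param annotations list of gene sets as returned by \code{readGmt}.
#' @rdname readGmt
#' @export
writeGmt <- function(annotations, path) {
  lines <- vapply(annotations, function(a)
    paste(c(a$termId, a$termName, a$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write neighbor-list tables
#'
#' Tab-delimited export of a co-expression query tool: columns query_gene,
#' neighbor_gene, support_count (number of series with observed
#' co-expression). The per-neighbor support stored on the matrix is the
#' median of the support counts across the queries that returned it.
#'
#' @param path file path.
#' @return a \linkS4class{NeighborMatrix}.
#' @export
readNeighborList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_gene", "neighbor_gene")
  if (!all(need %in% names(tab)))
    stop(path, " must have columns query_gene, neighbor_gene",
         " (and optionally support_count)")
  lists <- split(tab$neighbor_gene, factor(tab$query_gene,
                                           levels = unique(tab$query_gene)))
  support <- NULL
  if ("support_count" %in% names(tab)) {
    med <- tapply(tab$support_count, tab$neighbor_gene, stats::median)
    support <- stats::setNames(as.numeric(med), names(med))
  }
  buildNeighborMatrix(as.list(lists), support = support)
}

#' @param nm a \linkS4class{NeighborMatrix}.
#' @rdname readNeighborList
#' @export
writeNeighborList <- function(nm, path) {
  idx <- which(nm@m, arr.ind = TRUE)
  sup <- nm@support[idx[, 2L]]
  lines <- paste(nm@lGenes[idx[, 1L]], nm@neighbors[idx[, 2L]],
                 ifelse(is.na(sup), "NA", format(sup, trim = TRUE)),
                 sep = "\t")
  ord <- order(nm@lGenes[idx[, 1L]], nm@neighbors[idx[, 2L]])
  writeLines(c("query_gene\tneighbor_gene\tsupport_count", lines[ord]), path)
  invisible(path)
}

#' Write a collection scan result as TSV
#'
#' @param scanResult a \linkS4class{ScanResult}.
#' @param path output file.
#' @export
writeScanResult <- function(scanResult, path) {
  tab <- scanTable(scanResult)
  out <- data.frame(series_id = tab$seriesId, sample_i = tab$sampleI,
                    sample_j = tab$sampleJ, covered = tab$covered,
                    coverage = fmtNum(tab$coverage),
                    n_informative = tab$nInformative,
                    k_positive = tab$kPositive,
                    proportion = fmtNum(tab$proportion),
                    p_value = fmtP(tab$pValue),
                    holm_adjusted = fmtP(tab$holmAdjusted),
                    selected = tab$selected, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write differential-signature results
#'
#' \code{writeDEResult} writes the per-gene table (gene, t, p, direction,
#' selected); \code{writeRunSummary} writes a JSON summary with the tested
#' gene count, alpha, selected count and FDR estimate.
#'
#' @param deResult a \linkS4class{DEResult}.
#' @param path output file.
#' @export
writeDEResult <- function(deResult, path) {
  tab <- deTable(deResult)
  out <- data.frame(gene = tab$gene, t = fmtNum(tab$t), p = fmtP(tab$p),
                    direction = tab$direction, selected = tab$selected,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @export
writeRunSummary <- function(deResult, path) {
  jsonlite::write_json(
    list(tested_genes = deResult@testedCount, alpha = deResult@alpha,
         selected = sum(deResult@table$selected),
         fdr_estimate = deResult@fdrEstimate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an enrichment or term table as TSV
#'
#' @param tab data.frame from \code{\link{enrichList}} or
#'   \code{\link{significantTerms}}.
#' @param path output file.
#' @export
writeResultTable <- function(tab, path) {
  out <- tab
  for (col in names(out)) {
    if (!is.numeric(out[[col]])) next
    out[[col]] <- if (grepl("^(p|fdr|adj)", col, ignore.case = TRUE))
      fmtP(out[[col]]) else fmtNum(out[[col]])
  }
  int_cols <- names(tab)[vapply(tab, is.integer, logical(1))]
  for (col in int_cols) out[[col]] <- tab[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster membership as TSV
#'
#' @param clusters list of clusters (named by cluster id if available).
#' @param path output file.
#' @export
writeClusters <- function(clusters, path) {
  ids <- names(clusters)
  if (is.null(ids)) ids <- paste0("c", seq_along(clusters))
  rows <- unlist(lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    paste(cl$members, ids[i],
          cl$members %in% cl$lMembers, sep = "\t")
  }))
  writeLines(c("gene\tcluster_id\tis_L", rows), path)
  invisible(path)
}

#' Write / read a summary graph as GraphML
#'
#' Nodes carry size, signature-gene count and the semicolon-joined member
#' and signature-member lists; edges carry the connectivity value. The
#' reader reconstructs an equivalent \linkS4class{SummaryGraph}.
#'
#' @param graph a \linkS4class{SummaryGraph}.
#' @param path file path.
#' @export
writeSummaryGraph <- function(graph, path) {
  n <- nrow(graph@nodes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n) {
    igraph::V(g)$name <- graph@nodes$clusterId
    igraph::V(g)$size <- graph@nodes$size
    igraph::V(g)$lCount <- graph@nodes$lCount
    igraph::V(g)$members <- vapply(graph@clusters, function(cl)
      paste(cl$members, collapse = ";"), character(1))
    igraph::V(g)$lMembers <- vapply(graph@clusters, function(cl)
      paste(cl$lMembers, collapse = ";"), character(1))
  }
  if (nrow(graph@edges)) {
    g <- igraph::add_edges(
      g, rbind(match(graph@edges$from, graph@nodes$clusterId),
               match(graph@edges$to, graph@nodes$clusterId)))
    igraph::E(g)$connectivity <- graph@edges$connectivity
  }
  g <- igraph::set_graph_attr(g, "threshold", graph@threshold)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeSummaryGraph
#' @export
readSummaryGraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  ids <- if (n) igraph::V(g)$name else character(0)
  clusters <- lapply(seq_len(n), function(i) {
    mem <- strsplit(igraph::V(g)$members[i], ";", fixed = TRUE)[[1L]]
    lm <- igraph::V(g)$lMembers[i]
    lmem <- if (nzchar(lm)) strsplit(lm, ";", fixed = TRUE)[[1L]]
            else character(0)
    list(members = mem, lMembers = lmem)
  })
  names(clusters) <- ids
  nodes <- data.frame(clusterId = ids,
                      size = if (n) as.integer(igraph::V(g)$size) else integer(0),
                      lCount = if (n) as.integer(igraph::V(g)$lCount) else integer(0),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      connectivity = if (nrow(el))
                        igraph::E(g)$connectivity else numeric(0),
                      stringsAsFactors = FALSE)
  thr <- igraph::graph_attr(g, "threshold")
  new("SummaryGraph", clusters = clusters, nodes = nodes, edges = edges,
      threshold = if (is.null(thr)) 0 else as.numeric(thr))
}
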
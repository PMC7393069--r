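#' Read a UMI count matrix
#'
#' Reads either a 10x-style MatrixMarket triplet directory (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`, optionally gzipped) or a dense gene x cell
#' TSV with gene ids in the first column and cell ids in the header. A
#' `cell_meta.tsv` file in the same directory, if present, is attached as
#' per-cell metadata.
#'
#' @param path directory containing the triplet files, or path to a dense TSV.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    f <- function(base) {
      for (cand in file.path(path, c(base, paste0(base, ".gz"))))
        if (file.exists(cand)) return(cand)
      stopf("missing %s under %s", base, path)
    }
    mtx <- f("matrix.mtx")
    con <- if (grepl("\\.gz$", mtx)) gzfile(mtx) else file(mtx)
    m <- Matrix::readMM(con)
    genes <- read_id_column(f("features.tsv"))
    cells <- read_id_column(f("barcodes.tsv"))
    if (length(genes) != nrow(m))
      stopf("features.tsv has %d lines but matrix has %d rows",
            length(genes), nrow(m))
    if (length(cells) != ncol(m))
      stopf("barcodes.tsv has %d lines but matrix has %d columns",
            length(cells), ncol(m))
    meta <- NULL
    mf <- file.path(path, "cell_meta.tsv")
    if (file.exists(mf)) {
      meta <- read.table(mf, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
      rownames(meta) <- NULL
    }
    count_matrix(m, genes, cells, meta)
  } else if (file.exists(path)) {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    count_matrix(as.matrix(tab), rownames(tab), colnames(tab))
  } else stopf("no such file or directory: %s", path)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a UMI count matrix as a MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` (and `cell_meta.tsv`
#' when metadata is present) under `dir`. The round trip
#' `read_counts(write_counts(x, d))` reproduces `x` exactly.
#'
#' @param x a [count_matrix()] object.
#' @param dir output directory, created if needed.
#' @param gzip write gzip-compressed files.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir, gzip = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mtx <- file.path(dir, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(x$counts, tmp)
    writeLines(readLines(tmp), gzfile(mtx))
    unlink(tmp)
  } else Matrix::writeMM(x$counts, mtx)
  wl <- function(txt, base) {
    p <- file.path(dir, paste0(base, ext))
    con <- if (gzip) gzfile(p) else file(p)
    writeLines(txt, con)
    close(con)
  }
  wl(x$gene_ids, "features.tsv")
  wl(x$cell_ids, "barcodes.tsv")
  if (ncol(x$cell_meta) > 0)
    write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: set name, description, then gene ids. Empty lines are
#' skipped; duplicate genes within a set are dropped; duplicate set names are
#' an error.
#'
#' @param path GMT file path.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_sets(setNames(list(), character(0))))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stopf("GMT line %d has fewer than 2 fields", which(bad)[1])
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stopf("duplicate set name in GMT: %s", nms[duplicated(nms)][1])
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  gene_sets(setNames(sets, nms), desc)
}

#' Write a gene-set collection as GMT
#' @param sets a [gene_sets()] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)),
                                                   names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected interaction network from a two-column edge list
#'
#' Whitespace-separated gene pairs, one edge per line. Self-loops are dropped
#' with a warning; duplicate edges are collapsed.
#'
#' @param path edge-list file path.
#' @return An undirected simple `igraph` graph over gene ids.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- lengths(parts) < 2
  if (any(bad)) stopf("edge-list line %d has fewer than 2 columns",
                      which(bad)[1])
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  loops <- from == to
  if (any(loops)) {
    bec_log("io", sprintf("dropping %d self-loop(s) from edge list",
                          sum(loops)))
    warning(sprintf("%d self-loop(s) dropped", sum(loops)), call. = FALSE)
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::simplify(g)
}

#' Write a network as a two-column edge list
#' @param net an `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}
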
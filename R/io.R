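# Readers and writers for the package's interchange formats. All tabular
# files are TSV; writers prepend "#"-comment header lines carrying the tool
# version, a config fingerprint and the seed, and readers skip them.

file_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("gcnbench"))
  c(sprintf("# gcnbench %s", ver),
    if (!is.null(config)) sprintf("# config_hash %.0f",
                                  fnv1a32(paste(deparse(config), collapse = ""))),
    if (!is.null(seed)) sprintf("# seed %d", as.integer(seed)))
}

write_tsv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(seed = seed, config = config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' The on-disk shape is: first column `gene_id`, then one column per sample
#' (header row of sample ids). `read_expression` optionally joins a design
#' table (columns `sample_id`, `condition_id`, `replicate`).
#'
#' @param matrix genes x samples numeric matrix.
#' @param path output / input file path.
#' @param seed,config optional provenance recorded in the file header.
#' @return `write_expression` returns the path invisibly; `read_expression`
#'   returns a list with `expr` (matrix) and `design` (data.frame or NULL).
#' @export
write_expression <- function(matrix, path, seed = NULL, config = NULL) {
  check_expression(matrix)
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, seed = seed, config = config)
}

#' @param design_path optional design TSV path.
#' @rdname write_expression
#' @export
read_expression <- function(path, design_path = NULL) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in ", path, ": ", ids[duplicated(ids)][1])
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1]
    stop("non-numeric expression values in column ", names(df)[-1][bad],
         " of ", path)
  }
  rownames(vals) <- ids
  design <- if (!is.null(design_path)) read_design(design_path) else NULL
  if (!is.null(design)) {
    missing <- setdiff(colnames(vals), design$sample_id)
    if (length(missing)) {
      stop("samples absent from design: ", paste(missing, collapse = ", "))
    }
  }
  list(expr = structure(vals, class = c("expression_matrix", "matrix", "array")),
       design = design)
}

#' Write / read a sample design table
#' @param design data.frame `sample_id`, `condition_id`, `replicate`.
#' @inheritParams write_expression
#' @export
write_design <- function(design, path, seed = NULL) {
  write_tsv_with_header(design, path, seed = seed)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sample_id", "condition_id")
  if (!all(need %in% names(df))) {
    stop("design file must have columns sample_id, condition_id: ", path)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  df
}

#' Write / read a network
#'
#' Two formats: a weighted edge-list TSV (`gene_a`, `gene_b`, `weight`;
#' canonical lexicographic pair order for reproducible diffs) and GraphML
#' with a `weight` edge attribute (Cytoscape-compatible). Reading rejects
#' self-loops, duplicate edges and directed GraphML input.
#'
#' @param network a [gcn()] object.
#' @param path file path; format is inferred from the extension
#'   (`.graphml` vs anything else = edge-list TSV) unless `format` is given.
#' @param format `"edgelist_tsv"` or `"graphml"`.
#' @param seed,config optional provenance for the TSV header.
#' @return `write_network` returns the path invisibly; `read_network`
#'   returns a [gcn()].
#' @export
write_network <- function(network, path, format = NULL, seed = NULL,
                          config = NULL) {
  stopifnot(inherits(network, "gcn"))
  format <- format %||% (if (grepl("\\.graphml$", path)) "graphml" else "edgelist_tsv")
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    df <- stats::setNames(network$edges, c("gene_a", "gene_b", "weight"))
    write_tsv_with_header(df, path, seed = seed, config = config)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.graphml$", path)) "graphml" else "edgelist_tsv")
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::is_directed(g)) {
      stop("GraphML file contains directed edges; collapse it with ",
           "undirect_network() first: ", path)
    }
    el <- igraph::as_data_frame(g, what = "edges")
    w <- if ("weight" %in% names(el)) el$weight else 1
    edges <- data.frame(from = el$from, to = el$to, weight = w,
                        stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_checked(path)
    if (ncol(df) < 2) stop("edge list needs at least two columns: ", path)
    edges <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                        weight = if (ncol(df) >= 3) as.numeric(df[[3]]) else 1,
                        stringsAsFactors = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-loop in ", path, " at row ",
         which(edges$from == edges$to)[1])
  }
  key <- edge_key(edges$from, edges$to)
  if (anyDuplicated(key)) {
    stop("duplicate edge in ", path, " at row ", which(duplicated(key))[1])
  }
  gcn(edges, method = "file")
}

#' Write / read a partition as TSV (gene, module_id)
#' @param partition a `gcn_partition`.
#' @param network the network the partition covers (needed to rebuild the
#'   partition object when reading).
#' @inheritParams write_expression
#' @export
write_partition <- function(partition, path, seed = NULL) {
  stopifnot(inherits(partition, "gcn_partition"))
  df <- data.frame(gene = names(partition$module_of),
                   module_id = unname(partition$module_of),
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, seed = seed)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, network) {
  df <- read_tsv_checked(path)
  if (!all(c("gene", "module_id") %in% names(df))) {
    stop("partition file must have columns gene, module_id: ", path)
  }
  mem <- stats::setNames(as.character(df$module_id), df$gene)
  as_partition(network, mem, method = "external")
}

#' Read annotations from a (gene, term) TSV or a GMT gene-set file
#'
#' @param path input path; GMT is assumed for a `.gmt` extension (one set
#'   per line: name, description, genes...), otherwise a two-column TSV.
#' @param universe optional gene universe.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, universe = NULL) {
  if (grepl("\\.gmt$", path)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    pairs <- do.call(rbind, lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
      data.frame(gene = f[-(1:2)], term = f[1], stringsAsFactors = FALSE)
    }))
  } else {
    df <- read_tsv_checked(path, header = FALSE)
    if (tolower(df[1, 1]) == "gene") df <- df[-1, , drop = FALSE]
    if (ncol(df) < 2) stop("annotation TSV needs columns gene, term: ", path)
    pairs <- data.frame(gene = as.character(df[[1]]),
                        term = as.character(df[[2]]), stringsAsFactors = FALSE)
  }
  annotation_table(pairs, universe = universe)
}

#' Write annotations as a (gene, term) TSV
#' @param annotations an [annotation_table()].
#' @inheritParams write_expression
#' @export
write_annotations <- function(annotations, path, seed = NULL) {
  stopifnot(inherits(annotations, "annotation_table"))
  pairs <- data.frame(
    gene = rep(names(annotations$gene2term), lengths(annotations$gene2term)),
    term = unlist(annotations$gene2term, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_with_header(pairs, path, seed = seed)
}

#' Read a directed regulatory network from a two/three-column TSV
#'
#' Expects the RegulonDB/SubtiWiki export shape: `regulator`, `target` and
#' an optional `sign` column. Duplicate directed edges are collapsed and
#' self-edges dropped.
#'
#' @param path input path.
#' @return A `regnet` object.
#' @export
read_regnet <- function(path) {
  df <- read_tsv_checked(path, header = FALSE)
  if (tolower(df[1, 1]) %in% c("regulator", "tf")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("regulatory network TSV needs >= 2 columns: ", path)
  edges <- data.frame(regulator = as.character(df[[1]]),
                      target = as.character(df[[2]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 3) edges$sign <- as.character(df[[3]])
  edges <- edges[edges$regulator != edges$target, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$regulator, edges$target, sep = "\r")), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$regulator, edges$target)))),
            class = "regnet")
}

# Strict TSV reading: skip "#" comments, error on empty or ragged input.
read_tsv_checked <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#")]
  raw <- raw[nzchar(raw)]
  if (!length(raw)) stop("empty file: ", path)
  fields <- lengths(strsplit(raw, "\t", fixed = TRUE))
  if (length(unique(fields)) > 1) {
    stop("ragged row in ", path, " at line ",
         which(fields != fields[1])[1])
  }
  utils::read.delim(text = paste(raw, collapse = "\n"), header = header,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
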
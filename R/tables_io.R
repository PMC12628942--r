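# Tab-delimited, UTF-8, '.'-decimal is the canonical dialect for every table
# this package reads or writes (QIIME-style orientation: taxa rows, sample
# columns). Transposed-looking count tables are rejected, never auto-fixed.

#' Read an ASV count table from TSV
#'
#' @param path TSV file; first column taxon ids, remaining columns one per
#'   sample with sample ids in the header.
#' @param domain domain tag applied to every row (`"bacteria"`, `"fungi"`,
#'   `"protist"` or `"nematode"`).
#' @return a [count_table].
#' @export
read_count_table <- function(path, domain) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("read_count_table: expected a taxon-id column plus >=1 sample column in ", path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("read_count_table: duplicate taxon id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "read_count_table: invalid cell '%s' at taxon '%s', sample '%s' (counts must be non-negative integers)",
      mat[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  rownames(num) <- ids
  count_table(num, domain)
}

#' Write an ASV count table as TSV
#'
#' @param x a [count_table].
#' @param path output file.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(taxon_id = taxon_ids(x), x$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata frame from TSV
#'
#' Validates the closed vocabularies for the climatic group and rainfall
#' treatment columns and coerces environmental columns to numeric. Unknown
#' extra columns are kept as numerics when possible, otherwise as character.
#'
#' @param path TSV file with a `sample_id` column.
#' @return a `data.frame` with one row per sample.
#' @export
read_sample_frame <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

validate_sample_frame <- function(df) {
  if (!"sample_id" %in% names(df))
    stop("sample frame: missing 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("sample frame: duplicate sample id(s)")
  if ("group" %in% names(df)) {
    bad <- setdiff(unique(df$group), CLIMATE_GROUPS)
    if (length(bad) > 0)
      stop("sample frame: unknown climatic group(s) ",
           paste(sprintf("'%s'", bad), collapse = ", "),
           "; allowed: ", paste(sprintf("'%s'", CLIMATE_GROUPS), collapse = ", "))
  }
  if ("treatment" %in% names(df)) {
    bad <- setdiff(unique(df$treatment), TREATMENTS)
    if (length(bad) > 0)
      stop("sample frame: unknown treatment(s) ",
           paste(sprintf("'%s'", bad), collapse = ", "),
           "; allowed: ", paste(sprintf("'%s'", TREATMENTS), collapse = ", "))
  }
  for (v in setdiff(names(df), c("sample_id", "group", "treatment"))) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    if (!all(is.na(num) & !is.na(df[[v]]))) df[[v]] <- num
  }
  df
}

#' Write a sample metadata frame as TSV
#' @param frame data.frame with a `sample_id` column.
#' @param path output file.
#' @export
write_sample_frame <- function(frame, path) {
  write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with a `taxon_id` column plus ranked lineage columns
#'   (e.g. kingdom...genus) and optionally a free-text `guild` column.
#'   Missing ranks stay as empty strings, never dropped.
#' @return data.frame keyed by unique `taxon_id`.
#' @export
read_taxonomy_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = NULL)
  if (!"taxon_id" %in% names(df))
    stop("taxonomy table: missing 'taxon_id' column")
  if (anyDuplicated(df$taxon_id))
    stop("taxonomy table: duplicate taxon id(s)")
  for (v in setdiff(names(df), "taxon_id")) {
    df[[v]] <- as.character(df[[v]])
    df[[v]][is.na(df[[v]])] <- ""
  }
  df
}

#' Write a taxonomy table as TSV
#' @param tax data.frame with a `taxon_id` column.
#' @param path output file.
#' @export
write_taxonomy_table <- function(tax, path) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a signed network with module and role annotations
#'
#' Writes three files sharing `prefix`: `<prefix>_edges.tsv` (source, target,
#' r, sign, q), `<prefix>_nodes.tsv` (node, domain, guild, module, Zi, Pi,
#' role) and `<prefix>.graphml` carrying the same attributes, Cytoscape-ready.
#'
#' @param net a signed network from [build_network()].
#' @param partition a [fast_greedy_partition()] result covering the nodes.
#' @param roles a role table from [zi_pi_roles()] covering the nodes.
#' @param prefix path prefix for the three output files.
#' @return invisibly, the character vector of files written.
#' @export
export_network <- function(net, partition, roles, prefix) {
  nodes <- igraph::V(net)$name
  missing_part <- setdiff(nodes, names(partition$membership))
  if (length(missing_part) > 0)
    stop("export_network: partition missing node(s): ",
         paste(missing_part, collapse = ", "))
  missing_role <- setdiff(nodes, roles$node)
  if (length(missing_role) > 0)
    stop("export_network: role table missing node(s): ",
         paste(missing_role, collapse = ", "))

  ed <- igraph::as_data_frame(net, what = "edges")
  edge_df <- data.frame(source = ed$from, target = ed$to,
                        r = ed$r, sign = ed$sign, q = ed$q)
  edge_path <- paste0(prefix, "_edges.tsv")
  write.table(edge_df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)

  ri <- roles[match(nodes, roles$node), ]
  guild <- if (!is.null(igraph::V(net)$guild)) igraph::V(net)$guild else rep("unknown", length(nodes))
  node_df <- data.frame(node = nodes,
                        domain = igraph::V(net)$domain,
                        guild = guild,
                        module = unname(partition$membership[nodes]),
                        Zi = ri$Zi, Pi = ri$Pi, role = ri$role)
  node_path <- paste0(prefix, "_nodes.tsv")
  write.table(node_df, node_path, sep = "\t", quote = FALSE, row.names = FALSE)

  g <- net
  igraph::V(g)$guild <- guild
  igraph::V(g)$module <- as.integer(node_df$module)
  igraph::V(g)$Zi <- node_df$Zi
  igraph::V(g)$Pi <- node_df$Pi
  igraph::V(g)$role <- node_df$role
  graphml_path <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml_path, format = "graphml")

  invisible(c(edges = edge_path, nodes = node_path, graphml = graphml_path))
}

#' Re-import a network exported by [export_network()]
#' @param path a `.graphml` file.
#' @return an igraph graph with the exported attributes.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
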
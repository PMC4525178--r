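EDGE_COLS <- c("source_cell", "target_cell", "ligand", "receptor",
               "ligand_tpm", "receptor_tpm", "weight")

as_edge_df <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(data.frame(source_cell = character(0), target_cell = character(0),
                      ligand = character(0), receptor = character(0),
                      ligand_tpm = numeric(0), receptor_tpm = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  missing <- setdiff(EDGE_COLS, names(df))
  if (length(missing) > 0L) {
    stop_ligrec("edge list missing column(s): ", paste(missing, collapse = ", "))
  }
  df[EDGE_COLS]
}

#' Write a cell-to-cell edge list
#'
#' Exports the weighted, directed cell-to-cell communication edges produced
#' by [build_edges()]. Three formats are supported: plain TSV (exactly the
#' seven edge columns), GraphML (nodes are cell types; each edge carries the
#' ligand, receptor, both TPM levels and the weight as attributes — suitable
#' for Cytoscape/Gephi), and JSON in the hive-view schema
#' `{"nodes": [{"name": ...}], "edges": [{source, target, ligand, receptor,
#' ligand_tpm, receptor_tpm, weight}]}`.
#'
#' @param edges Data.frame with columns source_cell, target_cell, ligand,
#'   receptor, ligand_tpm, receptor_tpm, weight.
#' @param path Output file path.
#' @param format One of "tsv", "graphml", "json".
#' @return The path, invisibly.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "graphml", "json")) {
  format <- match.arg(format)
  df <- as_edge_df(edges)
  if (format == "tsv") {
    write_tsv(df, path)
  } else if (format == "graphml") {
    nodes <- sort(unique(c(df$source_cell, df$target_cell)))
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    if (nrow(df) > 0L) {
      idx <- rbind(match(df$source_cell, nodes), match(df$target_cell, nodes))
      g <- igraph::add_edges(g, as.vector(idx),
                             ligand = df$ligand, receptor = df$receptor,
                             ligand_tpm = df$ligand_tpm,
                             receptor_tpm = df$receptor_tpm,
                             weight = df$weight)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    nodes <- sort(unique(c(df$source_cell, df$target_cell)))
    obj <- list(
      nodes = lapply(nodes, function(n) list(name = n)),
      edges = lapply(seq_len(nrow(df)), function(i) {
        list(source = df$source_cell[i], target = df$target_cell[i],
             ligand = df$ligand[i], receptor = df$receptor[i],
             ligand_tpm = df$ligand_tpm[i], receptor_tpm = df$receptor_tpm[i],
             weight = df$weight[i])
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cell-to-cell edge list
#'
#' Inverse of [write_edge_list()] for all three formats; round-tripping
#' preserves the node and edge multiset (TSV values to 6 significant digits).
#'
#' @param path Input file path.
#' @param format One of "tsv", "graphml", "json".
#' @return Data.frame with the seven canonical edge columns.
#' @export
read_edge_list <- function(path, format = c("tsv", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path, colClasses = c(rep("character", 4), rep("numeric", 3)))
    return(as_edge_df(df))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el) == 0L) return(as_edge_df(NULL))
    df <- data.frame(source_cell = el[, 1], target_cell = el[, 2],
                     ligand = igraph::edge_attr(g, "ligand"),
                     receptor = igraph::edge_attr(g, "receptor"),
                     ligand_tpm = igraph::edge_attr(g, "ligand_tpm"),
                     receptor_tpm = igraph::edge_attr(g, "receptor_tpm"),
                     weight = igraph::edge_attr(g, "weight"),
                     stringsAsFactors = FALSE)
    return(as_edge_df(df))
  }
  obj <- jsonlite::read_json(path)
  if (length(obj$edges) == 0L) return(as_edge_df(NULL))
  df <- do.call(rbind, lapply(obj$edges, function(e) {
    data.frame(source_cell = e$source, target_cell = e$target,
               ligand = e$ligand, receptor = e$receptor,
               ligand_tpm = as.numeric(e$ligand_tpm),
               receptor_tpm = as.numeric(e$receptor_tpm),
               weight = as.numeric(e$weight), stringsAsFactors = FALSE)
  }))
  as_edge_df(df)
}
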
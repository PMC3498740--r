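# Attributed biological networks: nodes with optional layout and per-node
# image references, edges with free-text interaction types. GML carries
# layout and arbitrary attributes; SIF and edge-list CSV are topology-only;
# SBML is consumed as topology with reaction-centric hyperedge expansion.

#' Construct an omics network
#'
#' @param nodes data.frame with columns `id`, `label`, and optionally `x`,
#'   `y`, `w`, `h`, `node_class`, `image_ref`.
#' @param edges data.frame with columns `source`, `target`, `interaction`
#'   (may be NULL for an edgeless network).
#' @param directed Logical.
#' @param source_format Format the network was read from (informational).
#' @param node_attrs,edge_attrs Optional lists (one named character vector
#'   per node/edge) of opaque attributes preserved through GML round-trips.
#' @return An object of class `omics_network`.
#' @export
omics_network <- function(nodes, edges = NULL, directed = TRUE,
                          source_format = "constructed",
                          node_attrs = NULL, edge_attrs = NULL) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (is.null(nodes$label)) nodes$label <- nodes$id
  for (col in c("x", "y", "w", "h")) {
    if (is.null(nodes[[col]])) nodes[[col]] <- NA_real_
    nodes[[col]] <- as.numeric(nodes[[col]])
  }
  if (is.null(nodes$node_class)) nodes$node_class <- ""
  if (is.null(nodes$image_ref)) nodes$image_ref <- NA_character_
  nodes$image_ref[!is.na(nodes$image_ref) & nodes$image_ref == ""] <- NA_character_
  nodes <- nodes[, c("id", "label", "x", "y", "w", "h", "node_class",
                     "image_ref")]
  rownames(nodes) <- NULL
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        interaction = character(0), stringsAsFactors = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$interaction)) edges$interaction <- ""
  edges$interaction <- as.character(edges$interaction)
  edges <- edges[, c("source", "target", "interaction")]
  rownames(edges) <- NULL
  dangle <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangle)) {
    stop("edge endpoint(s) missing from node set: ",
         paste(dangle, collapse = ", "))
  }
  if (is.null(node_attrs)) node_attrs <- rep(list(character(0)), nrow(nodes))
  if (is.null(edge_attrs)) edge_attrs <- rep(list(character(0)), nrow(edges))
  stopifnot(length(node_attrs) == nrow(nodes),
            length(edge_attrs) == nrow(edges))
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 source_format = source_format,
                 node_attrs = node_attrs, edge_attrs = edge_attrs),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat("Omics network (", x$source_format, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), if (x$directed) " directed" else " undirected",
      " edges\n", sep = "")
  n_img <- sum(!is.na(x$nodes$image_ref))
  if (n_img) cat("  nodes with attached images: ", n_img, "\n", sep = "")
  invisible(x)
}

#' Read a biological network file
#'
#' Supported dialects: `gml` (layout and attributes preserved), `sif`
#' (topology only, one interaction per line: `source  type  target ...`),
#' `edge_csv` (CSV with header `source,target,interaction`), and
#' `sbml_topology` (species become nodes; every reaction becomes an
#' intermediate process node with reactant-to-reaction and
#' reaction-to-product edges, plus `modifier` edges).
#'
#' @param path Network file.
#' @param format One of `"gml"`, `"sif"`, `"edge_csv"`, `"sbml_topology"`;
#'   guessed from the extension by default.
#' @return An [omics_network()].
#' @export
read_network <- function(path,
                         format = c("auto", "gml", "sif", "edge_csv",
                                    "sbml_topology")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", sif = "sif", csv = "edge_csv",
                     xml = , sbml = "sbml_topology",
                     stop("cannot guess network format from extension '",
                          ext, "'"))
  }
  switch(format,
         gml = read_gml(path),
         sif = .read_sif(path),
         edge_csv = .read_edge_csv(path),
         sbml_topology = .read_sbml_topology(path))
}

.net_from_edges <- function(edges, source_format) {
  ids <- unique(c(edges$source, edges$target))
  omics_network(data.frame(id = ids, label = ids, stringsAsFactors = FALSE),
                edges, directed = TRUE, source_format = source_format)
}

.read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  edges <- list()
  nodes <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) == 1) {         # isolated node
      nodes <- c(nodes, f)
    } else if (length(f) >= 3) {  # source type target [target...]
      for (t in f[3:length(f)]) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = f[1], target = t, interaction = f[2],
          stringsAsFactors = FALSE)
      }
    } else {
      stop("malformed SIF line ", i, ": '", lines[i], "'")
    }
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               interaction = character(0))
  ids <- unique(c(e$source, e$target, nodes))
  omics_network(data.frame(id = ids, label = ids, stringsAsFactors = FALSE),
                e, directed = TRUE, source_format = "sif")
}

.read_edge_csv <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  if (!all(c("source", "target") %in% names(tab))) {
    stop("edge CSV needs 'source' and 'target' columns; found: ",
         paste(names(tab), collapse = ", "))
  }
  if (is.null(tab$interaction)) tab$interaction <- ""
  .net_from_edges(tab[, c("source", "target", "interaction")], "edge_csv")
}

.read_sbml_topology <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(species, "id")
  sp_names <- xml2::xml_attr(species, "name")
  sp_names[is.na(sp_names)] <- sp_ids[is.na(sp_names)]
  reactions <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  nodes <- data.frame(id = sp_ids, label = sp_names,
                      node_class = "species", stringsAsFactors = FALSE)
  edges <- list()
  for (rx in reactions) {
    rid <- xml2::xml_attr(rx, "id")
    rnode <- paste0("rxn_", rid)
    nodes <- rbind(nodes, data.frame(id = rnode, label = rid,
                                     node_class = "process",
                                     stringsAsFactors = FALSE))
    ref <- function(xpath) xml2::xml_attr(
      xml2::xml_find_all(rx, xpath), "species")
    for (s in ref(".//listOfReactants/speciesReference")) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = s, target = rnode, interaction = "reactant")
    }
    for (s in ref(".//listOfProducts/speciesReference")) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = rnode, target = s, interaction = "product")
    }
    for (s in ref(".//listOfModifiers/modifierSpeciesReference")) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = s, target = rnode, interaction = "modifier")
    }
  }
  e <- if (length(edges)) do.call(rbind, edges) else NULL
  omics_network(nodes, e, directed = TRUE, source_format = "sbml_topology")
}

#' Write a network file
#'
#' GML output re-reads with identical topology, positions and attributes.
#' SIF output keeps topology only; writing a laid-out network to SIF warns
#' that layout is dropped.
#'
#' @param net An [omics_network()].
#' @param path Output file.
#' @param format `"gml"` or `"sif"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "gml", "sif")) {
  stopifnot(inherits(net, "omics_network"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "sif") "sif" else "gml"
  }
  if (format == "gml") return(write_gml(net, path))
  if (any(!is.na(net$nodes$x))) {
    warning("SIF cannot carry layout; node positions are dropped")
  }
  e <- net$edges
  lines <- character(0)
  if (nrow(e)) {
    inter <- ifelse(nzchar(e$interaction), e$interaction, "interacts")
    lines <- paste(e$source, inter, e$target, sep = "\t")
  }
  isolated <- setdiff(net$nodes$id, c(e$source, e$target))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Attach painted images to matching network nodes
#'
#' Identifier-based mapping: every node whose matching attribute equals a
#' manifest key receives that image as `image_ref` and is resized to the
#' image's aspect ratio; all other nodes are untouched. Idempotent.
#'
#' @param net An [omics_network()].
#' @param images Named character vector mapping gene ids to image paths, or
#'   a data.frame with columns `gene_id` and `path`.
#' @param match_attr Node attribute compared against manifest keys:
#'   `"label"` (default; network genes are usually display labels) or
#'   `"id"`.
#' @param case_fold If TRUE, match case-insensitively. Default FALSE:
#'   identifier equality is exact.
#' @param base_dir Directory against which relative manifest paths are
#'   resolved when reading image dimensions; the (relative) manifest path
#'   itself is what gets stored in `image_ref`, which keeps exported
#'   networks relocatable.
#' @return A list with `network` (updated) and `report`: matched node ids,
#'   unmatched node ids, and unused manifest keys.
#' @export
attach_images <- function(net, images, match_attr = c("label", "id"),
                          case_fold = FALSE, base_dir = NULL) {
  stopifnot(inherits(net, "omics_network"))
  match_attr <- match.arg(match_attr)
  if (is.data.frame(images)) {
    images <- stats::setNames(as.character(images$path),
                              as.character(images$gene_id))
  }
  if (anyDuplicated(names(images))) {
    stop("duplicate manifest key: ",
         paste(unique(names(images)[duplicated(names(images))]),
               collapse = ", "))
  }
  keys <- names(images)
  nodekey <- net$nodes[[match_attr]]
  cmp_keys <- if (case_fold) tolower(keys) else keys
  cmp_node <- if (case_fold) tolower(nodekey) else nodekey
  hit <- match(cmp_node, cmp_keys)
  matched <- which(!is.na(hit))
  for (i in matched) {
    p <- unname(images[hit[i]])
    net$nodes$image_ref[i] <- p
    if (!file.exists(p) && !is.null(base_dir)) p <- file.path(base_dir, p)
    if (file.exists(p)) {
      d <- dim(png::readPNG(p))
      w <- if (is.na(net$nodes$w[i]) || net$nodes$w[i] <= 0) 60 else
        net$nodes$w[i]
      net$nodes$h[i] <- round(w * d[1] / d[2], 6)
      net$nodes$w[i] <- w
    }
  }
  report <- list(
    matched = net$nodes$id[matched],
    unmatched_nodes = net$nodes$id[setdiff(seq_len(nrow(net$nodes)), matched)],
    unused_images = keys[setdiff(seq_along(keys), hit[matched])]
  )
  list(network = net, report = report)
}

#' Assign a grid layout to layout-less nodes
#'
#' Fallback for topology-only inputs (SIF, CSV, SBML): nodes are placed on
#' a row-major square-ish grid in their current order. Nodes that already
#' have positions keep them.
#'
#' @param net An [omics_network()].
#' @param cell Grid cell spacing in drawing units.
#' @param node_size Default node width/height for nodes without a size.
#' @return The network with complete positions.
#' @export
assign_grid_layout <- function(net, cell = 150, node_size = 60) {
  n <- nrow(net$nodes)
  ncol_grid <- ceiling(sqrt(n))
  missing <- which(is.na(net$nodes$x) | is.na(net$nodes$y))
  for (j in seq_along(missing)) {
    i <- missing[j]
    net$nodes$x[i] <- ((j - 1) %% ncol_grid) * cell + cell / 2
    net$nodes$y[i] <- ((j - 1) %/% ncol_grid) * cell + cell / 2
  }
  fix <- is.na(net$nodes$w) | net$nodes$w <= 0
  net$nodes$w[fix] <- node_size
  fix <- is.na(net$nodes$h) | net$nodes$h <= 0
  net$nodes$h[fix] <- node_size
  net
}
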
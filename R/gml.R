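# Minimal reader/writer for classic key-value GML with nested blocks.
# The `graphics [ x y w h ... ]` block carries node layout, which must
# survive round-trips; unknown keys are kept verbatim as opaque attributes
# so files exported by other network editors are not mangled.

.gml_tokenize <- function(text) {
  # Tokens: quoted strings, brackets, bare atoms. GML strings do not
  # contain escaped quotes in the files we target.
  pat <- "\"[^\"]*\"|\\[|\\]|[^\\s\\[\\]\"]+"
  m <- gregexpr(pat, text, perl = TRUE)
  regmatches(text, m)[[1]]
}

# Parse a token stream into a list of (key, value) pairs; values are
# character scalars or nested lists. Keys may repeat.
.gml_parse_block <- function(tokens, pos) {
  pairs <- list()
  keys <- character(0)
  while (pos <= length(tokens)) {
    tok <- tokens[pos]
    if (tok == "]") return(list(pairs = pairs, keys = keys, pos = pos + 1L))
    key <- tok
    pos <- pos + 1L
    if (pos > length(tokens)) stop("GML: dangling key '", key, "'")
    val <- tokens[pos]
    if (val == "[") {
      sub <- .gml_parse_block(tokens, pos + 1L)
      pairs[[length(pairs) + 1L]] <- sub
      pos <- sub$pos
    } else {
      if (startsWith(val, "\"")) val <- substr(val, 2, nchar(val) - 1L)
      pairs[[length(pairs) + 1L]] <- val
      pos <- pos + 1L
    }
    keys <- c(keys, key)
  }
  list(pairs = pairs, keys = keys, pos = pos)
}

# Safe lookup in a named character vector (`[[` errors on absent names).
.sget <- function(sc, key) {
  if (key %in% names(sc)) sc[[key]] else NULL
}

.gml_get <- function(block, key) {
  i <- which(block$keys == key)
  if (!length(i)) NULL else block$pairs[[i[1]]]
}

.gml_scalars <- function(block) {
  keep <- vapply(block$pairs, is.character, TRUE)
  stats::setNames(unlist(block$pairs[keep], use.names = FALSE),
                  block$keys[keep])
}

read_gml <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  tokens <- .gml_tokenize(text)
  top <- .gml_parse_block(tokens, 1L)
  gi <- which(top$keys == "graph")
  if (!length(gi)) stop("GML: no 'graph' block in ", path)
  graph <- top$pairs[[gi[1]]]
  directed <- identical(.gml_get(graph, "directed"), "1")

  node_blocks <- graph$pairs[graph$keys == "node"]
  edge_blocks <- graph$pairs[graph$keys == "edge"]

  nodes <- lapply(node_blocks, function(nb) {
    sc <- .gml_scalars(nb)
    gml_id <- .sget(sc, "id")
    if (is.null(gml_id)) stop("GML: node without id")
    label <- .sget(sc, "label") %||% gml_id
    sid <- .sget(sc, "name") %||% label
    gfx <- .gml_get(nb, "graphics")
    x <- y <- w <- h <- NA_real_
    gattrs <- character(0)
    if (!is.null(gfx)) {
      gs <- .gml_scalars(gfx)
      x <- suppressWarnings(as.numeric(.sget(gs, "x") %||% NA))
      y <- suppressWarnings(as.numeric(.sget(gs, "y") %||% NA))
      w <- suppressWarnings(as.numeric(.sget(gs, "w") %||% NA))
      h <- suppressWarnings(as.numeric(.sget(gs, "h") %||% NA))
      rest <- gs[setdiff(names(gs), c("x", "y", "w", "h"))]
      if (length(rest)) {
        gattrs <- stats::setNames(unname(rest),
                                  paste0("graphics_", names(rest)))
      }
    }
    known <- c("id", "label", "name", "node_class", "image_ref")
    extra <- sc[setdiff(names(sc), known)]
    list(gml_id = gml_id, id = sid, label = label,
         node_class = .sget(sc, "node_class") %||% "",
         image_ref = .sget(sc, "image_ref") %||% NA_character_,
         x = x, y = y, w = w, h = h,
         attrs = c(extra, gattrs))
  })
  gml_ids <- vapply(nodes, function(n) n$gml_id, "")
  ids <- vapply(nodes, function(n) n$id, "")

  edges <- lapply(edge_blocks, function(eb) {
    sc <- .gml_scalars(eb)
    s <- match(.sget(sc, "source"), gml_ids)
    t <- match(.sget(sc, "target"), gml_ids)
    if (!length(s) || is.na(s)) stop("GML: edge refers to missing node id ", .sget(sc, "source"))
    if (!length(t) || is.na(t)) stop("GML: edge refers to missing node id ", .sget(sc, "target"))
    inter <- .sget(sc, "interaction") %||% .sget(sc, "label") %||% ""
    extra <- sc[setdiff(names(sc), c("source", "target", "interaction",
                                     "label"))]
    list(source = ids[s], target = ids[t], interaction = inter, attrs = extra)
  })

  omics_network(
    nodes = data.frame(
      id = ids,
      label = vapply(nodes, function(n) n$label, ""),
      x = vapply(nodes, function(n) n$x, 0),
      y = vapply(nodes, function(n) n$y, 0),
      w = vapply(nodes, function(n) n$w, 0),
      h = vapply(nodes, function(n) n$h, 0),
      node_class = vapply(nodes, function(n) n$node_class, ""),
      image_ref = vapply(nodes, function(n) n$image_ref, ""),
      stringsAsFactors = FALSE),
    edges = if (length(edges)) data.frame(
      source = vapply(edges, function(e) e$source, ""),
      target = vapply(edges, function(e) e$target, ""),
      interaction = vapply(edges, function(e) e$interaction, ""),
      stringsAsFactors = FALSE) else NULL,
    directed = directed,
    source_format = "gml",
    node_attrs = lapply(nodes, function(n) n$attrs),
    edge_attrs = lapply(edges, function(e) e$attrs)
  )
}

.gml_value <- function(v) {
  if (grepl("^-?[0-9]+(\\.[0-9]+)?$", v)) v else paste0("\"", v, "\"")
}

.gml_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 10)
}

write_gml <- function(net, path) {
  n <- net$nodes
  con <- file(path, "w")
  on.exit(close(con))
  out <- c("graph [", paste0("  directed ", as.integer(net$directed)))
  for (i in seq_len(nrow(n))) {
    lines <- c("  node [",
               paste0("    id ", i - 1L),
               paste0("    label \"", n$label[i], "\""),
               paste0("    name \"", n$id[i], "\""))
    if (nzchar(n$node_class[i])) {
      lines <- c(lines, paste0("    node_class \"", n$node_class[i], "\""))
    }
    if (!is.na(n$image_ref[i]) && nzchar(n$image_ref[i])) {
      lines <- c(lines, paste0("    image_ref \"", n$image_ref[i], "\""))
    }
    attrs <- net$node_attrs[[i]]
    gfx_keys <- grep("^graphics_", names(attrs), value = TRUE)
    plain <- attrs[setdiff(names(attrs), gfx_keys)]
    for (k in names(plain)) {
      lines <- c(lines, paste0("    ", k, " ", .gml_value(plain[[k]])))
    }
    if (!is.na(n$x[i])) {
      g <- c(paste0("      x ", .gml_num(n$x[i])),
             paste0("      y ", .gml_num(n$y[i])),
             paste0("      w ", .gml_num(n$w[i])),
             paste0("      h ", .gml_num(n$h[i])))
      for (k in gfx_keys) {
        g <- c(g, paste0("      ", sub("^graphics_", "", k), " ",
                         .gml_value(attrs[[k]])))
      }
      lines <- c(lines, "    graphics [", g, "    ]")
    }
    out <- c(out, lines, "  ]")
  }
  e <- net$edges
  idx <- match(e$source, n$id)
  tdx <- match(e$target, n$id)
  for (i in seq_len(nrow(e))) {
    lines <- c("  edge [",
               paste0("    source ", idx[i] - 1L),
               paste0("    target ", tdx[i] - 1L),
               paste0("    interaction \"", e$interaction[i], "\""))
    attrs <- net$edge_attrs[[i]]
    for (k in names(attrs)) {
      lines <- c(lines, paste0("    ", k, " ", .gml_value(attrs[[k]])))
    }
    out <- c(out, lines, "  ]")
  }
  out <- c(out, "]")
  writeLines(out, con)
  invisible(path)
}
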
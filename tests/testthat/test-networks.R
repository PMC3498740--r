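# Network formats, round-trips, and identifier-based image mapping.

test_that("a single SIF line yields two nodes and one labeled edge", {
  path <- tempfile(fileext = ".sif")
  writeLines("LFY\tactivation\tAP1", path)
  net <- read_network(path)
  expect_equal(sort(net$nodes$id), c("AP1", "LFY"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$interaction, "activation")
  expect_true(net$directed)
  # multi-target SIF line expands to one edge per target
  writeLines(c("A pp B C D", "E"), path)
  net2 <- read_network(path)
  expect_equal(nrow(net2$edges), 3L)
  expect_true("E" %in% net2$nodes$id)       # isolated node kept
  writeLines("A pp", path)
  expect_error(read_network(path), "malformed SIF line 1")
})

test_that("edge-list CSV parses topology with interaction column", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("source,target,interaction", "LEC1,FUS3,activation",
               "FUS3,FUS3,activation"), path)
  net <- read_network(path)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(sum(net$edges$source == net$edges$target), 1L)  # self-loop
  writeLines(c("from,to", "a,b"), path)
  expect_error(read_network(path, "edge_csv"), "source.*target")
})

test_that("SBML topology expands reactions into process nodes", {
  path <- tempfile(fileext = ".sbml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="s1" name="Glc"/><species id="s2" name="G6P"/>',
    '<species id="s3" name="HXK"/>',
    '</listOfSpecies><listOfReactions><reaction id="r1">',
    '<listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="s2"/></listOfProducts>',
    '<listOfModifiers><modifierSpeciesReference species="s3"/></listOfModifiers>',
    '</reaction></listOfReactions></model></sbml>'), path)
  net <- read_network(path)
  expect_equal(nrow(net$nodes), 4L)           # 3 species + 1 process node
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$edges$interaction, c("reactant", "product", "modifier"))
  expect_equal(net$nodes$node_class[net$nodes$id == "rxn_r1"], "process")
})

test_that("GML round-trips topology, layout and opaque attributes", {
  gml <- tempfile(fileext = ".gml")
  writeLines(c(
    "graph [", "  directed 1",
    '  node [ id 0 label "AP1" sbgn_class "macromolecule"',
    "    graphics [ x 10 y 20 w 40 h 30 fill \"#CCCCFF\" ] ]",
    '  node [ id 1 label "LFY" graphics [ x 50 y 60 w 40 h 30 ] ]',
    '  node [ id 2 label "AG" ]',
    '  edge [ source 1 target 0 interaction "activation" weight 2 ]',
    '  edge [ source 0 target 2 interaction "inhibition" ]',
    "]"), gml)
  net <- read_network(gml)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$nodes$x[net$nodes$label == "AP1"], 10)
  expect_equal(net$node_attrs[[1]][["sbgn_class"]], "macromolecule")
  expect_equal(net$node_attrs[[1]][["graphics_fill"]], "#CCCCFF")
  expect_equal(net$edge_attrs[[1]][["weight"]], "2")

  out <- tempfile(fileext = ".gml")
  write_network(net, out, "gml")
  net2 <- read_network(out)
  expect_equal(net2$nodes, net$nodes)
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$node_attrs[[1]][["sbgn_class"]], "macromolecule")
  expect_equal(net2$node_attrs[[1]][["graphics_fill"]], "#CCCCFF")
  expect_equal(net2$edge_attrs[[1]][["weight"]], "2")

  # dangling edge is a parse error naming the missing node
  writeLines(c("graph [", '  node [ id 0 label "A" ]',
               "  edge [ source 0 target 9 ]", "]"), gml)
  expect_error(read_network(gml), "missing node id 9")
})

test_that("written GML agrees with igraph's independent GML reader", {
  skip_if_not_installed("igraph")
  spec <- fixture_spec(seed = 3, n_genes = 8, n_tissues = 2)
  net <- make_network(spec, sprintf("g%d", 1:8))
  path <- tempfile(fileext = ".gml")
  write_network(net, path, "gml")
  # igraph ignores the nested graphics block (that is why the package has
  # its own GML reader); the topology comparison is what matters here
  ig <- suppressWarnings(igraph::read_graph(path, format = "gml"))
  expect_equal(igraph::vcount(ig), nrow(net$nodes))
  expect_equal(igraph::ecount(ig), nrow(net$edges))
  expect_true(igraph::is_directed(ig))
  expect_setequal(igraph::V(ig)$label, net$nodes$label)
})

test_that("random generated networks survive write/read (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:20, 1)
    ids <- sprintf("N%02d", seq_len(n))
    m <- sample(1:(2 * n), 1)
    edges <- data.frame(source = sample(ids, m, TRUE),
                        target = sample(ids, m, TRUE),
                        interaction = sample(c("activation", "inhibition",
                                               "pp"), m, TRUE))
    edges <- unique(edges)
    net <- assign_grid_layout(omics_network(
      data.frame(id = ids, label = ids), edges))
    path <- tempfile(fileext = ".gml")
    write_network(net, path)
    back <- read_network(path)
    expect_equal(back$nodes, net$nodes)
    expect_equal(back$edges, net$edges)
  }
})

test_that("SIF export drops layout with a warning and keeps topology", {
  net <- assign_grid_layout(omics_network(
    data.frame(id = c("A", "B", "C")),
    data.frame(source = "A", target = "B", interaction = "activation")))
  path <- tempfile(fileext = ".sif")
  expect_warning(write_network(net, path, "sif"), "layout")
  back <- read_network(path)
  expect_setequal(back$nodes$id, c("A", "B", "C"))  # isolated C preserved
  expect_equal(nrow(back$edges), 1L)
})

test_that("attach_images maps by identifier with optional case folding", {
  d <- withr::local_tempdir()
  img <- file.path(d, "AP1.png")
  write_raster(atlaspaint:::new_raster(20L, 10L), img)   # 20 wide, 10 high
  net <- omics_network(data.frame(id = c("n1", "n2", "n3"),
                                  label = c("AP1", "LFY", "X")))
  res <- attach_images(net, c(AP1 = img, LFY = img))
  expect_setequal(res$report$matched, c("n1", "n2"))
  expect_equal(res$report$unmatched_nodes, "n3")
  expect_equal(length(res$report$unused_images), 0L)
  # counts are conserved
  expect_equal(length(res$report$matched) +
                 length(res$report$unmatched_nodes), nrow(net$nodes))
  # node resized to the image aspect ratio (h = w * 10/20)
  n1 <- res$network$nodes[res$network$nodes$id == "n1", ]
  expect_equal(n1$h / n1$w, 0.5)
  # idempotence
  res2 <- attach_images(res$network, c(AP1 = img, LFY = img))
  expect_equal(res2$network, res$network)
  # empty manifest: identity
  res3 <- attach_images(net, character(0))
  expect_equal(res3$network$nodes, net$nodes)
  # case folding
  netl <- omics_network(data.frame(id = "x", label = "ap1"))
  expect_equal(length(attach_images(netl, c(AP1 = img))$report$matched), 0L)
  expect_equal(attach_images(netl, c(AP1 = img),
                             case_fold = TRUE)$report$matched, "x")
  # match on id instead of label
  netid <- omics_network(data.frame(id = "AP1", label = "pretty name"))
  expect_equal(attach_images(netid, c(AP1 = img),
                             match_attr = "id")$report$matched, "AP1")
  expect_error(attach_images(net, c(AP1 = img, AP1 = img)),
               "duplicate manifest key")
})

test_that("generated fixture network has hub, cycle, self-loop over genes", {
  spec <- fixture_spec(seed = 9, n_genes = 5, n_tissues = 2)
  genes <- sprintf("G%d", 1:5)
  net <- make_network(spec, genes)
  e <- net$edges
  hub <- "G1"
  expect_equal(sum(e$source == hub & e$target != hub), 4L)  # out-degree 4
  expect_true(any(e$source == e$target))                    # self-loop
  expect_true(all(net$nodes$id %in% genes))
  # every node id in the dataset gene set => full match in attach_images
  d <- withr::local_tempdir()
  img <- file.path(d, "g.png")
  write_raster(atlaspaint:::new_raster(5L, 5L), img)
  manifest <- stats::setNames(rep(img, length(genes)), genes)
  res <- attach_images(net, manifest)
  expect_equal(length(res$report$unmatched_nodes), 0L)
})
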
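# Welfare ontology: bipartite needs-parameter graph, selection, export.

test_that("packaged ontology carries the fourteen needs and the model parameters", {
  ont <- default_ontology()
  expect_equal(nrow(ont$needs), 14L)
  expect_true(all(c("respiration", "nutrition", "safety", "reproduction")
                  %in% ont$needs$id))
  # excerpt wiring: respiration and nutrition each show five parameters
  expect_equal(node_degree(ont, "respiration"), 5L)
  expect_equal(node_degree(ont, "nutrition"), 5L)
  expect_equal(node_degree(ont, "safety"), 0L)  # isolated in the excerpt
  expect_error(node_degree(ont, "telepathy"), "unknown ontology node")
})

test_that("criteria selection admits exactly the model parameters", {
  ont <- default_ontology()
  sel <- select_parameters(ont, c("relevant", "practicable", "reliable"))
  expect_equal(nrow(sel), 80L)
  expect_false(any(c("vsi", "hematocrit") %in% sel$id))
  expect_setequal(sel$id, names(default_model_config()$parameters))
  # vacuous filter returns everything, including the excluded examples
  expect_equal(nrow(select_parameters(ont, character())), 82L)
  # selected parameters all carry a module assignment
  expect_false(any(is.na(sel$module)))
})

test_that("selection equals a brute-force filter on random criteria", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 30L
    pars <- data.frame(id = sprintf("p%02d", 1:n), name = "x",
                       relevant = sample(c(TRUE, FALSE), n, TRUE),
                       practicable = sample(c(TRUE, FALSE), n, TRUE),
                       reliable = sample(c(TRUE, FALSE), n, TRUE),
                       module = NA_character_, stringsAsFactors = FALSE)
    g <- ontology_graph(data.frame(id = "n1", name = "N",
                                   description = "d"),
                        pars, NULL)
    req <- sample(c("relevant", "practicable", "reliable"),
                  sample(0:3, 1))
    got <- select_parameters(g, req)$id
    want <- pars$id
    for (cr in req) want <- want[pars[[cr]][match(want, pars$id)]]
    expect_setequal(got, want)
  }
})

test_that("degree equals a brute-force filter of the triple list", {
  set.seed(7)
  needs <- data.frame(id = sprintf("n%d", 1:5), name = "N",
                      description = "d", stringsAsFactors = FALSE)
  pars <- data.frame(id = sprintf("p%d", 1:12), name = "P",
                     relevant = TRUE, practicable = TRUE, reliable = TRUE,
                     module = NA_character_, stringsAsFactors = FALSE)
  pairs <- expand.grid(need = needs$id, parameter = pars$id,
                       stringsAsFactors = FALSE)
  tr <- pairs[sample(nrow(pairs), 25), ]
  tr$relation <- sample(c("affects", "affected_by", "both"), 25, TRUE)
  g <- ontology_graph(needs, pars, tr)
  for (id in c(needs$id, pars$id)) {
    want <- sum(tr$need == id) + sum(tr$parameter == id)
    expect_equal(node_degree(g, id), want, info = id)
  }
})

test_that("ontology validation enforces referential integrity and bipartiteness", {
  needs <- data.frame(id = "resp", name = "Respiration", description = "d",
                      stringsAsFactors = FALSE)
  pars <- data.frame(id = "tan", name = "TAN", relevant = TRUE,
                     practicable = TRUE, reliable = TRUE,
                     module = NA_character_, stringsAsFactors = FALSE)
  ok <- ontology_graph(needs, pars, NULL)     # zero edges is fine
  expect_equal(nrow(ok$triples), 0L)

  expect_error(ontology_graph(needs, pars, data.frame(
    need = "ghost", parameter = "tan", relation = "affects")),
    "undefined need")
  expect_error(ontology_graph(needs, pars, data.frame(
    need = c("resp", "resp"), parameter = c("tan", "tan"),
    relation = c("affects", "both"))),
    "duplicate triple")
  expect_error(ontology_graph(needs, pars, data.frame(
    need = "resp", parameter = "tan", relation = "causes")),
    "unknown relation")
  pars2 <- pars; pars2$id <- "resp"
  expect_error(ontology_graph(needs, pars2, NULL), "bipartite")
  pars3 <- pars; pars3$module <- "W"; pars3$practicable <- FALSE
  expect_error(ontology_graph(needs, pars3, NULL),
               "fails a selection criterion")
})

test_that("GraphML export preserves nodes, edges and attributes", {
  ont <- default_ontology()
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(ont, path, format = "graphml")
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(ont$needs) + nrow(ont$parameters))
  expect_equal(igraph::ecount(ig), nrow(ont$triples))
  types <- igraph::vertex_attr(ig, "type")
  expect_equal(sum(types == "need"), nrow(ont$needs))
  expect_setequal(igraph::edge_attr(ig, "relation"), ont$triples$relation)
})

test_that("JSON export/import round trip reproduces the graph", {
  ont <- default_ontology()
  path <- withr::local_tempfile(fileext = ".json")
  export_graph(ont, path, format = "json")
  back <- load_ontology(path)
  expect_equal(back$needs, ont$needs)
  expect_equal(back$parameters, ont$parameters)
  expect_equal(back$triples, ont$triples)
})
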
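# Welfare ontology: needs, parameters and their correlation triples.
#
# The ontology is a bipartite graph.  One side holds the fourteen
# fundamental welfare needs (respiration, osmotic regulation, ...); the
# other side holds measurable parameters.  A triple asserts a correlation
# between a need and a parameter ("affects", "affected_by" or "both");
# relationships among needs or among parameters are deliberately not
# represented.  Parameters carry three selection criteria — relevant
# (scientific evidence of a welfare correlation), practicable (measurable
# on-farm at reasonable cost) and reliable (results consistently relate to
# welfare) — and only parameters meeting all three are admitted into the
# scoring model.

RELATION_KINDS <- c("affects", "affected_by", "both")

#' Assemble a welfare ontology graph
#'
#' @param needs Data frame with columns `id`, `name`, `description`.
#' @param parameters Data frame with columns `id`, `name`, `relevant`,
#'   `practicable`, `reliable` and optional `module` (`NA` unless the
#'   parameter was selected into the scoring model).
#' @param triples Data frame with columns `need`, `parameter`, `relation`.
#' @param validate Check referential integrity and bipartiteness.
#'
#' @return A list of class `welfare_ontology`.
#' @export
ontology_graph <- function(needs, parameters, triples, validate = TRUE) {
  if (is.null(triples) || nrow(triples) == 0L)
    triples <- data.frame(need = character(), parameter = character(),
                          relation = character(), stringsAsFactors = FALSE)
  if (!"module" %in% names(parameters)) parameters$module <- NA_character_
  g <- structure(list(needs = needs, parameters = parameters,
                      triples = triples),
                 class = "welfare_ontology")
  if (validate) validate_ontology(g)
  g
}

validate_ontology <- function(g) {
  problems <- character()
  if (anyDuplicated(g$needs$id))
    problems <- c(problems, "duplicate need id")
  if (anyDuplicated(g$parameters$id))
    problems <- c(problems, "duplicate parameter id")
  if (length(intersect(g$needs$id, g$parameters$id)))
    problems <- c(problems, paste0(
      "id used for both a need and a parameter: '",
      intersect(g$needs$id, g$parameters$id)[1L],
      "' (the ontology is bipartite)"))
  tr <- g$triples
  bad_need <- setdiff(tr$need, g$needs$id)
  if (length(bad_need))
    problems <- c(problems, paste0("triple references undefined need '",
                                   bad_need[1L], "'"))
  bad_par <- setdiff(tr$parameter, g$parameters$id)
  if (length(bad_par))
    problems <- c(problems, paste0("triple references undefined parameter '",
                                   bad_par[1L], "'"))
  if (any(!tr$relation %in% RELATION_KINDS))
    problems <- c(problems, paste0(
      "unknown relation '", setdiff(tr$relation, RELATION_KINDS)[1L],
      "' (must be one of ", paste(RELATION_KINDS, collapse = ", "), ")"))
  if (anyDuplicated(tr[c("need", "parameter")]))
    problems <- c(problems, "duplicate triple for a (need, parameter) pair")
  sel <- g$parameters[!is.na(g$parameters$module), , drop = FALSE]
  not_ok <- sel$id[!(sel$relevant & sel$practicable & sel$reliable)]
  if (length(not_ok))
    problems <- c(problems, paste0(
      "parameter '", not_ok[1L],
      "' is assigned to a module but fails a selection criterion"))
  if (length(problems))
    stop("invalid ontology:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(g)
}

#' @export
print.welfare_ontology <- function(x, ...) {
  cat("<welfare_ontology>", nrow(x$needs), "needs,",
      nrow(x$parameters), "parameters,", nrow(x$triples), "triples\n")
  invisible(x)
}

#' Load a welfare ontology from a JSON triple file
#'
#' The file holds three arrays: `needs` (`id`, `name`, `description`),
#' `parameters` (`id`, `name`, the three criteria booleans, optional
#' `module`) and `triples` (`need`, `parameter`, `relation`).
#'
#' @param source Path to a JSON file, or JSON text.
#' @return A validated `welfare_ontology`.
#' @export
#' @examples
#' ont <- default_ontology()
#' nrow(ont$needs)  # 14
load_ontology <- function(source) {
  x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  chr_col <- function(rows, col) vapply(rows, function(r) {
    v <- r[[col]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, NA_character_)
  lgl_col <- function(rows, col) vapply(rows, function(r)
    isTRUE(r[[col]]), NA)
  as_df <- function(rows, chr, lgl = character()) {
    cols <- c(lapply(chr, function(cl) chr_col(rows, cl)),
              lapply(lgl, function(cl) lgl_col(rows, cl)))
    names(cols) <- c(chr, lgl)
    if (length(rows) == 0L)
      cols <- lapply(cols, function(x) x[0])
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  needs <- as_df(x$needs, c("id", "name", "description"))
  pars <- as_df(x$parameters, c("id", "name", "module"),
                c("relevant", "practicable", "reliable"))
  pars <- pars[c("id", "name", "relevant", "practicable", "reliable",
                 "module")]
  triples <- as_df(x$triples, c("need", "parameter", "relation"))
  ontology_graph(needs, pars, triples)
}

#' The packaged default welfare ontology
#'
#' Contains the fourteen welfare needs, the 80 parameters of the default
#' scoring model (all three selection criteria met, module assigned) plus
#' two deliberately excluded examples (viscerosomatic index and
#' hematocrit), and an illustrative excerpt of correlation triples around
#' the needs respiration and nutrition.  The full published correlation
#' network (hundreds of parameters; respiration alone correlates with 44)
#' is far larger than this excerpt.
#'
#' @return A `welfare_ontology`.
#' @export
default_ontology <- function() {
  load_ontology(system.file("extdata", "ontology.json",
                            package = "fishwelfare", mustWork = TRUE))
}

#' Degree of an ontology node
#'
#' Number of triples touching a need or parameter.  In the full published
#' ontology the need respiration has degree 44 and nutrition degree 56;
#' the packaged excerpt carries five shown parameters for each.
#'
#' @param graph A `welfare_ontology`.
#' @param node_id Need or parameter id.
#' @return Non-negative integer count.
#' @export
node_degree <- function(graph, node_id) {
  if (node_id %in% graph$needs$id)
    sum(graph$triples$need == node_id)
  else if (node_id %in% graph$parameters$id)
    sum(graph$triples$parameter == node_id)
  else stop("unknown ontology node '", node_id, "'")
}

#' Select parameters by the three admission criteria
#'
#' Filters the ontology's parameters on any subset of the criteria
#' relevant / practicable / reliable.  Requiring all three reproduces the
#' model's parameter selection step.
#'
#' @param graph A `welfare_ontology`.
#' @param require Character vector naming the criteria that must hold;
#'   `character()` requires nothing and returns every parameter.
#' @return The matching rows of `graph$parameters`, ordered by `id`.
#' @export
#' @examples
#' sel <- select_parameters(default_ontology(),
#'                          c("relevant", "practicable", "reliable"))
#' nrow(sel)  # 80
select_parameters <- function(graph,
                              require = c("relevant", "practicable",
                                          "reliable")) {
  if (length(require) == 0L) {
    keep <- rep(TRUE, nrow(graph$parameters))
  } else {
    require <- match.arg(require, several.ok = TRUE)
    keep <- Reduce(`&`, lapply(require, function(cr) graph$parameters[[cr]]))
  }
  out <- graph$parameters[keep, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

ontology_to_igraph <- function(graph) {
  nodes <- rbind(
    data.frame(name = graph$needs$id, label = graph$needs$name,
               type = "need", module = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(name = graph$parameters$id, label = graph$parameters$name,
               type = "parameter", module = graph$parameters$module,
               stringsAsFactors = FALSE))
  edges <- graph$triples
  names(edges) <- c("from", "to", "relation")
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export an ontology graph
#'
#' Writes the bipartite graph with node attributes `type` (need /
#' parameter) and `module`, and edge attribute `relation`.  GraphML suits
#' graph viewers; the JSON form is the same triple-file schema accepted by
#' [load_ontology()], so an export/import round trip reproduces the graph.
#'
#' @param graph A `welfare_ontology`.
#' @param path Output file.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- ontology_to_igraph(graph)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    x <- list(
      needs = lapply(seq_len(nrow(graph$needs)), function(i)
        as.list(graph$needs[i, , drop = FALSE])),
      parameters = lapply(seq_len(nrow(graph$parameters)), function(i) {
        r <- as.list(graph$parameters[i, , drop = FALSE])
        if (is.na(r$module)) r$module <- NULL
        r
      }),
      triples = lapply(seq_len(nrow(graph$triples)), function(i)
        as.list(graph$triples[i, , drop = FALSE])))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                                null = "null"), path)
  }
  invisible(path)
}
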
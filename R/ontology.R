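# Relation vocabulary of a GO-style graph. Only these five edge types carry
# meaning in the pipeline; anything else found in an OBO file is dropped.
ONTOLOGY_RELATIONS <- c("is_a", "part_of", "regulates",
                        "positively_regulates", "negatively_regulates")
REGULATES_FAMILY <- c("regulates", "positively_regulates",
                      "negatively_regulates")
REGULATION_SIGN <- c(regulates = 0L,
                     positively_regulates = 1L,
                     negatively_regulates = -1L)
HIERARCHY_RELATIONS <- c("is_a", "part_of")

#' Construct an ontology graph
#'
#' An `ontology_graph` is the in-memory knowledge substrate of the pipeline:
#' a term table plus a typed edge list. Edges point from child to parent
#' (`"X is_a Y"` is stored as `child = X, parent = Y`). The subgraph restricted
#' to `is_a`/`part_of` must be acyclic; `regulates`-family edges carry the
#' sign information used by the polarity algebra and are not part of the
#' hierarchy.
#'
#' @param terms data.frame with columns `term_id`, `label`, `namespace`
#'   (one of `"biological_process"`, `"molecular_function"`, `"other"`) and
#'   logical `obsolete`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (one of `r paste(ONTOLOGY_RELATIONS, collapse = ", ")`).
#' @param validate run structural validation (default `TRUE`).
#' @return An object of class `ontology_graph`: a list with sorted,
#'   deduplicated `terms` and `edges` data.frames. Sorting makes the structure
#'   independent of input row order.
#' @export
ontology_graph <- function(terms, edges, validate = TRUE) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_t <- c("term_id", "label", "namespace", "obsolete")
  if (!all(need_t %in% names(terms)))
    stop("terms must have columns: ", paste(need_t, collapse = ", "))
  need_e <- c("child", "parent", "relation")
  if (nrow(edges) == 0L)
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  terms <- terms[order(terms$term_id), need_t]
  rownames(terms) <- NULL
  edges <- unique(edges[, need_e])
  edges <- edges[order(edges$child, edges$parent, edges$relation), ]
  rownames(edges) <- NULL
  g <- structure(list(terms = terms, edges = edges),
                 class = "ontology_graph")
  if (validate) validate_ontology_graph(g)
  g
}

validate_ontology_graph <- function(g) {
  terms <- g$terms
  edges <- g$edges
  if (anyDuplicated(terms$term_id))
    stop("duplicated term ids: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]),
               collapse = ", "))
  bad_id <- terms$term_id[!grepl("^\\S+$", terms$term_id)]
  if (length(bad_id))
    stop("malformed term id: '", bad_id[1], "'")
  no_label <- !terms$obsolete & (is.na(terms$label) | terms$label == "")
  if (any(no_label))
    stop("non-obsolete term without a label: ", terms$term_id[no_label][1])
  if (nrow(edges)) {
    if (any(edges$child == edges$parent))
      stop("self-loop on term ", edges$child[edges$child == edges$parent][1])
    unknown_rel <- setdiff(unique(edges$relation), ONTOLOGY_RELATIONS)
    if (length(unknown_rel))
      stop("unknown relation type(s): ", paste(unknown_rel, collapse = ", "))
    ep <- unique(c(edges$child, edges$parent))
    missing <- setdiff(ep, terms$term_id)
    if (length(missing))
      stop("edge endpoint not in term table: ", missing[1])
    h <- edges[edges$relation %in% HIERARCHY_RELATIONS, , drop = FALSE]
    if (nrow(h)) {
      ig <- igraph::graph_from_data_frame(h[, c("child", "parent")],
                                          directed = TRUE)
      if (!igraph::is_dag(ig)) {
        sc <- igraph::components(ig, mode = "strong")
        cyc <- names(sc$membership)[sc$membership ==
                                      which(sc$csize > 1)[1]]
        stop("cycle in is_a/part_of hierarchy involving term '",
             cyc[1], "'")
      }
    }
  }
  invisible(g)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    print(table(x$edges$relation))
  invisible(x)
}

has_term <- function(graph, term_id) term_id %in% graph$terms$term_id

term_row <- function(graph, term_id) {
  i <- match(term_id, graph$terms$term_id)
  if (is.na(i)) stop("unknown term: ", term_id)
  graph$terms[i, ]
}

#' Identify regulation terms
#'
#' A regulation term is one with at least one outgoing `regulates`-family edge
#' ("positive regulation of X"-style terms). Regulation terms generate no FTC
#' categories; their semantics are folded into the polarity of memberships on
#' the regulated base term.
#'
#' @param graph an `ontology_graph`.
#' @param term_id character vector of term ids.
#' @return logical vector.
#' @export
is_regulation_term <- function(graph, term_id) {
  reg_src <- unique(graph$edges$child[
    graph$edges$relation %in% REGULATES_FAMILY])
  term_id %in% reg_src
}

# igraph over a relation subset; vertices are all terms so that isolated
# terms are still addressable.
hierarchy_igraph <- function(graph, relations = HIERARCHY_RELATIONS) {
  e <- graph$edges[graph$edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("child", "parent")],
                                directed = TRUE,
                                vertices = graph$terms$term_id)
}

#' Ancestors of terms in the ontology hierarchy
#'
#' Follows child-to-parent edges of the selected relations transitively.
#'
#' @param graph an `ontology_graph`.
#' @param term_ids character vector of term ids.
#' @param relations edge types to traverse (default `is_a` + `part_of`).
#' @return named list: for each input term, the character vector of its
#'   proper ancestors (possibly empty).
#' @export
term_ancestors <- function(graph, term_ids,
                           relations = HIERARCHY_RELATIONS) {
  ig <- hierarchy_igraph(graph, relations)
  out <- lapply(term_ids, function(tid) {
    anc <- igraph::subcomponent(ig, tid, mode = "out")
    setdiff(names(anc), tid)
  })
  names(out) <- term_ids
  out
}
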
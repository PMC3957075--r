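#' FTC category identifiers
#'
#' A category id encodes the polarity and the numeric part of the anchor term:
#' `GO:0042730` with positive polarity becomes `FTC_P0042730`, with negative
#' polarity `FTC_A0042730` ("P" for pro-, "A" for anti-). The numeric part is
#' zero-padded to seven digits.
#'
#' @param anchor_term anchor term id (CURIE-style, e.g. `"GO:0042730"`).
#' @param polarity integer `+1` (pro) or `-1` (anti); vectorized.
#' @return character vector of category ids.
#' @export
ftc_category_id <- function(anchor_term, polarity) {
  num <- sub("^[A-Za-z]+[:_]", "", anchor_term)
  if (any(!grepl("^\\d+$", num)))
    stop("anchor term id has no numeric part: ",
         anchor_term[!grepl("^\\d+$", num)][1])
  stopifnot(all(polarity %in% c(-1L, 1L)))
  sprintf("FTC_%s%07d", ifelse(polarity > 0, "P", "A"), as.integer(num))
}

#' Parse an FTC category id back to anchor and polarity
#'
#' Inverse of [ftc_category_id()] up to the ontology id prefix, which is not
#' stored in the category id and must be supplied (default `"GO"`).
#'
#' @param category_id character vector of `FTC_[PA]\\d{7}` ids.
#' @param prefix ontology id prefix of the anchors.
#' @return data.frame with columns `category_id`, `polarity`, `anchor_term`.
#' @export
parse_ftc_category_id <- function(category_id, prefix = "GO") {
  ok <- grepl("^FTC_[PA]\\d{7}$", category_id)
  if (any(!ok))
    stop("not a well-formed FTC category id: '", category_id[!ok][1], "'")
  pol <- ifelse(substr(category_id, 5, 5) == "P", 1L, -1L)
  data.frame(category_id = category_id, polarity = pol,
             anchor_term = paste0(prefix, ":", substr(category_id, 6, 12)),
             stringsAsFactors = FALSE)
}

polarity_prefix <- function(polarity) ifelse(polarity > 0, "Pro-", "Anti-")

# Adjacency of regulates-family edges: named list child -> data.frame(target,
# sign). Signs: positively_regulates = +1, negatively_regulates = -1,
# plain regulates = 0 (neutral).
regulation_adjacency <- function(graph) {
  e <- graph$edges[graph$edges$relation %in% REGULATES_FAMILY, , drop = FALSE]
  if (!nrow(e)) return(list())
  e$sign <- REGULATION_SIGN[e$relation]
  split(data.frame(target = e$parent, sign = e$sign,
                   stringsAsFactors = FALSE), e$child)
}

reg_forms_recursive <- function(term, depth, reg_out) {
  e <- reg_out[[term]]
  if (is.null(e))
    return(data.frame(base_term = term, reg_sign = NA_integer_,
                      direct = TRUE, stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(e))) {
    tgt <- e$target[i]; s <- e$sign[i]
    if (is.null(reg_out[[tgt]])) {
      out[[length(out) + 1L]] <- data.frame(
        base_term = tgt, reg_sign = s, direct = FALSE,
        stringsAsFactors = FALSE)
    } else if (depth > 1L) {
      sub <- reg_forms_recursive(tgt, depth - 1L, reg_out)
      sub <- sub[!sub$direct, , drop = FALSE]  # tgt regulates, so never direct
      if (nrow(sub)) {
        sub$reg_sign <- s * sub$reg_sign
        out[[length(out) + 1L]] <- sub
      }
    }
    # chain deeper than `depth`: dropped (inert)
  }
  if (!length(out))
    return(data.frame(base_term = character(), reg_sign = integer(),
                      direct = logical(), stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Decompose a term into its regulation forms
#'
#' A term with `regulates`-family edges stands for a (signed) regulation of
#' its target(s): `positively_regulates` carries sign `+1`,
#' `negatively_regulates` sign `-1` and plain `regulates` the neutral sign `0`
#' (which can never contribute a pro/anti membership). A term without such
#' edges represents itself (`direct = TRUE`). Signs compose multiplicatively
#' along chains of regulation terms up to `depth` steps, so "positive
#' regulation of negative regulation of X" resolves to `(X, -1)`.
#'
#' @param term a term id; must exist and not be obsolete.
#' @param graph an [ontology_graph()].
#' @param depth maximum regulation chain length (default 2).
#' @return data.frame with columns `base_term`, `reg_sign` (`NA` when
#'   `direct`), `direct`; one row per resolved form.
#' @export
classify_regulation <- function(term, graph, depth = 2L) {
  if (!has_term(graph, term)) stop("unknown term: ", term)
  if (term_row(graph, term)$obsolete) stop("obsolete term: ", term)
  forms <- reg_forms_recursive(term, as.integer(depth),
                               regulation_adjacency(graph))
  forms <- forms[order(forms$base_term, forms$reg_sign), ]
  rownames(forms) <- NULL
  forms
}

#' Generate FTC categories from an ontology
#'
#' Every non-obsolete, non-regulation term in the included namespaces yields
#' exactly two mode-of-action categories: `"Pro-<label> agent"` (polarity +1)
#' and `"Anti-<label> agent"` (polarity -1). Regulation terms yield none;
#' their content reaches the base term's categories through the polarity
#' algebra.
#'
#' @param graph an [ontology_graph()].
#' @param include_namespaces namespaces whose terms are eligible.
#' @return data.frame with columns `category_id`, `polarity`, `anchor_term`,
#'   `label`, `namespace`, sorted by `category_id`.
#' @export
generate_categories <- function(graph,
                                include_namespaces = c("biological_process",
                                                       "molecular_function")) {
  t <- graph$terms
  eligible <- !t$obsolete &
    t$namespace %in% include_namespaces &
    !is_regulation_term(graph, t$term_id)
  t <- t[eligible, , drop = FALSE]
  if (!nrow(t))
    return(data.frame(category_id = character(), polarity = integer(),
                      anchor_term = character(), label = character(),
                      namespace = character(), stringsAsFactors = FALSE))
  cats <- rbind(
    data.frame(polarity = 1L, anchor_term = t$term_id,
               anchor_label = t$label, namespace = t$namespace,
               stringsAsFactors = FALSE),
    data.frame(polarity = -1L, anchor_term = t$term_id,
               anchor_label = t$label, namespace = t$namespace,
               stringsAsFactors = FALSE))
  cats$category_id <- ftc_category_id(cats$anchor_term, cats$polarity)
  cats$label <- paste0(polarity_prefix(cats$polarity), cats$anchor_label,
                       " agent")
  if (anyDuplicated(cats$category_id))
    stop("category id collision (non-unique numeric parts across term ids): ",
         cats$category_id[duplicated(cats$category_id)][1])
  cats <- cats[order(cats$category_id),
               c("category_id", "polarity", "anchor_term", "label",
                 "namespace")]
  rownames(cats) <- NULL
  cats
}

ftc_roots <- function() {
  data.frame(
    category_id = c("FTC_P_ROOT_BP", "FTC_A_ROOT_BP",
                    "FTC_P_ROOT_MF", "FTC_A_ROOT_MF"),
    polarity = c(1L, -1L, 1L, -1L),
    anchor_term = NA_character_,
    label = c("Pro-biological process agent",
              "Anti-biological process agent",
              "Pro-molecular function agent",
              "Anti-molecular function agent"),
    namespace = rep(c("biological_process", "molecular_function"),
                    each = 2),
    stringsAsFactors = FALSE)
}

#' Build the category taxonomy
#'
#' Lifts the ontology hierarchy onto the categories: `Pro-X` is a subclass of
#' `Pro-Y` (and `Anti-X` of `Anti-Y`) exactly when anchor `X` is a direct
#' descendant of anchor `Y` under the propagation relations, after transitive
#' reduction of the anchor-to-anchor reachability relation (paths may pass
#' through non-anchor terms such as regulation terms). Four synthetic roots
#' (pro/anti x biological process/molecular function) are added and every
#' parentless category is attached to its polarity/namespace root. Subclass
#' edges never mix polarities.
#'
#' @param categories data.frame from [generate_categories()].
#' @param graph the [ontology_graph()] the categories were generated from.
#' @param propagation_relations hierarchy relations to lift
#'   (default `is_a` + `part_of`); `regulates`-family edges never produce
#'   subclass edges.
#' @return object of class `ftc_taxonomy`: list with `categories` (including
#'   the roots, flagged `is_root`) and `edges` (`child`, `parent` category
#'   ids), guaranteed acyclic.
#' @export
build_taxonomy <- function(categories, graph,
                           propagation_relations = HIERARCHY_RELATIONS) {
  bad <- setdiff(categories$anchor_term, graph$terms$term_id)
  if (length(bad))
    stop("category anchored on a term outside the graph: ", bad[1])
  anchors <- unique(categories$anchor_term)
  reach <- term_ancestors(graph, anchors, relations = propagation_relations)
  reach <- lapply(reach, function(a) intersect(a, anchors))
  # transitive reduction over anchors
  direct_parents <- lapply(anchors, function(x) {
    r <- reach[[x]]
    if (!length(r)) return(character())
    setdiff(r, unique(unlist(reach[r], use.names = FALSE)))
  })
  names(direct_parents) <- anchors

  roots <- ftc_roots()
  cats <- categories
  cats$is_root <- FALSE
  roots$is_root <- TRUE
  all_cats <- rbind(cats, roots)

  edges <- list()
  for (i in seq_len(nrow(categories))) {
    x <- categories$anchor_term[i]
    pol <- categories$polarity[i]
    dp <- direct_parents[[x]]
    if (length(dp)) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = categories$category_id[i],
        parent = ftc_category_id(dp, rep(pol, length(dp))),
        stringsAsFactors = FALSE)
    } else {
      root_id <- roots$category_id[roots$polarity == pol &
                                     roots$namespace ==
                                       categories$namespace[i]]
      edges[[length(edges) + 1L]] <- data.frame(
        child = categories$category_id[i], parent = root_id,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$child, edges$parent), ]
  rownames(edges) <- NULL

  tax <- structure(list(categories = all_cats, edges = edges),
                   class = "ftc_taxonomy")
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  cats <- tax$categories
  edges <- tax$edges
  if (nrow(edges)) {
    pol <- stats::setNames(cats$polarity, cats$category_id)
    if (any(pol[edges$child] != pol[edges$parent]))
      stop("subclass edge connecting opposite polarities")
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = cats$category_id)
    if (!igraph::is_dag(ig)) stop("taxonomy is not acyclic")
  }
  invisible(tax)
}

#' @export
print.ftc_taxonomy <- function(x, ...) {
  cat("ftc_taxonomy:", sum(!x$categories$is_root), "categories + ",
      sum(x$categories$is_root), "roots,", nrow(x$edges),
      "subclass edges\n")
  invisible(x)
}

#' Ancestors of categories in the taxonomy
#'
#' @param taxonomy an `ftc_taxonomy`.
#' @param category_ids character vector of category ids.
#' @return named list of proper-ancestor id vectors (roots included).
#' @export
taxonomy_ancestors <- function(taxonomy, category_ids) {
  ig <- igraph::graph_from_data_frame(
    taxonomy$edges, directed = TRUE,
    vertices = taxonomy$categories$category_id)
  out <- lapply(category_ids, function(cid) {
    anc <- igraph::subcomponent(ig, cid, mode = "out")
    setdiff(names(anc), cid)
  })
  names(out) <- category_ids
  out
}
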
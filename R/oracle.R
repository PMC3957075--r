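#' Brute-force classification oracle
#'
#' Independent re-derivation of the classifier's output by naive enumeration:
#' for every (drug, category) pair it searches raw-graph paths satisfying the
#' category definition (a signed link, an annotation, and a regulates-chain of
#' at most `regulation_chain_depth` steps whose sign product matches the
#' category polarity), and computes indirect memberships by a hand-rolled
#' fixpoint over hierarchy reachability. It shares no traversal code with
#' [classify()] (no igraph, no cached adjacency) and exists so the rule engine
#' can be checked against exhaustive search on small knowledge bases.
#'
#' @param kb an `ftc_kb`.
#' @param propagation_relations,regulation_chain_depth,include_namespaces
#'   as in [classify()].
#' @return list with `memberships`: data.frame `drug_id`, `category_id`,
#'   `kind`, sorted.
#' @export
brute_force_oracle <- function(kb,
                               propagation_relations = c("is_a", "part_of"),
                               regulation_chain_depth = 2L,
                               include_namespaces = c("biological_process",
                                                      "molecular_function")) {
  g <- kb$graph
  edges <- g$edges
  terms <- g$terms
  reg_rel <- c("regulates", "positively_regulates", "negatively_regulates")
  reg_edges <- edges[edges$relation %in% reg_rel, , drop = FALSE]
  hier_edges <- edges[edges$relation %in% propagation_relations, , drop = FALSE]
  has_reg_out <- function(t) any(reg_edges$child == t)

  # eligible anchor terms, enumerated naively
  anchors <- terms$term_id[!terms$obsolete &
                             terms$namespace %in% include_namespaces]
  anchors <- anchors[!vapply(anchors, has_reg_out, logical(1))]

  oracle_cat_id <- function(anchor, pol)
    paste0("FTC_", if (pol > 0) "P" else "A",
           formatC(as.integer(sub("^[A-Za-z]+[:_]", "", anchor)),
                   width = 7, flag = "0"))

  edge_sign <- function(rel)
    switch(rel, positively_regulates = 1L, negatively_regulates = -1L, 0L)

  # all sign products of regulates-paths from T ending at a non-regulation
  # term, <= depth steps; a path stops at the first non-regulation node.
  path_results <- function(t, depth) {
    if (!has_reg_out(t)) return(list(list(base = t, direct = TRUE)))
    out <- list()
    walk <- function(node, steps_left, prod) {
      rows <- which(reg_edges$child == node)
      for (i in rows) {
        tgt <- reg_edges$parent[i]
        s <- prod * edge_sign(reg_edges$relation[i])
        if (!has_reg_out(tgt)) {
          out[[length(out) + 1L]] <<- list(base = tgt, direct = FALSE,
                                           sign = s)
        } else if (steps_left > 1L) {
          walk(tgt, steps_left - 1L, s)
        }
      }
    }
    walk(t, as.integer(regulation_chain_depth), 1L)
    out
  }

  # direct membership test for one (drug, anchor, polarity)
  satisfied <- function(drug, anchor, pol) {
    lrows <- which(kb$links$drug_id == drug & !is.na(kb$links$sign))
    for (i in lrows) {
      p <- kb$links$sign[i]
      arows <- which(kb$annotations$protein_id == kb$links$protein_id[i])
      for (j in arows) {
        t0 <- kb$annotations$term_id[j]
        for (res in path_results(t0, regulation_chain_depth)) {
          if (res$base != anchor) next
          if (res$direct) {
            if (p == pol) return(TRUE)
          } else if (res$sign != 0L && p * res$sign == pol) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }

  direct <- list()
  for (drug in kb$drugs$drug_id) {
    for (anchor in anchors) {
      for (pol in c(1L, -1L)) {
        if (satisfied(drug, anchor, pol))
          direct[[length(direct) + 1L]] <- data.frame(
            drug_id = drug, category_id = oracle_cat_id(anchor, pol),
            kind = "direct", stringsAsFactors = FALSE)
      }
    }
  }
  direct <- if (length(direct)) do.call(rbind, direct) else
    data.frame(drug_id = character(), category_id = character(),
               kind = character(), stringsAsFactors = FALSE)

  # hierarchy ancestors of an anchor, fixpoint expansion
  hier_anc <- function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier)) {
      nxt <- unique(hier_edges$parent[hier_edges$child %in% frontier])
      nxt <- setdiff(nxt, c(seen, t))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  ns_of <- stats::setNames(terms$namespace, terms$term_id)
  root_id <- function(pol, ns)
    paste0("FTC_", if (pol > 0) "P" else "A", "_ROOT_",
           if (ns == "biological_process") "BP" else "MF")

  # an anchor with no anchor ancestor is top-level; its categories attach to
  # the polarity root of its own namespace
  anchor_parentless <- function(a)
    length(intersect(hier_anc(a), anchors)) == 0L

  indirect <- list()
  for (drug in unique(direct$drug_id)) {
    dc <- direct$category_id[direct$drug_id == drug]
    up <- character()
    for (cid in dc) {
      pol <- if (substr(cid, 5, 5) == "P") 1L else -1L
      anchor <- anchors[vapply(anchors, function(a)
        oracle_cat_id(a, pol) == cid, logical(1))][1]
      anc <- intersect(hier_anc(anchor), anchors)
      if (length(anc))
        up <- c(up, vapply(anc, oracle_cat_id, "", pol = pol))
      # roots are reached through the parentless members of {anchor} U anc
      tops <- Filter(anchor_parentless, c(anchor, anc))
      up <- c(up, vapply(tops, function(a)
        root_id(pol, ns_of[[a]]), ""))
    }
    up <- setdiff(unique(up), dc)
    if (length(up))
      indirect[[length(indirect) + 1L]] <- data.frame(
        drug_id = drug, category_id = up, kind = "indirect",
        stringsAsFactors = FALSE)
  }
  indirect <- if (length(indirect)) do.call(rbind, indirect) else
    data.frame(drug_id = character(), category_id = character(),
               kind = character(), stringsAsFactors = FALSE)

  memberships <- rbind(direct, indirect)
  memberships <- memberships[order(memberships$drug_id,
                                   memberships$category_id,
                                   memberships$kind), ]
  rownames(memberships) <- NULL
  list(memberships = memberships)
}
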
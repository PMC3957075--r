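#' Default action-to-sign vocabulary
#'
#' Maps pharmacological action terms (DrugBank-style, lowercase) to the sign
#' of the drug-target perturbation: `-1` for negative perturbation (e.g.
#' inhibitor), `+1` for positive (e.g. agonist). Actions outside the table map
#' to `NA` ("unknown") and are inert in classification rather than errors,
#' because the action vocabulary of source databases is open.
#'
#' @return named integer vector.
#' @export
default_action_signs <- function() {
  c(inhibitor = -1L, antagonist = -1L, blocker = -1L, suppressor = -1L,
    "negative modulator" = -1L,
    agonist = 1L, activator = 1L, inducer = 1L, stimulator = 1L,
    potentiator = 1L, "positive modulator" = 1L)
}

#' Map an action term to a perturbation sign
#'
#' Case-insensitive lookup in the sign vocabulary; `extra` entries extend or
#' override the defaults.
#'
#' @param action_term character vector of action terms.
#' @param table base vocabulary (default [default_action_signs()]).
#' @param extra optional named integer vector of additional mappings.
#' @return integer vector of `+1`, `-1` or `NA` (unknown).
#' @export
map_action_to_sign <- function(action_term, table = default_action_signs(),
                               extra = NULL) {
  tab <- c(table, extra)
  names(tab) <- tolower(names(tab))
  tab <- tab[!duplicated(names(tab), fromLast = TRUE)]  # extra overrides
  unname(tab[tolower(trimws(action_term))])
}

# Regulation forms for a set of terms, one call per unique term.
regulation_forms_table <- function(graph, term_ids, depth) {
  reg_out <- regulation_adjacency(graph)
  term_ids <- unique(term_ids)
  forms <- lapply(term_ids, function(tid)
    cbind(term_id = tid,
          reg_forms_recursive(tid, depth, reg_out),
          stringsAsFactors = FALSE))
  forms <- do.call(rbind, forms)
  if (is.null(forms))
    forms <- data.frame(term_id = character(), base_term = character(),
                        reg_sign = integer(), direct = logical(),
                        stringsAsFactors = FALSE)
  forms
}

#' Infer direct category memberships
#'
#' Implements the regulator pattern: for every perturbation link
#' (drug --p--> protein, p in {+1, -1}), every annotation
#' (protein -> term T) and every regulation form (B, r) of T, the drug is a
#' direct member of the category anchored at B with polarity `p` (when T is B
#' itself) or `p * r` (when T is a signed regulation of B). Neutral regulation
#' (r = 0) and unknown-sign links contribute nothing. Each satisfied pattern
#' appends one provenance chain; duplicate (drug, category) memberships merge
#' their provenance.
#'
#' @param drugs,links data.frames as in an `ftc_kb`.
#' @param annotations annotation data.frame.
#' @param graph the [ontology_graph()].
#' @param categories data.frame from [generate_categories()].
#' @param regulation_chain_depth passed to the regulation decomposition.
#' @return data.frame with columns `drug_id`, `category_id`, `kind`
#'   (`"direct"`), `provenance`, sorted by drug then category.
#' @export
infer_direct_memberships <- function(drugs, links, annotations, graph,
                                     categories,
                                     regulation_chain_depth = 2L) {
  empty <- data.frame(drug_id = character(), category_id = character(),
                      kind = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  lk <- links[!is.na(links$sign) & links$sign %in% c(-1L, 1L), , drop = FALSE]
  if (!nrow(lk) || !nrow(annotations) || !nrow(categories)) return(empty)
  la <- merge(lk, annotations[, c("protein_id", "term_id")],
              by = "protein_id")
  if (!nrow(la)) return(empty)
  forms <- regulation_forms_table(graph, la$term_id,
                                  as.integer(regulation_chain_depth))
  laf <- merge(la, forms, by = "term_id")
  if (!nrow(laf)) return(empty)
  pol <- ifelse(laf$direct, laf$sign, laf$sign * laf$reg_sign)
  laf <- laf[pol != 0L, , drop = FALSE]
  pol <- pol[pol != 0L]
  if (!nrow(laf)) return(empty)
  cat_id <- ftc_category_id(laf$base_term, pol)
  keep <- cat_id %in% categories$category_id
  laf <- laf[keep, , drop = FALSE]
  cat_id <- cat_id[keep]
  if (!nrow(laf)) return(empty)
  reg_part <- ifelse(
    laf$direct,
    sprintf("%s (direct)", laf$term_id),
    sprintf("%s -[%+d]-> %s", laf$term_id, laf$reg_sign, laf$base_term))
  prov <- sprintf("%s -[%+d]-> %s; %s annotated-to %s; %s",
                  laf$drug_id, laf$sign, laf$protein_id,
                  laf$protein_id, laf$term_id, reg_part)
  out <- data.frame(drug_id = laf$drug_id, category_id = cat_id,
                    provenance = prov, stringsAsFactors = FALSE)
  agg <- stats::aggregate(provenance ~ drug_id + category_id, data = out,
                          FUN = function(p)
                            paste(sort(unique(p)), collapse = " | "))
  agg$kind <- "direct"
  agg <- agg[order(agg$drug_id, agg$category_id),
             c("drug_id", "category_id", "kind", "provenance")]
  rownames(agg) <- NULL
  agg
}

#' Indirect memberships by ancestor closure
#'
#' For each drug, the indirect set is the union of the taxonomy ancestors
#' (roots included) of its direct categories, minus the direct set.
#' Idempotent: applying the closure to direct plus indirect adds nothing.
#'
#' @param direct data.frame of direct memberships.
#' @param taxonomy an `ftc_taxonomy`.
#' @return data.frame of memberships with `kind = "indirect"`.
#' @export
ancestor_closure <- function(direct, taxonomy) {
  empty <- data.frame(drug_id = character(), category_id = character(),
                      kind = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(direct)) return(empty)
  anc <- taxonomy_ancestors(taxonomy, unique(direct$category_id))
  rows <- lapply(split(direct$category_id, direct$drug_id),
                 function(cids) {
    up <- lapply(cids, function(c) anc[[c]])
    ind <- setdiff(unique(unlist(up, use.names = FALSE)), cids)
    if (!length(ind)) return(NULL)
    via <- vapply(ind, function(a)
      paste(sort(cids[vapply(up, function(u) a %in% u, logical(1))]),
            collapse = ","), character(1))
    data.frame(category_id = ind, provenance = paste0("via ", via),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, Map(function(d, df)
    cbind(drug_id = d, df, stringsAsFactors = FALSE),
    names(rows), rows))
  out$kind <- "indirect"
  out <- out[order(out$drug_id, out$category_id),
             c("drug_id", "category_id", "kind", "provenance")]
  rownames(out) <- NULL
  out
}

#' Classify a knowledge base into an FTC build
#'
#' Runs the whole pipeline: category generation, taxonomy construction,
#' direct membership inference via the regulator pattern, ancestor closure,
#' and build metrics. The result is deterministic: identical inputs give
#' identical sorted membership tables.
#'
#' @param kb an `ftc_kb` from [assemble_kb()] or [read_kb()].
#' @param propagation_relations hierarchy relations lifted into the taxonomy.
#' @param regulation_chain_depth maximum regulation chain length (default 2).
#' @param include_namespaces namespaces eligible for categories.
#' @return object of class `ftc_build`: list with `taxonomy`, `memberships`,
#'   `drugs`, `atc`, `metrics` and `settings`.
#' @export
classify <- function(kb,
                     propagation_relations = HIERARCHY_RELATIONS,
                     regulation_chain_depth = 2L,
                     include_namespaces = c("biological_process",
                                            "molecular_function")) {
  stopifnot(inherits(kb, "ftc_kb"))
  categories <- generate_categories(kb$graph,
                                    include_namespaces = include_namespaces)
  taxonomy <- build_taxonomy(categories, kb$graph,
                             propagation_relations = propagation_relations)
  direct <- infer_direct_memberships(kb$drugs, kb$links, kb$annotations,
                                     kb$graph, categories,
                                     regulation_chain_depth)
  indirect <- ancestor_closure(direct, taxonomy)
  memberships <- rbind(direct, indirect)
  memberships <- memberships[order(memberships$drug_id,
                                   memberships$category_id,
                                   memberships$kind), ]
  rownames(memberships) <- NULL
  build <- structure(
    list(taxonomy = taxonomy, memberships = memberships, drugs = kb$drugs,
         atc = kb$atc,
         settings = list(propagation_relations = propagation_relations,
                         regulation_chain_depth = regulation_chain_depth,
                         include_namespaces = include_namespaces)),
    class = "ftc_build")
  build$metrics <- build_metrics(build, kb)
  build
}

build_metrics <- function(build, kb) {
  cats <- build$taxonomy$categories
  n_cat <- sum(!cats$is_root)
  m <- build$memberships
  direct_cat <- unique(m$category_id[m$kind == "direct"])
  any_cat <- unique(m$category_id)
  per_drug_direct <- table(factor(m$drug_id[m$kind == "direct"]))
  list(
    n_terms = nrow(kb$graph$terms),
    n_annotations = nrow(kb$annotations),
    n_drugs = nrow(kb$drugs),
    n_links = nrow(kb$links),
    n_categories = n_cat,
    n_taxonomy_nodes = nrow(cats),
    n_drugs_classified = length(per_drug_direct),
    n_categories_direct = length(direct_cat),
    n_categories_direct_or_indirect = length(any_cat),
    frac_categories_direct = if (n_cat) length(direct_cat) / n_cat else 0,
    frac_categories_any = if (n_cat) length(any_cat) / n_cat else 0)
}

#' @export
print.ftc_build <- function(x, ...) {
  m <- x$metrics
  cat("ftc_build:", m$n_categories, "categories,", m$n_drugs, "drugs,",
      sum(x$memberships$kind == "direct"), "direct /",
      sum(x$memberships$kind == "indirect"), "indirect memberships\n")
  invisible(x)
}

#' @export
summary.ftc_build <- function(object, ...) {
  m <- object$metrics
  cat("FTC build\n")
  cat(sprintf("  terms: %d  annotations: %d  drugs: %d  links: %d\n",
              m$n_terms, m$n_annotations, m$n_drugs, m$n_links))
  cat(sprintf("  categories: %d (+4 roots)\n", m$n_categories))
  cat(sprintf("  categories with >=1 direct drug: %d (%.1f%%)\n",
              m$n_categories_direct, 100 * m$frac_categories_direct))
  cat(sprintf("  categories with >=1 direct or indirect drug: %d (%.1f%%)\n",
              m$n_categories_direct_or_indirect,
              100 * m$frac_categories_any))
  pp <- polypharmacology_stats(object)
  if (nrow(pp$per_drug) && any(pp$per_drug$n_direct > 0))
    cat(sprintf("  mean MoAs per classified drug: %.1f direct, %.1f with ancestors\n",
                pp$summary$direct["mean"], pp$summary$total["mean"]))
  invisible(m)
}

#' Polypharmacology spectrum
#'
#' Per-drug counts of direct and direct-plus-indirect mode-of-action
#' categories, with summary statistics (mean, min, max, range) over the drugs
#' that have at least one direct membership. The per-drug table covers every
#' drug in the build (zero rows for inert drugs) and is ready for histogram
#' plotting.
#'
#' @param build an `ftc_build`.
#' @return list with `per_drug` (data.frame `drug_id`, `n_direct`, `n_total`)
#'   and `summary` (list of named stat vectors `direct` and `total`).
#' @export
polypharmacology_stats <- function(build) {
  m <- build$memberships
  ids <- build$drugs$drug_id
  nd <- table(factor(m$drug_id[m$kind == "direct"], levels = ids))
  nt <- table(factor(m$drug_id, levels = ids))
  per_drug <- data.frame(drug_id = ids,
                         n_direct = as.integer(nd),
                         n_total = as.integer(nt),
                         stringsAsFactors = FALSE)
  cl <- per_drug[per_drug$n_direct > 0, , drop = FALSE]
  stat <- function(x) {
    if (!length(x)) return(c(mean = NA_real_, min = NA_real_,
                             max = NA_real_, range = NA_real_))
    c(mean = mean(x), min = min(x), max = max(x),
      range = max(x) - min(x))
  }
  list(per_drug = per_drug,
       summary = list(direct = stat(cl$n_direct),
                      total = stat(cl$n_total)))
}
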
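# Serialize a term/edge table pair as OBO 1.2 text.
write_obo_file <- function(terms, edges, path,
                           ontology_name = "ftc-fixture") {
  terms <- terms[order(terms$term_id), , drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("ontology: ", ontology_name), ""), con)
  by_child <- split(edges, edges$child)
  for (i in seq_len(nrow(terms))) {
    t <- terms[i, ]
    lines <- c("[Term]", paste0("id: ", t$term_id),
               paste0("name: ", t$label),
               paste0("namespace: ", t$namespace))
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    e <- by_child[[t$term_id]]
    if (!is.null(e) && !isTRUE(t$obsolete)) {
      e <- e[order(e$relation, e$parent), , drop = FALSE]
      for (j in seq_len(nrow(e))) {
        lines <- c(lines, if (e$relation[j] == "is_a")
          paste0("is_a: ", e$parent[j])
          else paste0("relationship: ", e$relation[j], " ", e$parent[j]))
      }
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a completed FTC build to disk
#'
#' Produces three files in `out_dir`:
#' * `taxonomy.obo` — the category taxonomy as OBO, FTC ids as term ids and
#'   subclass edges as `is_a`; re-parsable by [parse_obo()] into an
#'   isomorphic DAG.
#' * `memberships.tsv` — drug, category, direct/indirect kind, provenance.
#' * `metrics.json` — build metrics (category counts, drugs, coverage
#'   fractions).
#'
#' @param build an `ftc_build`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named character vector of the written paths.
#' @export
write_ftc_build <- function(build, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  cats <- build$taxonomy$categories
  obo_terms <- data.frame(term_id = cats$category_id, label = cats$label,
                          namespace = cats$namespace, obsolete = FALSE,
                          stringsAsFactors = FALSE)
  obo_edges <- build$taxonomy$edges
  obo_edges$relation <- if (nrow(obo_edges)) "is_a" else character()
  paths <- c(
    taxonomy = file.path(out_dir, "taxonomy.obo"),
    memberships = file.path(out_dir, "memberships.tsv"),
    metrics = file.path(out_dir, "metrics.json"))
  write_obo_file(obo_terms, obo_edges, paths[["taxonomy"]],
                 ontology_name = "ftc")
  write_tsv(build$memberships, paths[["memberships"]])
  jsonlite::write_json(build$metrics, paths[["metrics"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
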
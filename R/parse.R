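#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas and keeps the `is_a` and `relationship:` edges the
#' pipeline understands (`part_of`, `regulates`, `positively_regulates`,
#' `negatively_regulates`). Other relationship types are dropped with one
#' summary warning. Obsolete terms are recorded in the term table but take
#' part in no edges, and later generate no categories.
#'
#' @param path path to an OBO text file.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- lines[starts] == "[Term]"

  terms <- list(); edges <- list()
  dropped_rel <- character()
  default_ns <- "other"
  hdr <- if (starts[1] > 1) lines[seq_len(starts[1] - 1L)] else character()
  dns <- grep("^default-namespace:", hdr, value = TRUE)
  if (length(dns))
    default_ns <- norm_namespace(trimws(sub("^default-namespace:", "", dns[1])))

  for (k in which(keep)) {
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- sub("\\s+!.*$", "", body)        # trailing comments
    body <- body[nzchar(trimws(body))]
    kv <- regmatches(body, regexpr("^[^:]+:", body))
    key <- sub(":$", "", kv)
    val <- trimws(substring(body, nchar(kv) + 1L))
    id <- val[key == "id"][1]
    if (is.na(id)) next
    name <- val[key == "name"][1]
    ns <- val[key == "namespace"][1]
    ns <- if (is.na(ns)) default_ns else norm_namespace(ns)
    obsolete <- any(key == "is_obsolete" & val == "true")
    terms[[length(terms) + 1L]] <- data.frame(
      term_id = id, label = if (is.na(name)) "" else name,
      namespace = ns, obsolete = obsolete, stringsAsFactors = FALSE)
    if (obsolete) next
    for (i in which(key == "is_a"))
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = val[i], relation = "is_a",
        stringsAsFactors = FALSE)
    for (i in which(key == "relationship")) {
      parts <- strsplit(val[i], "\\s+")[[1]]
      if (length(parts) < 2) next
      rel <- parts[1]; target <- parts[2]
      if (rel %in% ONTOLOGY_RELATIONS) {
        edges[[length(edges) + 1L]] <- data.frame(
          child = id, parent = target, relation = rel,
          stringsAsFactors = FALSE)
      } else {
        dropped_rel <- c(dropped_rel, rel)
      }
    }
  }
  if (length(dropped_rel)) {
    tab <- table(dropped_rel)
    warning("dropped unrecognized relation type(s): ",
            paste(sprintf("%s (x%d)", names(tab), as.integer(tab)),
                  collapse = ", "), call. = FALSE)
  }
  terms <- do.call(rbind, terms)
  if (is.null(terms)) stop("no [Term] stanzas in ", path)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  # edges touching obsolete or unknown terms are removed
  obso <- terms$term_id[terms$obsolete]
  known <- terms$term_id
  bad <- !(edges$child %in% known) | !(edges$parent %in% known) |
    edges$child %in% obso | edges$parent %in% obso
  n_unknown <- sum(!(edges$child %in% known) | !(edges$parent %in% known))
  if (n_unknown)
    warning("dropped ", n_unknown,
            " edge(s) referencing terms absent from the file", call. = FALSE)
  edges <- edges[!bad, , drop = FALSE]
  ontology_graph(terms, edges)
}

norm_namespace <- function(ns) {
  if (ns %in% c("biological_process", "molecular_function")) ns else "other"
}

#' Parse a GAF 2.x protein-to-GO annotation file
#'
#' Comment lines start with `!`. Rows are dropped (and counted) when the
#' qualifier contains `NOT`, when the GO id is absent from the graph, when the
#' annotated term is obsolete, or when the evidence code is in
#' `exclude_evidence`. Retained rows are deduplicated and sorted, so parsing
#' is independent of input row order.
#'
#' @param path path to a GAF file.
#' @param graph the [ontology_graph()] the annotations refer to.
#' @param exclude_evidence character vector of evidence codes to drop
#'   (e.g. `"IEA"`); default `NULL` keeps everything.
#' @return data.frame with columns `protein_id`, `term_id`, `evidence_code`,
#'   `qualifier`; drop counts in `attr(, "drop_counts")`.
#' @export
parse_gaf <- function(path, graph, exclude_evidence = NULL) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) {
    out <- data.frame(protein_id = character(), term_id = character(),
                      evidence_code = character(), qualifier = character(),
                      stringsAsFactors = FALSE)
    attr(out, "drop_counts") <- c(not_qualifier = 0L, unknown_term = 0L,
                                  obsolete_term = 0L, evidence = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 15L)
  if (length(bad))
    stop("GAF parse error: line ", bad[1], " has ", nf[bad[1]],
         " columns (expected >= 15)")
  ann <- data.frame(
    protein_id = vapply(fields, `[[`, "", 2L),
    qualifier = vapply(fields, `[[`, "", 4L),
    term_id = vapply(fields, `[[`, "", 5L),
    evidence_code = vapply(fields, `[[`, "", 7L),
    stringsAsFactors = FALSE)

  is_not <- grepl("(^|\\|)NOT($|\\|)", ann$qualifier)
  n_not <- sum(is_not)
  ann <- ann[!is_not, , drop = FALSE]
  unknown <- !(ann$term_id %in% graph$terms$term_id)
  n_unknown <- sum(unknown)
  ann <- ann[!unknown, , drop = FALSE]
  obso <- graph$terms$term_id[graph$terms$obsolete]
  is_obs <- ann$term_id %in% obso
  n_obs <- sum(is_obs)
  ann <- ann[!is_obs, , drop = FALSE]
  n_ev <- 0L
  if (length(exclude_evidence)) {
    drop_ev <- ann$evidence_code %in% exclude_evidence
    n_ev <- sum(drop_ev)
    ann <- ann[!drop_ev, , drop = FALSE]
  }
  ann <- unique(ann[, c("protein_id", "term_id", "evidence_code",
                        "qualifier")])
  ann <- ann[order(ann$protein_id, ann$term_id, ann$evidence_code), ]
  rownames(ann) <- NULL
  attr(ann, "drop_counts") <- c(not_qualifier = n_not,
                                unknown_term = n_unknown,
                                obsolete_term = n_obs, evidence = n_ev)
  ann
}

#' Parse a drug-target table
#'
#' Tab-separated with header columns `drug_id`, `drug_name`, `protein_id`,
#' `action_term`. Each row becomes a perturbation link whose sign is the image
#' of the action term under [map_action_to_sign()]; unknown actions give sign
#' `NA` and the link is retained but inert in classification.
#'
#' @param path path to the TSV file.
#' @param actions optional named sign table passed to [map_action_to_sign()].
#' @return list with `drugs` (data.frame `drug_id`, `name`) and `links`
#'   (data.frame `drug_id`, `protein_id`, `action_term`, `sign`).
#' @export
parse_drug_targets <- function(path, actions = NULL) {
  tab <- read_tsv_checked(path, c("drug_id", "drug_name", "protein_id",
                                  "action_term"))
  if (nrow(tab) == 0L) {
    return(list(
      drugs = data.frame(drug_id = character(), name = character(),
                         stringsAsFactors = FALSE),
      links = data.frame(drug_id = character(), protein_id = character(),
                         action_term = character(), sign = integer(),
                         stringsAsFactors = FALSE)))
  }
  tab$action_term <- tolower(trimws(tab$action_term))
  links <- unique(tab[, c("drug_id", "protein_id", "action_term")])
  links$sign <- map_action_to_sign(links$action_term, extra = actions)
  links <- links[order(links$drug_id, links$protein_id, links$action_term), ]
  rownames(links) <- NULL
  drugs <- unique(tab[, c("drug_id", "drug_name")])
  names(drugs)[2] <- "name"
  if (anyDuplicated(drugs$drug_id)) {
    warning("drug id(s) with conflicting names; keeping the first",
            call. = FALSE)
    drugs <- drugs[!duplicated(drugs$drug_id), ]
  }
  drugs <- drugs[order(drugs$drug_id), ]
  rownames(drugs) <- NULL
  list(drugs = drugs, links = links)
}

ATC_PATTERN <- "^([A-Z]|[A-Z]\\d{2}|[A-Z]\\d{2}[A-Z]|[A-Z]\\d{2}[A-Z]{2}|[A-Z]\\d{2}[A-Z]{2}\\d{2})$"

#' Parse a drug-to-ATC table
#'
#' Tab-separated with header columns `drug_id`, `atc_code`, one row per code.
#' Codes are validated against the ATC level structure (1, 3, 4, 5 or 7
#' characters); drugs without a row are simply absent from the map (they show
#' up downstream as `"NoCategory"`).
#'
#' @param path path to the TSV file.
#' @return named list mapping `drug_id` to a sorted character vector of codes.
#' @export
parse_atc <- function(path) {
  tab <- read_tsv_checked(path, c("drug_id", "atc_code"))
  if (nrow(tab) == 0L) return(structure(list(), names = character()))
  bad <- !grepl(ATC_PATTERN, tab$atc_code)
  if (any(bad))
    stop("malformed ATC code: '", tab$atc_code[bad][1], "'")
  lapply(split(tab$atc_code, tab$drug_id),
         function(x) sort(unique(x)))
}

#' Parse curated FTC-to-ATC evaluation points
#'
#' Tab-separated with header columns `ftc_id`, `atc_code` and optionally
#' `comment`; several rows with the same `ftc_id` merge into one point with a
#' set of ATC code prefixes.
#'
#' @param path path to the TSV file.
#' @return list of evaluation points, each a list with `ftc_category_id`,
#'   `atc_codes` and `comment`.
#' @export
parse_evaluation_points <- function(path) {
  tab <- read_tsv_checked(path, c("ftc_id", "atc_code"))
  if (nrow(tab) == 0L) return(list())
  if (!"comment" %in% names(tab)) tab$comment <- ""
  bad <- !grepl("^FTC_[PA]\\d{7}$", tab$ftc_id)
  if (any(bad))
    stop("malformed FTC category id: '", tab$ftc_id[bad][1], "'")
  bad <- !grepl(ATC_PATTERN, tab$atc_code)
  if (any(bad))
    stop("malformed ATC code: '", tab$atc_code[bad][1], "'")
  pts <- lapply(split(tab, tab$ftc_id), function(d) {
    cm <- d$comment[nzchar(d$comment)]
    list(ftc_category_id = d$ftc_id[1],
         atc_codes = sort(unique(d$atc_code)),
         comment = if (length(cm)) cm[1] else "")
  })
  unname(pts[order(names(pts))])
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  tab
}

#' Assemble a knowledge base
#'
#' Bundles the parsed inputs after checking referential closure: every
#' annotation term must exist in the graph and every link must reference a
#' known drug. Links to proteins without annotations are legal (they yield no
#' memberships).
#'
#' @param graph [ontology_graph()].
#' @param annotations data.frame from [parse_gaf()].
#' @param drugs,links data.frames from [parse_drug_targets()].
#' @param atc optional ATC map from [parse_atc()].
#' @return object of class `ftc_kb`.
#' @export
assemble_kb <- function(graph, annotations, drugs, links, atc = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  bad <- setdiff(annotations$term_id, graph$terms$term_id)
  if (length(bad))
    stop("annotation references unknown term: ", bad[1])
  bad <- setdiff(links$drug_id, drugs$drug_id)
  if (length(bad))
    stop("link references unknown drug: ", bad[1])
  structure(list(graph = graph, annotations = annotations,
                 drugs = drugs, links = links, atc = atc),
            class = "ftc_kb")
}

#' @export
print.ftc_kb <- function(x, ...) {
  cat("ftc_kb:", nrow(x$graph$terms), "terms,",
      nrow(x$annotations), "annotations,",
      nrow(x$drugs), "drugs,", nrow(x$links), "links\n")
  invisible(x)
}

#' Read a knowledge base from a directory of standard files
#'
#' Expects `ontology.obo`, `annotations.gaf`, `drug_targets.tsv` and
#' optionally `atc.tsv` in `dir` (the layout written by the fixture
#' generators).
#'
#' @param dir directory path.
#' @param exclude_evidence passed to [parse_gaf()].
#' @param actions passed to [parse_drug_targets()].
#' @return an `ftc_kb`.
#' @export
read_kb <- function(dir, exclude_evidence = NULL, actions = NULL) {
  graph <- parse_obo(file.path(dir, "ontology.obo"))
  ann <- parse_gaf(file.path(dir, "annotations.gaf"), graph,
                   exclude_evidence = exclude_evidence)
  dt <- parse_drug_targets(file.path(dir, "drug_targets.tsv"),
                           actions = actions)
  atc_path <- file.path(dir, "atc.tsv")
  atc <- if (file.exists(atc_path)) parse_atc(atc_path) else NULL
  assemble_kb(graph, ann, dt$drugs, dt$links, atc = atc)
}
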
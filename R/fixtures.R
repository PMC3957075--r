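# Synthetic knowledge-base generators. Both emit the five external files the
# parsers consume (OBO ontology, GAF annotations, drug-target TSV, ATC TSV,
# evaluation-point TSV) plus a constructively known ground truth, so the
# classifier can be falsified rather than checked against itself.

gaf_line <- function(protein_id, symbol, qualifier, term_id, evidence) {
  paste(c("UniProtKB", protein_id, symbol, qualifier, term_id,
          "GO_REF:0000001", evidence, "", "P", symbol, "", "protein",
          "taxon:9606", "20130101", "UniProt", "", ""),
        collapse = "\t")
}

#' Minimal worked-example fixture (ximelagatran / prothrombin)
#'
#' Emits the smallest complete knowledge base exercising the regulator
#' pattern: one drug (ximelagatran, DB04898) inhibiting one protein
#' (prothrombin, P00734) annotated to "positive regulation of blood
#' coagulation" (GO:0030194), which positively regulates "blood coagulation"
#' (GO:0007596). The inhibitor sign (-1) composed with the positive
#' regulation (+1) classifies the drug as an anti-blood coagulation agent.
#'
#' @param dir directory to write into (created; default a fresh tempdir).
#' @param action action term for the link, default `"inhibitor"`; passing
#'   `"agonist"` flips the expected polarity to pro-.
#' @return object of class `ftc_fixture`: list with `dir`, `files` (named
#'   paths) and `ground_truth` (data.frame `drug_id`, `category_id`).
#' @export
make_figure1_fixture <- function(dir = tempfile("ftc_fig1_"),
                                 action = "inhibitor") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  terms <- data.frame(
    term_id = c("GO:0007596", "GO:0030194"),
    label = c("blood coagulation",
              "positive regulation of blood coagulation"),
    namespace = "biological_process", obsolete = FALSE,
    stringsAsFactors = FALSE)
  edges <- data.frame(child = "GO:0030194", parent = "GO:0007596",
                      relation = "positively_regulates",
                      stringsAsFactors = FALSE)
  files <- c(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    atc = file.path(dir, "atc.tsv"),
    evaluation_points = file.path(dir, "evaluation_points.tsv"))
  write_obo_file(terms, edges, files[["ontology"]])
  writeLines(c("!gaf-version: 2.1",
               gaf_line("P00734", "THRB", "", "GO:0030194", "IDA")),
             files[["annotations"]])
  write_tsv(data.frame(drug_id = "DB04898", drug_name = "ximelagatran",
                       protein_id = "P00734", action_term = action,
                       stringsAsFactors = FALSE),
            files[["drug_targets"]])
  write_tsv(data.frame(drug_id = "DB04898", atc_code = "B01AE05",
                       stringsAsFactors = FALSE), files[["atc"]])
  write_tsv(data.frame(ftc_id = "FTC_A0007596", atc_code = "B01AE",
                       comment = "direct thrombin inhibitors",
                       stringsAsFactors = FALSE),
            files[["evaluation_points"]])
  sign <- switch(action, inhibitor = -1L, agonist = 1L, NA_integer_)
  gt <- if (is.na(sign)) {
    data.frame(drug_id = character(), category_id = character(),
               stringsAsFactors = FALSE)
  } else {
    # inhibitor(-1) x positively_regulates(+1) -> anti; agonist -> pro
    data.frame(drug_id = "DB04898",
               category_id = paste0("FTC_", if (sign < 0) "A" else "P",
                                    "0007596"),
               stringsAsFactors = FALSE)
  }
  structure(list(dir = dir, files = files, ground_truth = gt),
            class = "ftc_fixture")
}

#' Generate a seeded random knowledge base with planted ground truth
#'
#' Builds a GO-like ontology as a rank-layered DAG (terms only point to
#' earlier terms of the same namespace, so acyclicity holds by construction),
#' attaches regulation terms with signed `regulates`-family edges (chains at
#' most two deep), annotates proteins, links drugs with signed actions, and
#' writes everything through the same file formats the real pipeline reads.
#' The expected direct memberships are derived constructively from the
#' planted chains by generator-local code, not by the classifier.
#'
#' With `n_clusters > 0`, drugs are grouped into clusters sharing a core set
#' of inhibitor links to cluster-specific proteins/terms and a cluster-wide
#' ATC first-level letter, planting both a MoA-similarity block structure and
#' matching evaluation points (one per cluster).
#'
#' @param seed integer seed; the same seed yields byte-identical files.
#' @param dir output directory (default a fresh tempdir).
#' @param n_terms total number of ontology terms (default 30).
#' @param regulation_fraction fraction of terms that are regulation terms
#'   (default 0.3).
#' @param n_proteins number of background proteins (default 10).
#' @param n_drugs number of drugs (default 8; 0 is valid).
#' @param links_per_drug background links per drug (default 2).
#' @param n_clusters number of planted drug clusters (default 0 = none).
#' @param cluster_core_size core targets shared within each cluster
#'   (default 3).
#' @param n_obsolete obsolete decoy terms (default 1).
#' @return an `ftc_fixture`: list with `dir`, `files`, `ground_truth`
#'   (data.frame `drug_id`, `category_id` of expected direct memberships)
#'   and `atc_labels` (named vector of planted first-level classes, clusters
#'   only).
#' @export
generate_random_kb <- function(seed, dir = tempfile("ftc_kb_"),
                               n_terms = 30L, regulation_fraction = 0.3,
                               n_proteins = 10L, n_drugs = 8L,
                               links_per_drug = 2L, n_clusters = 0L,
                               cluster_core_size = 3L, n_obsolete = 1L) {
  if (n_terms < 1L || n_proteins < 1L || n_drugs < 0L ||
      regulation_fraction < 0 || regulation_fraction > 1)
    stop("infeasible fixture spec: sizes must be positive and ",
         "regulation_fraction in [0, 1]")
  n_reg <- round(n_terms * regulation_fraction)
  n_base <- n_terms - n_reg - n_obsolete
  if (n_base < 1L)
    stop("infeasible fixture spec: no base terms left (n_terms too small ",
         "for regulation_fraction / n_obsolete)")
  if (n_clusters > 0L && n_clusters * cluster_core_size > n_base)
    stop("infeasible fixture spec: not enough base terms for the ",
         "requested clusters")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  res <- with_preserved_seed(as.integer(seed), {
    base_ids <- sprintf("GO:%07d", 1000000L + seq_len(n_base))
    n_bp <- max(1L, round(0.7 * n_base))
    base_ns <- rep(c("biological_process", "molecular_function"),
                   c(n_bp, n_base - n_bp))
    base_lab <- ifelse(base_ns == "biological_process",
                       sprintf("process %d", seq_len(n_base)),
                       sprintf("function %d", seq_len(n_base)))
    # hierarchy: each term (after the first of its namespace block) points
    # to 1-2 earlier terms of the same namespace
    hier <- list()
    for (ns in unique(base_ns)) {
      blk <- which(base_ns == ns)
      for (j in seq_along(blk)[-1]) {
        np <- sample.int(min(2L, j - 1L), 1L)
        parents <- blk[sample.int(j - 1L, np)]
        rel <- sample(c("is_a", "part_of"), np, replace = TRUE,
                      prob = c(0.85, 0.15))
        hier[[length(hier) + 1L]] <- data.frame(
          child = base_ids[blk[j]], parent = base_ids[parents],
          relation = rel, stringsAsFactors = FALSE)
      }
    }
    # regulation terms; reg-of-reg only targets depth-1 regulation terms so
    # chains never exceed the default composition depth of 2
    reg_ids <- if (n_reg) sprintf("GO:%07d", 2000000L + seq_len(n_reg))
      else character()
    reg_target <- character(n_reg); reg_sign <- integer(n_reg)
    reg_depth <- integer(n_reg); reg_lab <- character(n_reg)
    reg_edges <- list()
    sign_word <- c("-1" = "negative regulation of",
                   "0" = "regulation of", "1" = "positive regulation of")
    lab_of <- stats::setNames(base_lab, base_ids)
    for (i in seq_len(n_reg)) {
      shallow <- which(reg_depth[seq_len(i - 1L)] == 1L)
      use_reg <- length(shallow) > 0 && stats::runif(1) < 0.25
      tgt <- if (use_reg) reg_ids[shallow[sample.int(length(shallow), 1L)]]
        else base_ids[sample.int(n_base, 1L)]
      s <- sample(c(-1L, 0L, 1L), 1L, prob = c(0.45, 0.10, 0.45))
      rel <- names(REGULATION_SIGN)[match(s, REGULATION_SIGN)]
      reg_target[i] <- tgt; reg_sign[i] <- s
      reg_depth[i] <- if (use_reg) 2L else 1L
      reg_lab[i] <- paste(sign_word[as.character(s)], lab_of[tgt])
      lab_of[reg_ids[i]] <- reg_lab[i]
      reg_edges[[i]] <- data.frame(child = reg_ids[i], parent = tgt,
                                   relation = rel, stringsAsFactors = FALSE)
    }
    obso_ids <- if (n_obsolete) sprintf("GO:%07d",
                                        3000000L + seq_len(n_obsolete))
      else character()
    terms <- rbind(
      data.frame(term_id = base_ids, label = base_lab, namespace = base_ns,
                 obsolete = FALSE, stringsAsFactors = FALSE),
      if (n_reg) data.frame(term_id = reg_ids, label = reg_lab,
                            namespace = "biological_process",
                            obsolete = FALSE, stringsAsFactors = FALSE),
      if (n_obsolete) data.frame(term_id = obso_ids,
                                 label = sprintf("defunct term %d",
                                                 seq_len(n_obsolete)),
                                 namespace = "biological_process",
                                 obsolete = TRUE, stringsAsFactors = FALSE))
    edges <- do.call(rbind, c(hier, reg_edges))
    if (is.null(edges))
      edges <- data.frame(child = character(), parent = character(),
                          relation = character(), stringsAsFactors = FALSE)

    # proteins annotated to random non-obsolete terms
    prot_ids <- sprintf("P%05d", seq_len(n_proteins))
    annotatable <- c(base_ids, reg_ids)
    ann <- list()
    for (p in prot_ids) {
      k <- sample.int(2L, 1L)
      for (t in sample(annotatable, k))
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = p, term_id = t, stringsAsFactors = FALSE)
    }

    # cluster scaffolding
    cluster_of <- integer(0)
    core_prot <- list(); core_term <- list()
    if (n_clusters > 0L) {
      if (n_drugs < n_clusters)
        stop("infeasible fixture spec: fewer drugs than clusters")
      pool <- sample(base_ids, n_clusters * cluster_core_size)
      for (c in seq_len(n_clusters)) {
        idx <- ((c - 1L) * cluster_core_size + 1L):(c * cluster_core_size)
        core_term[[c]] <- pool[idx]
        core_prot[[c]] <- sprintf("PC%03d%02d", c,
                                  seq_len(cluster_core_size))
        for (k in seq_len(cluster_core_size))
          ann[[length(ann) + 1L]] <- data.frame(
            protein_id = core_prot[[c]][k], term_id = core_term[[c]][k],
            stringsAsFactors = FALSE)
      }
      cluster_of <- rep(seq_len(n_clusters), length.out = n_drugs)
    }

    drug_ids <- if (n_drugs) sprintf("DB%05d", seq_len(n_drugs))
      else character()
    noise_actions <- c("inhibitor", "agonist", "activator", "antagonist",
                       "binder")
    links <- list(); atc <- list()
    for (i in seq_len(n_drugs)) {
      if (n_clusters > 0L) {
        c <- cluster_of[i]
        for (p in core_prot[[c]])
          links[[length(links) + 1L]] <- data.frame(
            drug_id = drug_ids[i], protein_id = p,
            action_term = "inhibitor", stringsAsFactors = FALSE)
        # one unsigned (inert) noise link so cluster drugs share their whole
        # signed MoA profile: the planted overlap stays maximal
        links[[length(links) + 1L]] <- data.frame(
          drug_id = drug_ids[i],
          protein_id = sample(prot_ids, 1L),
          action_term = "binder",
          stringsAsFactors = FALSE)
        atc[[length(atc) + 1L]] <- data.frame(
          drug_id = drug_ids[i],
          atc_code = sprintf("%s01AA%02d", LETTERS[c], i),
          stringsAsFactors = FALSE)
      } else {
        for (p in sample(prot_ids, min(links_per_drug, n_proteins)))
          links[[length(links) + 1L]] <- data.frame(
            drug_id = drug_ids[i], protein_id = p,
            action_term = sample(noise_actions, 1L),
            stringsAsFactors = FALSE)
        if (stats::runif(1) < 0.8)
          atc[[length(atc) + 1L]] <- data.frame(
            drug_id = drug_ids[i],
            atc_code = sprintf("%s01AA%02d", sample(LETTERS[1:4], 1L), i),
            stringsAsFactors = FALSE)
      }
    }
    list(terms = terms, edges = edges,
         ann = unique(do.call(rbind, c(ann, list(NULL)))),
         links = if (length(links)) unique(do.call(rbind, links)) else
           data.frame(drug_id = character(), protein_id = character(),
                      action_term = character(), stringsAsFactors = FALSE),
         atc = if (length(atc)) do.call(rbind, atc) else
           data.frame(drug_id = character(), atc_code = character(),
                      stringsAsFactors = FALSE),
         drug_ids = drug_ids, cluster_of = cluster_of,
         core_term = core_term,
         reg = data.frame(term_id = reg_ids, target = reg_target,
                          sign = reg_sign, stringsAsFactors = FALSE))
  })

  gt <- constructive_ground_truth(res)

  files <- c(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    atc = file.path(dir, "atc.tsv"),
    evaluation_points = file.path(dir, "evaluation_points.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv"))
  write_obo_file(res$terms, res$edges, files[["ontology"]])
  ann <- res$ann[order(res$ann$protein_id, res$ann$term_id), , drop = FALSE]
  writeLines(c("!gaf-version: 2.1",
               mapply(gaf_line, ann$protein_id, ann$protein_id, "",
                      ann$term_id, "IDA", USE.NAMES = FALSE)),
             files[["annotations"]])
  links <- res$links
  links$drug_name <- if (nrow(links))
    paste0("drug ", sub("^DB0*", "", links$drug_id)) else character()
  links <- links[order(links$drug_id, links$protein_id, links$action_term),
                 c("drug_id", "drug_name", "protein_id", "action_term")]
  write_tsv(links, files[["drug_targets"]])
  write_tsv(res$atc[order(res$atc$drug_id, res$atc$atc_code), , drop = FALSE],
            files[["atc"]])
  eval_pts <- if (length(res$core_term)) {
    do.call(rbind, lapply(seq_along(res$core_term), function(c)
      data.frame(ftc_id = paste0("FTC_A",
                                 substr(res$core_term[[c]][1], 4, 10)),
                 atc_code = LETTERS[c],
                 comment = sprintf("planted cluster %d", c),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(ftc_id = character(), atc_code = character(),
               comment = character(), stringsAsFactors = FALSE)
  }
  write_tsv(eval_pts, files[["evaluation_points"]])
  write_tsv(gt, files[["ground_truth"]])

  atc_labels <- if (length(res$cluster_of))
    stats::setNames(LETTERS[res$cluster_of], res$drug_ids) else
      stats::setNames(character(0), character(0))
  structure(list(dir = dir, files = files, ground_truth = gt,
                 atc_labels = atc_labels),
            class = "ftc_fixture")
}

# Expected direct memberships, derived from the planted structure with
# generator-local lookups (no classifier code).
constructive_ground_truth <- function(res) {
  local_sign <- c(inhibitor = -1L, antagonist = -1L,
                  agonist = 1L, activator = 1L)
  reg <- res$reg
  is_reg <- function(t) t %in% reg$term_id
  rows <- list()
  if (nrow(res$links)) {
    for (i in seq_len(nrow(res$links))) {
      act <- res$links$action_term[i]
      if (!(act %in% names(local_sign))) next
      p <- local_sign[[act]]
      terms_hit <- res$ann$term_id[res$ann$protein_id ==
                                     res$links$protein_id[i]]
      for (t in terms_hit) {
        if (!is_reg(t)) {
          pol <- p; base <- t
        } else {
          j <- match(t, reg$term_id)
          s <- reg$sign[j]; base <- reg$target[j]
          if (is_reg(base)) {            # two-step chain
            k <- match(base, reg$term_id)
            s <- s * reg$sign[k]; base <- reg$target[k]
          }
          if (s == 0L) next
          pol <- p * s
        }
        rows[[length(rows) + 1L]] <- data.frame(
          drug_id = res$links$drug_id[i],
          category_id = paste0("FTC_", if (pol > 0) "P" else "A",
                               substr(base, 4, 10)),
          stringsAsFactors = FALSE)
      }
    }
  }
  gt <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(drug_id = character(), category_id = character(),
               stringsAsFactors = FALSE)
  gt <- gt[order(gt$drug_id, gt$category_id), , drop = FALSE]
  rownames(gt) <- NULL
  gt
}

#' @export
print.ftc_fixture <- function(x, ...) {
  cat("ftc_fixture in", x$dir, "-", nrow(x$ground_truth),
      "planted direct memberships\n")
  invisible(x)
}
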
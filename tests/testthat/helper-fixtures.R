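# Hand-written 12-term toy ontology (written as raw OBO text, independent of
# the package's own OBO writer). Eight non-obsolete non-regulation terms,
# three regulation terms, one obsolete decoy.
toy_obo_text <- function() {
  c("format-version: 1.2",
    "ontology: toy-go",
    "",
    "[Term]",
    "id: GO:0007596",
    "name: blood coagulation",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000010",
    "name: blood coagulation-like process",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000020",
    "name: plasminogen activation cascade-like",
    "namespace: biological_process",
    "is_a: GO:0000010 ! blood coagulation-like process",
    "",
    "[Term]",
    "id: GO:0042730",
    "name: fibrinolysis",
    "namespace: biological_process",
    "is_a: GO:0000020 ! plasminogen activation cascade-like",
    "",
    "[Term]",
    "id: GO:0000030",
    "name: coagulation subprocess",
    "namespace: biological_process",
    "relationship: part_of GO:0007596 ! blood coagulation",
    "",
    "[Term]",
    "id: GO:0030194",
    "name: positive regulation of blood coagulation",
    "namespace: biological_process",
    "relationship: positively_regulates GO:0007596 ! blood coagulation",
    "",
    "[Term]",
    "id: GO:0043084",
    "name: penile erection",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0060407",
    "name: negative regulation of penile erection",
    "namespace: biological_process",
    "relationship: negatively_regulates GO:0043084 ! penile erection",
    "",
    "[Term]",
    "id: GO:0050000",
    "name: regulation of blood coagulation",
    "namespace: biological_process",
    "relationship: regulates GO:0007596 ! blood coagulation",
    "",
    "[Term]",
    "id: GO:0008900",
    "name: hydrogen:potassium-exchanging ATPase activity",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0001540",
    "name: amyloid-beta binding",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0099999",
    "name: old defunct term",
    "namespace: biological_process",
    "is_obsolete: true",
    "")
}

toy_obo_path <- function() {
  path <- tempfile("toy_", fileext = ".obo")
  writeLines(toy_obo_text(), path)
  path
}

# expected adjacency of the toy file, hand-written
toy_expected_edges <- function() {
  e <- data.frame(
    child = c("GO:0000020", "GO:0042730", "GO:0000030", "GO:0030194",
              "GO:0060407", "GO:0050000"),
    parent = c("GO:0000010", "GO:0000020", "GO:0007596", "GO:0007596",
               "GO:0043084", "GO:0007596"),
    relation = c("is_a", "is_a", "part_of", "positively_regulates",
                 "negatively_regulates", "regulates"),
    stringsAsFactors = FALSE)
  e[order(e$child, e$parent, e$relation), ]
}

toy_graph <- function() parse_obo(toy_obo_path())

# Build an ftc_kb directly in code from compact tables.
inline_kb <- function(graph, links, annotations, atc = NULL) {
  drugs <- data.frame(drug_id = sort(unique(links$drug_id)),
                      stringsAsFactors = FALSE)
  drugs$name <- drugs$drug_id
  links$sign <- map_action_to_sign(links$action_term)
  links <- links[order(links$drug_id, links$protein_id, links$action_term), ]
  annotations$evidence_code <- "IDA"
  annotations$qualifier <- ""
  assemble_kb(graph, annotations, drugs, links, atc = atc)
}

membership_keys <- function(m)
  sort(paste(m$drug_id, m$category_id, m$kind))
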
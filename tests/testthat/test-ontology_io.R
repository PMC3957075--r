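test_that("parse_obo reads the smallest DAG and the toy fixture faithfully", {
  p <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: X:0000001", "name: X",
               "namespace: biological_process", "is_a: X:0000002", "",
               "[Term]", "id: X:0000002", "name: Y",
               "namespace: biological_process", ""), p)
  g <- parse_obo(p)
  expect_equal(nrow(g$terms), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$relation, "is_a")

  toy <- toy_graph()
  expect_equal(nrow(toy$terms), 12L)
  got <- toy$edges[order(toy$edges$child, toy$edges$parent,
                         toy$edges$relation), ]
  rownames(got) <- NULL
  want <- toy_expected_edges()
  rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(
    toy$edges$relation[toy$edges$child == "GO:0030194"],
    "positively_regulates")
})

test_that("obsolete terms are recorded but excluded from edges and categories", {
  toy <- toy_graph()
  expect_true(toy$terms$obsolete[toy$terms$term_id == "GO:0099999"])
  expect_false("GO:0099999" %in% c(toy$edges$child, toy$edges$parent))
  cats <- generate_categories(toy)
  expect_false(any(grepl("0099999", cats$category_id)))
})

test_that("unrecognized OBO relations are dropped with a warning", {
  p <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:0000001", "name: a",
               "namespace: biological_process",
               "relationship: has_part X:0000002", "",
               "[Term]", "id: X:0000002", "name: b",
               "namespace: biological_process", ""), p)
  expect_warning(g <- parse_obo(p), "has_part")
  expect_equal(nrow(g$edges), 0L)
})

test_that("a hierarchy cycle is rejected naming a cycle member", {
  p <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:0000001", "name: a",
               "namespace: biological_process", "is_a: X:0000002", "",
               "[Term]", "id: X:0000002", "name: b",
               "namespace: biological_process", "is_a: X:0000001", ""), p)
  expect_error(parse_obo(p), "cycle.*X:000000[12]")
})

test_that("parse_gaf keeps good rows and drops NOT / unknown-term rows with counts", {
  toy <- toy_graph()
  gaf <- tempfile()
  row <- function(prot, qual, go)
    paste(c("UniProtKB", prot, prot, qual, go, "GO_REF:0000001", "IDA",
            "", "P", "", "", "protein", "taxon:9606", "20130101",
            "UniProt", "", ""), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("P00734", "", "GO:0030194"),
               row("P11111", "NOT", "GO:0007596"),
               row("P22222", "", "GO:9999999")), gaf)
  ann <- parse_gaf(gaf, toy)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$protein_id, "P00734")
  expect_equal(ann$term_id, "GO:0030194")
  dc <- attr(ann, "drop_counts")
  expect_equal(unname(dc["not_qualifier"]), 1L)
  expect_equal(unname(dc["unknown_term"]), 1L)

  bad <- tempfile()
  writeLines("only\tthree\tcolumns", bad)
  expect_error(parse_gaf(bad, toy), "line 1")
})

test_that("evidence-code filtering is off by default and opt-in", {
  toy <- toy_graph()
  gaf <- tempfile()
  row <- function(prot, ev)
    paste(c("UniProtKB", prot, prot, "", "GO:0007596", "GO_REF:0000001",
            ev, "", "P", "", "", "protein", "taxon:9606", "20130101",
            "UniProt", "", ""), collapse = "\t")
  writeLines(c(row("P1", "IEA"), row("P2", "IDA")), gaf)
  expect_equal(nrow(parse_gaf(gaf, toy)), 2L)
  kept <- parse_gaf(gaf, toy, exclude_evidence = "IEA")
  expect_equal(kept$protein_id, "P2")
  expect_equal(unname(attr(kept, "drop_counts")["evidence"]), 1L)
})

test_that("parse_drug_targets resolves signs, deduplicates, errors on missing column", {
  p <- tempfile()
  writeLines(c("drug_id\tdrug_name\tprotein_id\taction_term",
               "DB04898\tximelagatran\tP00734\tinhibitor",
               "DB04898\tximelagatran\tP00734\tinhibitor",
               "DB00001\tdrug one\tP00001\tagonist",
               "DB00002\tdrug two\tP00002\tbinder"), p)
  dt <- parse_drug_targets(p)
  expect_equal(nrow(dt$links), 3L)
  expect_equal(dt$links$sign[dt$links$drug_id == "DB04898"], -1L)
  expect_equal(dt$links$sign[dt$links$drug_id == "DB00001"], 1L)
  expect_true(is.na(dt$links$sign[dt$links$drug_id == "DB00002"]))
  expect_equal(nrow(dt$drugs), 3L)

  bad <- tempfile()
  writeLines("drug_id\tprotein_id", bad)
  expect_error(parse_drug_targets(bad), "missing column")
})

test_that("parse_atc round-trips codes and rejects malformed ones", {
  p <- tempfile()
  writeLines(c("drug_id\tatc_code", "DB00015\tB01AD07"), p)
  atc <- parse_atc(p)
  expect_equal(atc[["DB00015"]], "B01AD07")
  bad <- tempfile()
  writeLines(c("drug_id\tatc_code", "DB00001\tnot-a-code"), bad)
  expect_error(parse_atc(bad), "not-a-code")
})

test_that("evaluation points parse, group by category, and may be empty", {
  p <- tempfile()
  writeLines(c("ftc_id\tatc_code\tcomment",
               "FTC_A0008900\tA02BC\tproton pump inhibitors",
               "FTC_A0008900\tA02BD\tcombinations"), p)
  pts <- parse_evaluation_points(p)
  expect_length(pts, 1L)
  expect_equal(pts[[1]]$ftc_category_id, "FTC_A0008900")
  expect_equal(pts[[1]]$atc_codes, c("A02BC", "A02BD"))

  e <- tempfile()
  writeLines("ftc_id\tatc_code\tcomment", e)
  expect_length(parse_evaluation_points(e), 0L)
  fake_build <- classify(inline_kb(
    toy_graph(),
    data.frame(drug_id = "DB1", protein_id = "P1",
               action_term = "inhibitor", stringsAsFactors = FALSE),
    data.frame(protein_id = "P1", term_id = "GO:0007596",
               stringsAsFactors = FALSE)))
  rep <- evaluate_ftc(fake_build, list(), list())
  expect_true(rep$no_evaluation)
})

test_that("parsing is independent of input row and stanza order", {
  lines <- toy_obo_text()
  starts <- grep("^\\[Term\\]$", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  stanzas <- Map(function(s, e) lines[s:e], starts, ends)
  set.seed(7)
  shuffled <- c(lines[1:(starts[1] - 1L)],
                unlist(stanzas[sample(length(stanzas))]))
  p <- tempfile()
  writeLines(shuffled, p)
  expect_equal(parse_obo(p), toy_graph())

  rows <- c("DB2\tb\tP2\tagonist", "DB1\ta\tP1\tinhibitor",
            "DB3\tc\tP1\tbinder")
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("drug_id\tdrug_name\tprotein_id\taction_term", rows), p1)
  writeLines(c("drug_id\tdrug_name\tprotein_id\taction_term",
               rev(rows)), p2)
  expect_equal(parse_drug_targets(p1), parse_drug_targets(p2))
})

test_that("written taxonomy round-trips to an isomorphic DAG and metrics recount", {
  fx <- generate_random_kb(11, n_terms = 20, n_drugs = 5)
  kb <- read_kb(fx$dir)
  b <- classify(kb)
  out <- tempfile()
  paths <- write_ftc_build(b, out)
  g2 <- parse_obo(paths[["taxonomy"]])
  expect_setequal(g2$terms$term_id, b$taxonomy$categories$category_id)
  expect_setequal(paste(g2$edges$child, g2$edges$parent),
                  paste(b$taxonomy$edges$child, b$taxonomy$edges$parent))

  metrics <- jsonlite::read_json(paths[["metrics"]])
  t <- kb$graph$terms
  eligible <- !t$obsolete &
    t$namespace %in% c("biological_process", "molecular_function") &
    !is_regulation_term(kb$graph, t$term_id)
  expect_equal(metrics$n_categories, 2L * sum(eligible))

  # empty build still writes valid files
  kb0 <- assemble_kb(kb$graph, kb$annotations, kb$drugs[0, ], kb$links[0, ])
  p0 <- write_ftc_build(classify(kb0), tempfile())
  expect_equal(nrow(read.delim(p0[["memberships"]])), 0L)
  expect_s3_class(parse_obo(p0[["taxonomy"]]), "ontology_graph")
})

test_that("referential closure holds in assembled knowledge bases", {
  toy <- toy_graph()
  ann <- data.frame(protein_id = "P1", term_id = "GO:0099000",
                    evidence_code = "IDA", qualifier = "",
                    stringsAsFactors = FALSE)
  drugs <- data.frame(drug_id = "DB1", name = "d", stringsAsFactors = FALSE)
  links <- data.frame(drug_id = "DB1", protein_id = "P1",
                      action_term = "inhibitor", sign = -1L,
                      stringsAsFactors = FALSE)
  expect_error(assemble_kb(toy, ann, drugs, links), "unknown term")
  ann$term_id <- "GO:0007596"
  links$drug_id <- "DB9"
  expect_error(assemble_kb(toy, ann, drugs, links), "unknown drug")
})
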
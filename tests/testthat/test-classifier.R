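test_that("action terms map to signs case-insensitively with extensible table", {
  expect_equal(map_action_to_sign("inhibitor"), -1L)
  expect_equal(map_action_to_sign("AGONIST"), 1L)
  expect_true(is.na(map_action_to_sign("binder")))
  expect_equal(map_action_to_sign(c("blocker", "potentiator", "x")),
               c(-1L, 1L, NA))
  expect_equal(map_action_to_sign("binder", extra = c(binder = -1L)), -1L)
})

test_that("the regulator pattern composes link and regulation signs", {
  toy <- toy_graph()
  ann <- data.frame(protein_id = c("P1", "P2", "P3"),
                    term_id = c("GO:0030194",   # pos reg of blood coagulation
                                "GO:0042730",   # fibrinolysis (direct)
                                "GO:0060407"),  # neg reg of penile erection
                    stringsAsFactors = FALSE)
  links <- data.frame(
    drug_id = c("DBI1", "DBA2", "DBI3"),
    protein_id = c("P1", "P2", "P3"),
    action_term = c("inhibitor", "agonist", "inhibitor"),
    stringsAsFactors = FALSE)
  b <- classify(inline_kb(toy, links, ann))
  direct <- b$memberships[b$memberships$kind == "direct", ]
  # inhibitor x positive regulation -> anti
  expect_equal(direct$category_id[direct$drug_id == "DBI1"], "FTC_A0007596")
  # agonist on a directly annotated process -> pro
  expect_equal(direct$category_id[direct$drug_id == "DBA2"], "FTC_P0042730")
  # inhibitor x negative regulation -> pro (double negative)
  expect_equal(direct$category_id[direct$drug_id == "DBI3"], "FTC_P0043084")
})

test_that("neutral regulation and unknown actions are inert", {
  toy <- toy_graph()
  ann <- data.frame(protein_id = c("P1", "P2"),
                    term_id = c("GO:0050000", "GO:0007596"),
                    stringsAsFactors = FALSE)
  links <- data.frame(drug_id = c("DB1", "DB2"),
                      protein_id = c("P1", "P2"),
                      action_term = c("inhibitor", "binder"),
                      stringsAsFactors = FALSE)
  b <- classify(inline_kb(toy, links, ann))
  expect_equal(nrow(b$memberships), 0L)
})

test_that("ancestor closure is idempotent, disjoint from direct, and closed", {
  for (s in c(21, 22, 23)) {
    fx <- generate_random_kb(s, n_terms = 30, n_drugs = 8)
    b <- classify(read_kb(fx$dir))
    m <- b$memberships
    direct <- m[m$kind == "direct", ]
    indirect <- m[m$kind == "indirect", ]
    for (d in unique(m$drug_id)) {
      dd <- direct$category_id[direct$drug_id == d]
      ii <- indirect$category_id[indirect$drug_id == d]
      expect_length(intersect(dd, ii), 0L)
      anc <- taxonomy_ancestors(b$taxonomy, union(dd, ii))
      expect_true(all(unlist(anc) %in% union(dd, ii)))
    }
    again <- ancestor_closure(m, b$taxonomy)
    expect_true(all(paste(again$drug_id, again$category_id) %in%
                      paste(m$drug_id, m$category_id)))
  }
})

test_that("a drug direct only in a root has no indirect memberships", {
  toy <- toy_graph()
  tax <- build_taxonomy(generate_categories(toy), toy)
  direct <- data.frame(drug_id = "DB1", category_id = "FTC_P_ROOT_BP",
                       kind = "direct", provenance = "synthetic",
                       stringsAsFactors = FALSE)
  expect_equal(nrow(ancestor_closure(direct, tax)), 0L)
})

test_that("flipping every link sign flips every direct membership polarity", {
  fx <- generate_random_kb(31, n_terms = 30, n_drugs = 10)
  kb <- read_kb(fx$dir)
  b1 <- classify(kb)
  kb$links$sign <- -kb$links$sign
  b2 <- classify(kb)
  d1 <- b1$memberships[b1$memberships$kind == "direct", ]
  d2 <- b2$memberships[b2$memberships$kind == "direct", ]
  flip <- function(cid) chartr("PA", "AP", substr(cid, 1, 5)) |>
    paste0(substr(cid, 6, 12))
  expect_setequal(paste(d2$drug_id, d2$category_id),
                  paste(d1$drug_id, flip(d1$category_id)))
})

test_that("adding a link or annotation never removes a membership", {
  fx <- generate_random_kb(41, n_terms = 25, n_drugs = 6)
  kb <- read_kb(fx$dir)
  before <- membership_keys(classify(kb)$memberships)
  kb2 <- kb
  extra <- kb$links[1, ]
  extra$protein_id <- kb$annotations$protein_id[nrow(kb$annotations)]
  extra$action_term <- "agonist"; extra$sign <- 1L
  kb2$links <- unique(rbind(kb$links, extra))
  after <- membership_keys(classify(kb2)$memberships)
  expect_true(all(before %in% after))

  kb3 <- kb
  new_ann <- kb$annotations[1, ]
  new_ann$term_id <- "GO:1000001"
  kb3$annotations <- unique(rbind(kb$annotations, new_ann))
  after3 <- membership_keys(classify(kb3)$memberships)
  expect_true(all(before %in% after3))
})

test_that("classification is deterministic and matches the oracle on fixtures", {
  for (s in c(51, 52)) {
    fx <- generate_random_kb(s, n_terms = 30, n_drugs = 8,
                             n_clusters = s %% 3)
    kb <- read_kb(fx$dir)
    b1 <- classify(kb); b2 <- classify(kb)
    expect_identical(b1$memberships, b2$memberships)
    o <- brute_force_oracle(kb)
    expect_identical(b1$memberships[, c("drug_id", "category_id", "kind")],
                     o$memberships)
  }
})

test_that("every direct membership carries a complete provenance chain", {
  fx <- make_figure1_fixture()
  b <- classify(read_kb(fx$dir))
  direct <- b$memberships[b$memberships$kind == "direct", ]
  expect_true(all(grepl("-\\[[+-]1\\]-> .*annotated-to", direct$provenance)))
})

test_that("polypharmacology counts and summaries recount correctly", {
  fx <- generate_random_kb(61, n_terms = 30, n_drugs = 8, n_clusters = 2)
  kb <- read_kb(fx$dir)
  b <- classify(kb)
  pp <- polypharmacology_stats(b)
  m <- b$memberships
  for (i in seq_len(nrow(pp$per_drug))) {
    d <- pp$per_drug$drug_id[i]
    expect_equal(pp$per_drug$n_direct[i],
                 sum(m$drug_id == d & m$kind == "direct"))
    expect_equal(pp$per_drug$n_total[i], sum(m$drug_id == d))
  }
  cl <- pp$per_drug[pp$per_drug$n_direct > 0, ]
  expect_equal(unname(pp$summary$direct["mean"]), mean(cl$n_direct))
  expect_equal(unname(pp$summary$total["range"]),
               max(cl$n_total) - min(cl$n_total))
  # independent recount against the oracle's membership table
  o <- brute_force_oracle(kb)
  ot <- table(factor(o$memberships$drug_id, levels = b$drugs$drug_id))
  expect_equal(pp$per_drug$n_total, as.integer(ot))
})

test_that("classify on an empty drug list yields a full taxonomy, no memberships", {
  fx <- generate_random_kb(71, n_terms = 20, n_drugs = 0)
  kb <- read_kb(fx$dir)
  b <- classify(kb)
  expect_gt(nrow(b$taxonomy$categories), 4L)
  expect_equal(nrow(b$memberships), 0L)
})
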
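make_drug <- function(id, name, groups, targets_genes,
                      organism = "Humans", categories = character()) {
  list(drug_id = id, name = name, groups = groups, categories = categories,
       targets = data.frame(
         uniprot_id = sprintf("U%s%02d", id, seq_along(targets_genes)),
         organism = rep_len(organism, length(targets_genes)),
         gene_symbol = targets_genes, stringsAsFactors = FALSE))
}

test_that("drug XML parsing reports groups and survives a round trip", {
  drugs <- structure(list(
    make_drug("D1", "alpha", c("approved", "investigational"), c("HDAC1")),
    make_drug("D2", "bravo", "experimental", c("EZH2")),
    make_drug("D3", "charlie", "approved", character())),
    class = "drug_collection")
  p <- file.path(withr::local_tempdir(), "drugs.xml")
  write_drug_database_xml(drugs, p)
  parsed <- parse_drug_database(p)
  expect_length(parsed, 3)
  gc <- attr(parsed, "group_counts")
  expect_equal(sum(gc), 4)     # dual membership preserved
  expect_equal(unname(gc["approved"]), 2)
  # round trip: identical collection content
  for (i in 1:3) {
    expect_equal(parsed[[i]]$drug_id, drugs[[i]]$drug_id)
    expect_equal(parsed[[i]]$groups, drugs[[i]]$groups)
    expect_equal(parsed[[i]]$targets$uniprot_id, drugs[[i]]$targets$uniprot_id)
  }
  # drug without an id is skipped with a warning
  writeLines(c("<drugbank><drug><name>x</name></drug></drugbank>"), p)
  expect_warning(none <- parse_drug_database(p), class = "drug_skipped")
  expect_length(none, 0)
})

test_that("group and organism filtering follows the selection rules and is idempotent", {
  drugs <- structure(list(
    make_drug("D1", "alpha", "experimental", "HDAC1"),
    make_drug("D2", "bravo", c("approved", "investigational"), "HDAC1"),
    make_drug("D3", "charlie", "approved", c("HDAC1", "EZH2"),
              organism = c("Mouse", "Humans"))),
    class = "drug_collection")
  sel <- select_drugs(drugs)
  expect_length(sel, 2)                      # experimental excluded
  expect_equal(vapply(sel, `[[`, "", "name"), c("bravo", "charlie"))
  expect_equal(sel[[2]]$targets$gene_symbol, "EZH2")   # mouse target dropped
  expect_identical(select_drugs(sel), sel)   # idempotent
})

test_that("the interaction matrix encodes incidence with consistent marginals", {
  reg <- load_packaged_registry()
  drugs <- structure(list(
    make_drug("D1", "alpha", "approved", c("HDAC1", "EZH2", "NOPE1")),
    make_drug("D2", "bravo", "approved", c("HDAC1"))),
    class = "drug_collection")
  m <- build_interaction_matrix(drugs, reg)
  expect_equal(dim(m$matrix), c(2, 2))
  expect_equal(unname(m$enzyme_marginals["HDAC1"]), 2)
  expect_equal(m$total, 3)
  expect_equal(sum(m$drug_marginals), m$total)
  expect_equal(sum(m$enzyme_marginals), m$total)
  # all-decoy collection -> empty matrix
  decoy <- structure(list(make_drug("D9", "zulu", "approved", "NOPE9")),
                     class = "drug_collection")
  m0 <- build_interaction_matrix(decoy, reg)
  expect_equal(dim(m0$matrix), c(0, 0))
  expect_equal(m0$total, 0)
  expect_error(build_interaction_matrix(drugs,
                 structure(list(records = data.frame()),
                           class = "enzyme_registry")),
               class = "empty_registry")
})

test_that("the fostamatinib profile yields a row marginal of 20, all histone-substrate", {
  reg <- load_packaged_registry()
  m <- build_interaction_matrix(fostamatinib_record(n_decoys = 30), reg)
  expect_equal(unname(m$drug_marginals["Fostamatinib"]), 20)
  hit <- colnames(m$matrix)[m$matrix["Fostamatinib", ] == 1]
  actions <- reg$records$enzyme_action[match(hit, reg$records$gene_symbol)]
  expect_true(all(classify_substrate(actions) == "histone"))
})

test_that("the matrix equals the generator's planted truth cell-for-cell", {
  for (seed in c(1, 23, 99)) {
    d <- withr::local_tempdir()
    reg <- parse_enzyme_registry(
      generate_enzyme_registry(30, seed = seed, dir = d)$path)
    db <- generate_drug_database(35, reg, seed = seed, dir = d,
                                 overlap_fraction = 0.6)
    sel <- select_drugs(parse_drug_database(db$path))
    m <- build_interaction_matrix(sel, reg, id_map = read.delim(db$map_path))
    expect_identical(m$matrix, db$truth$matrix)
    expect_equal(m$total, db$truth$total)
    expect_equal(sum(m$drug_marginals), sum(m$enzyme_marginals))
  }
})

test_that("category histogram counts distinct drugs and applies the threshold", {
  mk <- function(i, cats) make_drug(sprintf("C%d", i), sprintf("drug%d", i),
                                    "approved", character(), categories = cats)
  drugs <- structure(c(
    lapply(1:6, mk, cats = "antineoplastic agents"),
    lapply(7:10, mk, cats = "rare category")),
    class = "drug_collection")
  h <- category_histogram(drugs, min_count = 5)
  expect_equal(h$category, "antineoplastic agents")
  expect_equal(h$n_drugs, 6)
  # duplicate category within one drug counted once
  dup <- structure(list(mk(1, c("x", "x"))), class = "drug_collection")
  expect_equal(category_histogram(dup, min_count = 1)$n_drugs, 1)
})

test_that("the 2x2 chi-square matches hand evaluation and the analytic oracle", {
  r <- two_by_two_chi_square(matrix(c(10, 20, 90, 80), 2))
  expect_equal(r$chi_square, 3.9216, tolerance = 1e-4)
  expect_equal(r$df, 1)
  # identical row proportions -> independence
  r0 <- two_by_two_chi_square(matrix(c(10, 20, 30, 60), 2))
  expect_equal(r0$chi_square, 0)
  expect_equal(r0$p_value, 1)
  expect_error(two_by_two_chi_square(matrix(c(0, 0, 5, 5), 2)),
               class = "zero_margin")
  set.seed(99)
  for (i in 1:1000) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2)
    got <- two_by_two_chi_square(tab)
    expect_equal(got$chi_square, oracle_chi_square(tab), tolerance = 1e-9)
    expect_equal(got$p_value,
                 stats::pchisq(oracle_chi_square(tab), 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("percentage bookkeeping matches the printed shares", {
  expect_equal(percentage_share(82, 2914), 2.81)
  expect_equal(percentage_share(3051, 109645), 2.78)
  expect_equal(percentage_share(15, 7213, digits = 1), 0.2)
  expect_equal(percentage_share(0, 100), 0)
  expect_error(percentage_share(1, 0), class = "domain_error")
})

test_that("coverage statistics aggregate counts and shares", {
  reg <- load_packaged_registry()
  drugs <- structure(list(
    make_drug("D1", "alpha", "approved", c("HDAC1", "EZH2"))),
    class = "drug_collection")
  m <- build_interaction_matrix(drugs, reg)
  cov <- coverage_statistics(drugs, m, reg, n_all_drugs = 500,
                             n_all_human_targets = 2914)
  expect_equal(cov$n_interacting_drugs, 1)
  expect_equal(cov$total_interactions, 2)
  expect_equal(cov$pct_interacting_drugs, 0.2)
  expect_equal(cov$pct_epigenetic_targets, percentage_share(2, 2914))
})
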
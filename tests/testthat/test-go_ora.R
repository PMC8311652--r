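write_obo <- function(lines) {
  p <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), p)
  p
}

chain_obo <- function() write_obo(c(
  "[Term]", "id: T:3", "name: root", "namespace: molecular_function", "",
  "[Term]", "id: T:2", "name: mid", "namespace: molecular_function",
  "is_a: T:3 ! root", "",
  "[Term]", "id: T:1", "name: leaf", "namespace: molecular_function",
  "is_a: T:2 ! mid", ""))

test_that("OBO parsing builds the DAG, drops obsolete terms and rejects cycles", {
  dag <- parse_ontology(chain_obo())
  expect_equal(nrow(dag$terms), 3)
  expect_equal(nrow(dag$edges), 2)
  expect_equal(dag_roots(dag), "T:3")

  p <- write_obo(c("[Term]", "id: T:1", "name: dead", "is_obsolete: true", "",
                   "[Term]", "id: T:2", "name: alive", ""))
  dag2 <- parse_ontology(p)
  expect_equal(dag2$terms$term_id, "T:2")

  p3 <- write_obo(c("[Term]", "id: T:1", "is_a: T:2", "",
                    "[Term]", "id: T:2", "is_a: T:1", ""))
  expect_error(parse_ontology(p3), class = "ontology_cycle")

  p4 <- write_obo(c("[Term]", "name: anonymous", "",
                    "[Term]", "id: T:9", ""))
  expect_warning(dag4 <- parse_ontology(p4), class = "obo_stanza_skipped")
  expect_equal(dag4$terms$term_id, "T:9")
})

test_that("generated ontologies round-trip their edge set", {
  gen <- generate_ontology_with_annotations(n_terms = 25, n_genes = 50,
                                            set_size = 10, seed = 13,
                                            dir = withr::local_tempdir())
  dag <- parse_ontology(gen$obo_path)
  got <- dag$edges[order(dag$edges$child, dag$edges$parent), ]
  want <- gen$truth$edges[order(gen$truth$edges$child,
                                gen$truth$edges$parent), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("true-path propagation matches brute-force reachability on random DAGs", {
  for (seed in c(4, 17, 31)) {
    gen <- generate_ontology_with_annotations(n_terms = 20, n_genes = 40,
                                              set_size = 10, seed = seed,
                                              p_background = 0.2,
                                              dir = withr::local_tempdir())
    dag <- parse_ontology(gen$obo_path)
    ann <- read.delim(gen$annotation_path)
    idx <- propagate_annotations(dag, ann, gen$truth$universe)
    direct <- lapply(split(ann$gene_id, ann$term_id), unique)
    direct <- direct[order(names(direct))]
    all_terms <- dag$terms$term_id
    prop_edges <- dag$edges[dag$edges$relation %in% c("is_a", "part_of"), ]
    for (t in all_terms) {
      want <- sort(oracle_propagated(prop_edges, direct, t, all_terms) %||%
                     character())
      expect_equal(sort(idx$propagated[[t]]), want, info = t)
    }
    # monotone child -> parent
    for (k in seq_len(nrow(prop_edges))) {
      expect_true(all(idx$propagated[[prop_edges$child[k]]] %in%
                        idx$propagated[[prop_edges$parent[k]]]))
    }
  }
})

test_that("propagation enforces the universe and warns on unknown terms", {
  dag <- parse_ontology(chain_obo())
  ann <- data.frame(gene_id = "g1", term_id = "T:1", evidence = "IDA")
  idx <- propagate_annotations(dag, ann, c("g1", "g2"))
  expect_equal(idx$propagated[["T:3"]], "g1")   # reaches the root
  expect_error(propagate_annotations(dag, ann, "g2"),
               class = "gene_outside_universe")
  bad <- rbind(ann, data.frame(gene_id = "g2", term_id = "T:99",
                               evidence = "IEA"))
  expect_warning(idx2 <- propagate_annotations(dag, bad, c("g1", "g2")),
                 class = "unknown_term_annotation")
  expect_equal(idx2$propagated[["T:1"]], "g1")
  # curated-only drops electronic annotations
  mix <- data.frame(gene_id = c("g1", "g2"), term_id = "T:1",
                    evidence = c("IDA", "IEA"))
  idx3 <- propagate_annotations(dag, mix, c("g1", "g2"), curated_only = TRUE)
  expect_equal(idx3$propagated[["T:1"]], "g1")
})

test_that("the Fisher test reproduces the enumerated example and oracle", {
  # universe of 10, term annotates 5, set of 4 all annotated
  dag <- parse_ontology(chain_obo())
  universe <- sprintf("g%02d", 1:10)
  ann <- data.frame(gene_id = universe[1:5], term_id = "T:1",
                    evidence = "IDA")
  idx <- propagate_annotations(dag, ann, universe)
  res <- run_ora(universe[1:4], idx, ora_config(min_genes_per_term = 2))
  r1 <- res[res$term_id == "T:1", ]
  expect_equal(r1$observed, 4)
  expect_equal(r1$expected, 2.0)
  expect_equal(r1$p_value, 10 / 210, tolerance = 1e-10)   # = 0.047619
  expect_equal(r1$p_value, oracle_fisher_two_sided(4, 0, 1, 5),
               tolerance = 1e-10)
})

test_that("Fisher p equals exhaustive hypergeometric enumeration for small universes", {
  set.seed(314)
  for (i in 1:200) {
    N <- sample(8:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    a <- sample(max(0, n - (N - K)):min(n, K), 1)
    tab <- matrix(c(a, n - a, K - a, N - n - (K - a)), 2)
    p_impl <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    expect_equal(p_impl, oracle_fisher_two_sided(a, n - a, K - a,
                                                 N - n - (K - a)),
                 tolerance = 1e-10,
                 info = sprintf("N=%d K=%d n=%d a=%d", N, K, n, a))
  }
})

test_that("Bonferroni correction, degenerate sets and directions behave", {
  dag <- parse_ontology(chain_obo())
  universe <- sprintf("g%02d", 1:10)
  ann <- data.frame(gene_id = universe[1:5], term_id = "T:1",
                    evidence = "IDA")
  idx <- propagate_annotations(dag, ann, universe)
  # gene_set = universe: observed equals expected, p = 1, direction none
  res <- run_ora(universe, idx, ora_config())
  expect_true(all(res$p_value == 1))
  expect_true(all(res$observed == res$expected))
  expect_true(all(res$direction == "none"))
  # Bonferroni multiplies by the number of tested terms and caps at 1
  res2 <- run_ora(universe[1:4], idx, ora_config())
  m <- attr(res2, "m_tested")
  expect_equal(res2$p_adjusted, pmin(1, res2$p_value * m))
  expect_true(all(res2$p_adjusted >= res2$p_value))
  expect_error(run_ora(c("gX"), idx, ora_config()),
               class = "gene_outside_universe")
  # every significant term is exactly one of over/under
  gen <- generate_ontology_with_annotations(n_terms = 40, n_genes = 200,
                                            set_size = 30, seed = 8,
                                            dir = withr::local_tempdir())
  dag2 <- parse_ontology(gen$obo_path)
  idx2 <- propagate_annotations(dag2, read.delim(gen$annotation_path),
                                gen$truth$universe)
  res3 <- run_ora(gen$truth$gene_set, idx2, ora_config(p_threshold = 0.05),
                  dag2)
  sig <- res3[res3$p_adjusted < 0.05, ]
  expect_true(all(sig$direction %in% c("over", "under")))
  expect_true(all(res3$direction[res3$p_adjusted >= 0.05] == "none"))
})

test_that("detail and headline roles match the exhaustive per-path oracle", {
  # single significant leaf on a chain: leaf is both detail and headline
  dag <- parse_ontology(chain_obo())
  res <- data.frame(term_id = c("T:1", "T:2", "T:3"),
                    n_annotated = c(3L, 5L, 10L), observed = c(3L, 3L, 4L),
                    expected = c(1.2, 2, 4),
                    p_value = c(1e-5, 0.5, 1), p_adjusted = c(3e-5, 1, 1),
                    direction = c("over", "none", "none"))
  roles <- annotate_dag_roles(res, dag, ora_config(), universe_size = 10)
  expect_equal(roles$results$is_detail, c(TRUE, FALSE, FALSE))
  expect_equal(roles$results$is_headline, c(TRUE, FALSE, FALSE))

  # no significant terms: everything structural
  res0 <- res; res0$direction <- "none"; res0$p_adjusted <- 1
  roles0 <- annotate_dag_roles(res0, dag, ora_config(), universe_size = 10)
  expect_false(any(roles0$results$is_detail))
  expect_false(any(roles0$results$is_headline))
  expect_true(all(roles0$report$nodes$class == "structural"))

  # random DAGs with planted enrichment: headlines equal the brute-force
  # maximization over every detail-to-root path
  for (seed in c(3, 21)) {
    gen <- generate_ontology_with_annotations(n_terms = 25, n_genes = 150,
                                              set_size = 25, seed = seed,
                                              odds_ratio = 10,
                                              dir = withr::local_tempdir())
    dag2 <- parse_ontology(gen$obo_path)
    idx2 <- propagate_annotations(dag2, read.delim(gen$annotation_path),
                                  gen$truth$universe)
    cfg <- ora_config(p_threshold = 0.05)
    res2 <- run_ora(gen$truth$gene_set, idx2, cfg, dag2)
    roles2 <- annotate_dag_roles(res2, dag2, cfg, universe_size = 150)
    rr <- roles2$results
    sig <- rr$term_id[rr$direction %in% c("over", "under")]
    prop_edges <- dag2$edges[dag2$edges$relation %in% c("is_a", "part_of"), ]
    # oracle details
    want_details <- sig[vapply(sig, function(t) {
      below <- dag2$terms$term_id[vapply(dag2$terms$term_id, function(u)
        t %in% oracle_ancestors(prop_edges, u), logical(1))]
      !any(below %in% sig)
    }, logical(1))]
    expect_setequal(rr$term_id[rr$is_detail], want_details)
    # oracle headlines: per-path argmax of remarkableness
    rmk <- stats::setNames(rr$remarkableness, rr$term_id)
    padj <- stats::setNames(rr$p_adjusted, rr$term_id)
    want_headlines <- character()
    for (dtl in want_details) {
      for (path in oracle_root_paths(prop_edges, dtl)) {
        cand <- path[path %in% sig]
        if (!length(cand)) next
        depth <- length(path) - match(cand, path)
        ord <- order(-rmk[cand], padj[cand], -depth)
        want_headlines <- c(want_headlines, cand[ord[1]])
      }
    }
    expect_setequal(rr$term_id[rr$is_headline], unique(want_headlines))
    # headlines are significant; every detail path holds >= 1 headline
    expect_true(all(rr$term_id[rr$is_headline] %in% sig))
  }
})

test_that("DOT export is deterministic and class-coded", {
  dag <- parse_ontology(chain_obo())
  res <- data.frame(term_id = c("T:1", "T:2", "T:3"),
                    n_annotated = c(3L, 5L, 10L), observed = c(3L, 0L, 4L),
                    expected = c(1.2, 2, 4),
                    p_value = c(1e-5, 1e-5, 1), p_adjusted = c(3e-5, 3e-5, 1),
                    direction = c("over", "under", "none"))
  roles <- annotate_dag_roles(res, dag, ora_config(), universe_size = 10)
  dot <- export_dag(roles$report)
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), 2)
  expect_equal(sum(grepl("shape=ellipse", dot)), 3)
  expect_true(any(grepl("fillcolor=yellow", dot)))   # headline present
  expect_identical(dot, export_dag(roles$report))    # byte-identical
})
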
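test_that("count matrix round-trips losslessly through TSV and MatrixMarket", {
  m <- expression_matrix(named_matrix(c(1, 3, 2, 4), 2, "G"))
  expect_identical(m$counts["G01", "S02"], 2)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, tsv, "tsv")
  expect_identical(read_counts(tsv, "tsv")$counts, m$counts)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_counts(m, mtx, "mtx")
  expect_identical(read_counts(mtx, "mtx")$counts, m$counts)
})

test_that("count validation rejects negatives, non-integers and empty samples", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G2\t-1\t4"), tsv)
  expect_error(read_counts(tsv, "tsv"), "G2.*S1", )
  expect_error(expression_matrix(named_matrix(c(1.5, 2, 3, 4), 2, "G")),
               "non-negative integers")
  expect_error(expression_matrix(named_matrix(c(1, 2, 0, 0), 2, "G")),
               "zero total count")
  dup <- named_matrix(1:4, 2, "G")
  rownames(dup) <- c("G01", "G01")
  expect_error(expression_matrix(dup), "duplicate gene ids")
})

test_that("lipid panel derives class totals and mol% and rejects bad labels", {
  conc <- named_matrix(c(1, 3), 2, "L")
  rownames(conc) <- c("CER(1)", "CER(2)")
  lp <- lipid_panel(conc, c("CER(1)" = "CER", "CER(2)" = "CER"))
  expect_equal(unname(lp$class_totals["CER", ]), 4, tolerance = 1e-9)
  expect_equal(unname(lp$composition["CER(1)", 1]), 25)
  expect_equal(unname(lp$composition["CER(2)", 1]), 75)
  expect_error(lipid_panel(conc, c("CER(1)" = "XYZ", "CER(2)" = "CER")),
               "allowed: FFA")
})

test_that("lipid class totals equal member sums and mol% sums to 100", {
  s <- generate_study(simulation_config(seed = 11, n_lipids = 60))
  lp <- s$lipids
  for (cl in rownames(lp$class_totals)) {
    member_sum <- colSums(lp$concentrations[lp$class == cl, , drop = FALSE])
    expect_equal(unname(lp$class_totals[cl, ]), unname(member_sum),
                 tolerance = 1e-9)
    comp_sum <- colSums(lp$composition[lp$class == cl, , drop = FALSE])
    expect_equal(unname(comp_sum), rep(100, ncol(lp$concentrations)),
                 tolerance = 1e-6)
  }
  expect_length(lipid_classes(), 13)
})

test_that("panel TSVs round-trip through read_panel", {
  s <- generate_study(simulation_config(seed = 5, n_genes = 50,
                                        n_lipids = 40, gene_module_size = 5,
                                        lipid_block_size = 5))
  lp_path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(s$lipids, lp_path)
  lp <- read_panel(lp_path, "lipid")
  expect_equal(lp$concentrations, s$lipids$concentrations, tolerance = 1e-12)
  expect_identical(lp$class, s$lipids$class)

  bio_path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(s$biomarkers, bio_path)
  expect_equal(read_panel(bio_path, "biomarker")$values,
               s$biomarkers$values, tolerance = 1e-12)

  meta_path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(s$metadata, meta_path)
  meta <- read_panel(meta_path, "metadata")
  expect_identical(meta$sample_id, s$metadata$sample_id)
  expect_identical(meta$group, s$metadata$group)
  expect_equal(meta$age, s$metadata$age)
})

test_that("GMT parsing handles members, duplicates and degenerate files", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB"), gmt)
  expect_identical(read_gmt(gmt)$S1, c("A", "B"))

  writeLines(c("S1\tdesc\tA\tA"), gmt)
  expect_warning(sets <- read_gmt(gmt), "duplicate members")
  expect_identical(sets$S1, "A")

  writeLines(character(), gmt)
  expect_length(read_gmt(gmt), 0)

  writeLines("S1\tdesc_only", gmt)
  expect_error(read_gmt(gmt), "line 1")

  writeLines(c("S1\td\tA\tB\tC", "S2\td\tB\tD"), gmt)
  rt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(read_gmt(gmt), rt)
  expect_identical(readLines(rt), readLines(gmt))
})

test_that("network round-trips through pair tables and GraphML", {
  nodes <- data.frame(id = c("G1", "G2", "L1"),
                      role = c("gene", "gene", "lipid"))
  edges <- data.frame(id1 = c("G1", "G1"), id2 = c("G2", "L1"),
                      r = c(0.9, -0.8), p = c(0.001, 0.002), n = c(10L, 10L),
                      pair_class = c("gene-gene", "gene-lipid"))
  net <- integrative_network(nodes, edges)

  prefix <- withr::local_tempfile()
  write_network(net, prefix, "tsv_pair")
  back <- read_network(prefix, "tsv_pair")
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges$r, net$edges$r, tolerance = 1e-5)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  back2 <- read_network(gml, "graphml")
  expect_setequal(back2$nodes$id, net$nodes$id)
  key <- function(e) paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  expect_setequal(key(back2$edges), key(net$edges))
  expect_equal(sort(back2$edges$r), sort(net$edges$r), tolerance = 1e-12)

  empty <- integrative_network(nodes[0, ], edges[0, ])
  write_network(empty, prefix, "tsv_pair")
  expect_equal(nrow(read_network(prefix, "tsv_pair")$edges), 0)
})

test_that("network validation rejects inconsistent structures", {
  nodes <- data.frame(id = c("G1", "L1"), role = c("gene", "lipid"))
  good <- data.frame(id1 = "G1", id2 = "L1", r = 0.9, p = 0.001, n = 10L,
                     pair_class = "gene-lipid")
  expect_s3_class(integrative_network(nodes, good), "integrative_network")
  bad_class <- transform(good, pair_class = "gene-gene")
  expect_error(integrative_network(nodes, bad_class), "pair_class")
  self <- transform(good, id2 = "G1")
  expect_error(integrative_network(nodes, self), "self-edges")
  weak <- transform(good, r = 0.3)
  expect_error(integrative_network(nodes, weak), "filter")
  lips <- data.frame(id = c("L1", "L2"), role = "lipid")
  ll <- data.frame(id1 = "L1", id2 = "L2", r = 0.9, p = 0.001, n = 10L,
                   pair_class = "gene-lipid")
  expect_error(integrative_network(lips, ll), "pair_class")
})
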
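# A small deterministic multi-omic fixture with one strongly coupled
# gene/lipid pair and independent noise elsewhere.
tiny_study <- function(seed = 81, n_genes = 40, n_lipids = 45, n = 12) {
  set.seed(seed)
  expr <- named_matrix(rnorm(n_genes * n), n_genes, "G")
  conc <- named_matrix(abs(rnorm(n_lipids * n, 10, 2)), n_lipids, "L")
  cls <- setNames(rep(lipid_classes(), length.out = n_lipids),
                  rownames(conc))
  bio <- named_matrix(abs(rnorm(2 * n, 100, 10)), 2, "M")
  list(expr = expr, lipids = lipid_panel(conc, cls),
       bio = biomarker_panel(bio))
}

fake_deg <- function(gene_ids, p) {
  res <- data.frame(gene_id = gene_ids, logFC = 0, t_mod = 0, p = p,
                    adj_p = bh_adjust(p), mean_expr = 0, tested = TRUE,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$gene_id), ]
  class(res) <- c("dge_result", "data.frame")
  res
}

test_that("a lipid equal to the only selected gene ranks first with r = 1", {
  st <- tiny_study()
  st$lipids$concentrations["L01", ] <- st$expr["G05", ] + 20
  deg <- fake_deg(rownames(st$expr),
                  c(rep(0.5, 4), 1e-6, rep(0.5, nrow(st$expr) - 5)))
  rk <- rank_lipids(st$expr, st$lipids, deg, network_config())
  expect_identical(rk$lipid_id[1], "L01")
  expect_equal(rk$mean_r[1], 1, tolerance = 1e-12)
  expect_equal(rk$rank[1], 1)
})

test_that("signed averaging cancels balanced correlations", {
  st <- tiny_study()
  y <- st$expr["G01", ]
  st$expr["G02", ] <- -y  # exactly anticorrelated pair
  st$lipids$concentrations["L03", ] <- y + 30
  deg <- fake_deg(rownames(st$expr),
                  c(1e-6, 1e-6, rep(0.5, nrow(st$expr) - 2)))
  rk <- rank_lipids(st$expr, st$lipids, deg, network_config())
  expect_equal(rk$mean_r[rk$lipid_id == "L03"], 0, tolerance = 1e-12)
  expect_equal(rk$n_genes_used[rk$lipid_id == "L03"], 2)
})

test_that("lipid ranking is invariant to sample order and unit rescaling", {
  s <- generate_study(simulation_config(seed = 82, n_genes = 300,
                                        n_lipids = 60,
                                        lipid_block_size = 10))
  deg <- run_dge(s$counts, s$metadata)
  nm <- attr(deg, "normalized")
  rk1 <- rank_lipids(nm, s$lipids, deg)
  perm <- sample(ncol(s$lipids$concentrations))
  scaled <- lipid_panel(s$lipids$concentrations[, perm] * 1000,
                        s$lipids$class)
  rk2 <- rank_lipids(nm, scaled, deg)
  expect_equal(rk1, rk2, tolerance = 1e-9)
})

test_that("the retained edge set matches exhaustive pairwise enumeration", {
  set.seed(83)
  n <- 14
  expr <- named_matrix(rnorm(2 * n), 2, "G")
  base <- rnorm(n)
  expr["G01", ] <- base + rnorm(n, sd = 0.3)
  conc <- named_matrix(abs(base * 2 + 10 + rnorm(n, sd = 0.3)), 1, "L")
  bio <- named_matrix(abs(base + 5 + rnorm(n, sd = 0.3)), 1, "M")
  lipids <- lipid_panel(conc, c(L01 = "CER"))
  markers <- biomarker_panel(bio)
  deg <- fake_deg(rownames(expr), c(1e-4, 1e-4))
  cfg <- network_config(n_top_lipids = 1)
  net <- suppressWarnings(suppressMessages(
    build_network(expr, lipids, markers, deg, config = cfg)))

  # independent enumeration over all allowed pairs with cor.test
  rows <- rbind(expr, conc, bio)
  roles <- c(gene = "G01", gene = "G02", lipid = "L01", biomarker = "M01")
  want <- list()
  ids <- rownames(rows)
  for (i in 1:3) for (j in (i + 1):4) {
    role_i <- names(roles)[i]; role_j <- names(roles)[j]
    if (!"gene" %in% c(role_i, role_j)) next
    orc <- oracle_pearson(rows[i, ], rows[j, ])
    if (abs(orc$r) > 0.5 && orc$p < 0.01)
      want[[length(want) + 1]] <- data.frame(
        id1 = min(ids[i], ids[j]), id2 = max(ids[i], ids[j]),
        r = orc$r, p = orc$p)
  }
  want <- do.call(rbind, want)
  want <- want[order(want$id1, want$id2), ]
  expect_equal(nrow(net$edges), nrow(want))
  expect_equal(net$edges$id1, want$id1)
  expect_equal(net$edges$id2, want$id2)
  expect_equal(net$edges$r, want$r, tolerance = 1e-12)
  expect_equal(net$edges$p, want$p, tolerance = 1e-12)
})

test_that("relaxed thresholds give the complete graph on allowed pairs", {
  st <- tiny_study(seed = 84, n_genes = 6, n_lipids = 13)
  deg <- fake_deg(rownames(st$expr), rep(1e-4, 6))
  cfg <- network_config(edge_r_threshold = 0, edge_p_threshold = 1,
                        n_top_lipids = 13)
  cfg$edge_p_threshold <- 1  # p < 1 keeps everything non-degenerate
  net <- build_network(st$expr, st$lipids, st$bio, deg, config = cfg)
  n_gene <- 6; n_lip <- 13; n_bio <- 2
  expect_equal(nrow(net$edges),
               choose(n_gene, 2) + n_gene * n_lip + n_gene * n_bio)
  expect_true(all(net$edges$pair_class %in%
                    c("gene-gene", "gene-lipid", "gene-biomarker")))
})

test_that("default configuration admits exactly 50 lipid candidates", {
  s <- generate_study(simulation_config(seed = 85))
  deg <- run_dge(s$counts, s$metadata)
  nm <- attr(deg, "normalized")
  rk <- rank_lipids(nm, s$lipids, deg)
  expect_equal(nrow(rk), 200)
  net <- build_network(nm, s$lipids, s$biomarkers, deg, rk)
  lipid_nodes <- net$nodes$id[net$nodes$role == "lipid"]
  expect_lte(length(lipid_nodes), 50)
  expect_true(all(lipid_nodes %in% rk$lipid_id[1:50]))
})

test_that("every retained edge satisfies the filter; forbidden pairs absent", {
  s <- generate_study(simulation_config(seed = 86, n_genes = 500,
                                        n_lipids = 60,
                                        lipid_block_size = 10))
  deg <- run_dge(s$counts, s$metadata)
  nm <- attr(deg, "normalized")
  net <- build_network(nm, s$lipids, s$biomarkers, deg)
  expect_true(all(abs(net$edges$r) > 0.5 & net$edges$p < 0.01))
  expect_true(all(net$edges$pair_class %in%
                    c("gene-lipid", "gene-biomarker", "gene-gene")))
  roles <- setNames(net$nodes$role, net$nodes$id)
  both <- cbind(roles[net$edges$id1], roles[net$edges$id2])
  expect_true(all(both[, 1] == "gene" | both[, 2] == "gene"))

  # byte-identical persistence across repeated builds
  net2 <- build_network(nm, s$lipids, s$biomarkers, deg)
  d1 <- withr::local_tempfile(); d2 <- withr::local_tempfile()
  write_network(net, d1, "tsv_pair"); write_network(net2, d2, "tsv_pair")
  expect_identical(readLines(paste0(d1, ".edges.tsv")),
                   readLines(paste0(d2, ".edges.tsv")))
})

test_that("anchor genes are kept even when isolated; missing anchors skipped", {
  st <- tiny_study(seed = 87)
  deg <- fake_deg(rownames(st$expr),
                  c(1e-6, 1e-6, rep(0.9, nrow(st$expr) - 2)))
  cfg <- network_config(anchor_genes = c("G40", "ABSENT"))
  expect_message(
    net <- suppressWarnings(
      build_network(st$expr, st$lipids, st$bio, deg, config = cfg)),
    "ABSENT")
  expect_true("G40" %in% net$nodes$id)
  expect_false("ABSENT" %in% net$nodes$id)
  expect_length(anchor_gene_panel(), 8)
})

test_that("network summaries report degrees and pair-class counts", {
  empty <- integrative_network(
    data.frame(id = character(), role = character()),
    data.frame(id1 = character(), id2 = character(), r = numeric(),
               p = numeric(), n = integer(), pair_class = character()))
  expect_equal(nrow(network_summary(empty)$degrees), 0)

  star_nodes <- data.frame(id = c("G01", "L01", "L02", "L03", "L04"),
                           role = c("gene", rep("lipid", 4)))
  star_edges <- data.frame(id1 = "G01", id2 = c("L01", "L02", "L03", "L04"),
                           r = 0.9, p = 1e-4, n = 10L,
                           pair_class = "gene-lipid")
  star <- network_summary(integrative_network(star_nodes, star_edges))
  expect_equal(star$degrees$degree, c(4, 1, 1, 1, 1))
  expect_identical(star$degrees$node_id[1], "G01")

  tri_nodes <- data.frame(id = c("G01", "G02", "G03"), role = "gene")
  tri_edges <- data.frame(id1 = c("G01", "G01", "G02"),
                          id2 = c("G02", "G03", "G03"),
                          r = 0.8, p = 1e-4, n = 10L,
                          pair_class = "gene-gene")
  tri <- network_summary(integrative_network(tri_nodes, tri_edges))
  expect_equal(tri$degrees$degree, c(2, 2, 2))
  expect_equal(
    tri$edge_counts$count[tri$edge_counts$pair_class == "gene-gene"], 3)
})
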
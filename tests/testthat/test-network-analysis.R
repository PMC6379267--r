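make_annotation <- function() {
  tibble::tibble(
    gene = c("CfA", "GrB", "OthC", "RegD", "OthE", "FarF"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(900000, 1100000, 1140000, 500000, 800000, 5000000),
    end = c(950000, 1150000, 1160000, 520000, 820000, 5010000),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "regulatory_other", "protein_coding", "protein_coding")
  )
}

test_that("marker annotation applies the window and the category priority", {
  ann <- make_annotation()
  markers <- tibble::tibble(
    marker = c("mA", "mB", "mC", "mD"),
    chrom = c("chr1", "chr2", "chr2", "chr3"),
    pos = c(1000000, 510000, 701000, 100))
  res <- annotate_markers(markers, ann, craniofacial = "CfA", growth = "GrB",
                          window = 200000)
  # mA: CfA at distance 50 kb, GrB at 100 kb, OthC at 140 kb -> Craniofacial
  expect_setequal(res$genes[[1]], c("CfA", "GrB", "OthC"))
  expect_identical(res$category[1], "Craniofacial")
  # mB: overlapping the regulatory element only -> Regulatory
  expect_identical(res$category[2], "Regulatory")
  # mC: within 200 kb of OthE (99 kb) -> Other
  expect_identical(res$category[3], "Other")
  # unknown chromosome: flagged with an empty list
  expect_true(res$unknown_chrom[4])
  expect_identical(res$n_genes[4], 0L)
  # window = 0 keeps only overlapping genes
  res0 <- annotate_markers(markers[1, ], ann, window = 0)
  expect_identical(res0$n_genes, 0L)
  # monotone in the window
  res100 <- annotate_markers(markers, ann, window = 100000)
  for (i in seq_len(nrow(markers))) {
    expect_true(all(res100$genes[[i]] %in% res$genes[[i]]))
  }
})

test_that("markers with identical gene lists merge into order-invariant regions", {
  ann <- make_annotation()
  markers <- tibble::tibble(
    marker = c("m1", "m2", "m3"),
    chrom = "chr1",
    pos = c(1000000, 1010000, 1400000))
  res <- annotate_markers(markers, ann, window = 200000)
  regions <- merge_markers(res)
  # m1 and m2 share {CfA, GrB, OthC}; m3 sees fewer genes
  expect_identical(nrow(regions), 2L)
  big <- regions[vapply(regions$markers, length, 1L) == 2L, ]
  expect_setequal(big$markers[[1]], c("m1", "m2"))
  expect_equal(big$start, 1000000)
  expect_equal(big$end, 1010000)
  # order invariance
  perm <- res[c(3, 1, 2), ]
  regions2 <- merge_markers(perm)
  expect_identical(regions$markers, regions2$markers)
})

test_that("the interaction graph collapses marker pairs onto region pairs", {
  regions <- tibble::tibble(
    region = c("R001", "R002", "R003"),
    chrom = "chr1", start = 1, end = 2,
    markers = list(c("m1", "m2"), "m3", "m4"),
    genes = list("a", "b", "c"),
    category = c("Craniofacial", "Growth", "Other"))
  inter <- tibble::tibble(
    marker_j = c("m1", "m2", "m3", "m1"),
    marker_k = c("m3", "m3", "m4", "m2"),
    significant = TRUE)
  g <- build_interaction_graph(inter, regions)
  expect_equal(igraph::vcount(g), 3)
  # m1-m3 and m2-m3 collapse to R001-R002 with weight 2
  e <- igraph::as_data_frame(g)
  w12 <- e$weight[(e$from == "R001" & e$to == "R002") |
                  (e$from == "R002" & e$to == "R001")]
  expect_equal(w12, 2)
  # the within-region m1-m2 pair is dropped
  expect_equal(igraph::graph_attr(g, "dropped_self"), 1)
  expect_equal(igraph::ecount(g), 2)
})

test_that("centralities match enumeration on canonical graphs", {
  tri <- igraph::make_ring(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  ct <- centralities(tri)
  expect_equal(ct$hub_score, rep(1, 3), tolerance = 1e-8)
  expect_equal(ct$betweenness, rep(0, 3))
  # path a-b-c: betweenness(b) = 1
  path <- igraph::make_graph(~ a - b, b - c)
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(sum(cp$betweenness[cp$node != "b"]), 0)
  # star with 4 leaves: centre betweenness C(4,2) = 6, hub score 1
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:4))
  cs <- centralities(star)
  expect_equal(cs$betweenness[cs$node == "hub"], 6)
  expect_equal(cs$hub_score[cs$node == "hub"], 1)
  expect_equal(length(unique(round(cs$hub_score[cs$node != "hub"], 10))), 1L)
  # complete graph: all betweenness zero
  cc <- centralities(igraph::make_full_graph(5))
  expect_true(all(cc$betweenness == 0))
  expect_error(centralities(igraph::make_empty_graph(0)), "Empty")
})

test_that("hub ranking equals eigenvector-centrality ranking on random graphs", {
  set.seed(42)
  for (r in 1:10) {
    g <- igraph::sample_gnp(12, 0.35)
    if (igraph::ecount(g) < 3) next
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    hub <- igraph::hits_scores(g)$hub
    eigc <- igraph::eigen_centrality(g)$vector
    expect_equal(order(hub), order(eigc))
  }
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:100)
  ref <- universe[1:50]
  cand <- c(universe[1:5], universe[51:55])  # 5 of 10 in the list
  res <- enrichment_test(cand, ref, universe)
  oracle <- sum(dhyper(5:10, 50, 50, 10))
  expect_equal(res$p, oracle, tolerance = 1e-10)
  # candidates = the whole reference list, universe twice the size
  res2 <- enrichment_test(ref, ref, universe)
  expect_lt(res2$p, 1e-6)
  expect_error(enrichment_test("x", ref, character()), "Empty")
  expect_error(enrichment_test("zzz", ref, universe), "subset")
})

test_that("category homogeneity reproduces the Pearson chi-square", {
  res <- category_homogeneity_test(c(30, 33, 43, 5), c(16, 23, 36, 5))
  expect_equal(res$chi2, 1.68, tolerance = 0.01)
  expect_equal(res$p, 0.64, tolerance = 0.01)
  expect_identical(res$df, 3L)
  expect_equal(category_homogeneity_test(c(10, 20, 30, 40),
                                         c(20, 40, 60, 80))$chi2, 0)
  # textbook-formula oracle on random tables
  set.seed(5)
  for (r in 1:5) {
    a <- rpois(4, 30) + 1
    b <- rpois(4, 20) + 1
    res_r <- category_homogeneity_test(a, b)
    tab <- rbind(a, b)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res_r$chi2, sum((tab - expd)^2 / expd), tolerance = 1e-10)
  }
  expect_error(category_homogeneity_test(c(0, 0, 1, 1), c(0, 0, 2, 2)),
               "pool")
})

test_that("annotation readers convert BED coordinates", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines(c("chr1\t999\t1500\tgeneA\tprotein_coding",
               "chr2\t0\t100\tgeneB\tregulatory_other"), bed)
  ann <- read_annotation(bed, format = "bed")
  expect_identical(ann$start, c(1000, 1))
  expect_identical(ann$end, c(1500, 100))
  lst <- file.path(dir, "list.txt")
  writeLines(c("geneA", "", " geneB "), lst)
  expect_identical(read_gene_list(lst), c("geneA", "geneB"))
})
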
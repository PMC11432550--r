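test_that("mutation distances count differing sites with gap-run collapsing", {
  expect_equal(mutation_distance_matrix(c(h1 = "AAA", h2 = "AAT"))[1, 2], 1L)
  expect_equal(mutation_distance_matrix(c(h1 = "AAA", h2 = "AAA"))[1, 2], 0L)
  ## a 2-gap run counts as a single step
  d <- mutation_distance_matrix(c(h1 = "AAAA", h2 = "A--A"))
  expect_equal(d[1, 2], 1L)
  dp <- mutation_distance_matrix(c(h1 = "AAAA", h2 = "A--A"),
                                 gap_mode = "position")
  expect_equal(dp[1, 2], 2L)
  ## unequal lengths are end-gap aligned first (3-bp deletion = 1 step)
  du <- mutation_distance_matrix(c(h1 = "ATGAAATTTCCC", h2 = "ATGTTTCCC"))
  expect_equal(du[1, 2], 1L)
  expect_error(mutation_distance_matrix(character(0)), "empty")
})

test_that("the MSN retains ties and contains a minimum spanning tree", {
  ## forced case: the weight-2 edge is redundant
  d <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3,
              dimnames = list(paste0("Hap", 1:3), paste0("Hap", 1:3)))
  net <- minimum_spanning_network(d)
  expect_equal(nrow(net), 2)
  expect_setequal(paste(net$hap_a, net$hap_b), c("Hap1 Hap2", "Hap1 Hap3"))
  expect_equal(sum(net$steps), enum_mst_weight(d))
  ## equilateral triangle: all three edges kept, spanning weight still 2
  deq <- matrix(1, 3, 3, dimnames = list(paste0("Hap", 1:3), paste0("Hap", 1:3)))
  diag(deq) <- 0
  neteq <- minimum_spanning_network(deq)
  expect_equal(nrow(neteq), 3)
  expect_equal(msn_spanning_weight(neteq, rownames(deq)), 2)
  ## two haplotypes: the single edge carries the distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(minimum_spanning_network(d2)$steps, 3)
  expect_error(minimum_spanning_network(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("MSN spanning weight equals brute-force MST weight on random graphs", {
  set.seed(4)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample(1:6, n * (n - 1) / 2, replace = TRUE)
    d <- d + t(d)
    dimnames(d) <- list(paste0("H", 1:n), paste0("H", 1:n))
    net <- minimum_spanning_network(d)
    expect_equal(msn_spanning_weight(net, rownames(d)), prim_mst_weight(d))
    if (n <= 5) expect_equal(prim_mst_weight(d), enum_mst_weight(d))
    ## each retained edge's steps equal the pairwise distance
    expect_true(all(net$steps == d[cbind(net$hap_a, net$hap_b)]))
    ## connectivity of the returned network
    g <- igraph::graph_from_data_frame(net[, 1:2], directed = FALSE,
                                       vertices = rownames(d))
    expect_true(igraph::is_connected(g))
  }
})

test_that("distinct distances give exactly the MST; relabeling is isomorphic", {
  set.seed(8)
  n <- 6
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- sample(seq(10, 150, 10), n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("H", 1:n), paste0("H", 1:n))
  net <- minimum_spanning_network(d)
  expect_equal(nrow(net), n - 1)  # a tree when all distances distinct
  expect_equal(sum(net$steps), prim_mst_weight(d))
  ## relabeled matrix gives the same edges modulo names
  perm <- sample(n)
  d2 <- d[perm, perm]
  net2 <- minimum_spanning_network(d2)
  key <- function(x) sort(paste(pmin(x$hap_a, x$hap_b), pmax(x$hap_a, x$hap_b)))
  expect_equal(key(net), key(net2))
})

test_that("gene networks carry population composition and export round-trips", {
  study <- small_sim_study()
  gchaps <- call_gchaps(study$reference, study$gene_models, study$variants,
                        study$panel)
  net <- build_hap_network(gchaps, study$panel, "g1")
  expect_s3_class(net, "hap_network")
  expect_equal(sum(net$nodes$n),
               sum(gchaps$haplotypes$n_carriers[gchaps$haplotypes$gene_id == "g1"]))
  expect_true(all(c("pop_Xian", "pop_Geng") %in% names(net$nodes)))
  expect_equal(rowSums(as.matrix(net$nodes[, c("pop_Xian", "pop_Geng")])),
               net$nodes$n, ignore_attr = TRUE)
  td <- withr::local_tempdir()
  files <- export_network(net, file.path(td, "net_g1"))
  ## GraphML round-trip preserves the edge set
  g <- igraph::read_graph(file.path(td, "net_g1.graphml"), format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  el <- readr::read_tsv(file.path(td, "net_g1.tsv"), show_col_types = FALSE)
  expect_equal(nrow(el), nrow(net$edges))
  expect_s3_class(autoplot(net), "ggplot")
})

test_that("a single-haplotype network exports a valid empty edge set", {
  fx <- counts_to_assignments(list(Xian = c(Hap1 = 10)))
  gchaps <- structure(list(
    assignments = fx$assignments,
    haplotypes = tibble::tibble(gene_id = "g1", hap_id = "Hap1",
                                hap_seq = "ATG", n_carriers = 10L, freq = 1),
    excluded = tibble::tibble(gene_id = character(), variety_id = character(),
                              reason = character())), class = "gchap_set")
  net <- build_hap_network(gchaps, fx$panel, "g1")
  expect_equal(nrow(net$edges), 0)
  td <- withr::local_tempdir()
  export_network(net, file.path(td, "solo"))
  el <- readr::read_tsv(file.path(td, "solo.tsv"), show_col_types = FALSE)
  expect_equal(nrow(el), 0)
})
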
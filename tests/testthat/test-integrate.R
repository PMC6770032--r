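toy_network_inputs <- function() {
  ids <- sprintf("s%d", 1:6)
  samples <- data.frame(sample_id = ids, tissue = "tumor",
                        age_years = (1:6) + 0.1, stringsAsFactors = FALSE)
  mirna <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                  dimnames = list("m1", ids))
  gene <- rbind(gA = c(6, 5, 4, 3, 2, 1),
                gB = c(1.1, 2.2, 2.9, 4.2, 5.1, 6.3))
  colnames(gene) <- ids
  targets <- data.frame(mirna = c("m1", "m1"), gene = c("gA", "gB"),
                        stringsAsFactors = FALSE)
  list(mirna = mirna, gene = gene, samples = samples, targets = targets)
}

test_that("perfect anti-correlation is retained; positive tracking is not", {
  x <- toy_network_inputs()
  net <- build_integration_network(x$mirna, x$gene, "m1", x$targets,
                                   x$samples)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$gene, "gA")
  expect_equal(net$edges$rho, -1)
  expect_identical(net$mirna_nodes, "m1")
})

test_that("edge sets equal the brute-force double-loop filter", {
  set.seed(13)
  for (i in 1:10) {
    n_s <- 10; n_m <- 5; n_g <- 8
    ids <- sprintf("s%02d", 1:n_s)
    samples <- data.frame(sample_id = ids, tissue = "tumor",
                          age_years = seq_len(n_s) + runif(n_s, 0, 0.5),
                          stringsAsFactors = FALSE)
    mirna <- matrix(rnorm(n_m * n_s), n_m, n_s,
                    dimnames = list(sprintf("m%d", 1:n_m), ids))
    gene <- matrix(rnorm(n_g * n_s), n_g, n_s,
                   dimnames = list(sprintf("g%d", 1:n_g), ids))
    # random many-to-many target table
    targets <- unique(data.frame(
      mirna = sample(rownames(mirna), 12, replace = TRUE),
      gene = sample(rownames(gene), 12, replace = TRUE),
      stringsAsFactors = FALSE))
    cand <- sample(rownames(mirna), 3)
    alpha <- runif(1, 0.05, 0.5)
    net <- suppressWarnings(suppressMessages(
      build_integration_network(mirna, gene, cand, targets, samples,
                                alpha = alpha)))
    ref <- brute_edges(mirna, gene, cand, targets, ids, alpha)
    expect_identical(sort(paste(net$edges$mirna, net$edges$gene)), ref)
  }
})

test_that("raising alpha never removes edges; shrinking targets never adds", {
  set.seed(14)
  n_s <- 12
  ids <- sprintf("s%02d", 1:n_s)
  samples <- data.frame(sample_id = ids, tissue = "tumor",
                        age_years = seq_len(n_s), stringsAsFactors = FALSE)
  mirna <- matrix(rnorm(4 * n_s), 4, n_s,
                  dimnames = list(sprintf("m%d", 1:4), ids))
  gene <- matrix(rnorm(10 * n_s), 10, n_s,
                 dimnames = list(sprintf("g%d", 1:10), ids))
  targets <- expand.grid(mirna = rownames(mirna), gene = rownames(gene),
                         stringsAsFactors = FALSE)
  cand <- rownames(mirna)
  key <- function(net) paste(net$edges$mirna, net$edges$gene)
  prev <- character(0)
  for (alpha in c(0.05, 0.2, 0.5, 0.9)) {
    net <- suppressWarnings(
      build_integration_network(mirna, gene, cand, targets, samples,
                                alpha = alpha))
    expect_true(all(prev %in% key(net)))
    prev <- key(net)
  }
  full <- suppressWarnings(
    build_integration_network(mirna, gene, cand, targets, samples,
                              alpha = 0.5))
  sub <- suppressWarnings(suppressMessages(
    build_integration_network(mirna, gene, cand,
                              targets[seq_len(20), ], samples, alpha = 0.5)))
  expect_true(all(key(sub) %in% key(full)))
})

test_that("retained edges are negative, significant and unique; nodes touch edges", {
  co <- simulate_cohort(sim_config_small(seed = 2))
  sc <- screen(correlate_matrix(co$mirna, co$samples, "tumor"),
               correlate_matrix(co$mirna, co$samples, "normal"))
  net <- suppressMessages(build_integration_network(
    co$mirna, co$gene, sc$tumor_specific_candidates, co$targets, co$samples))
  expect_true(all(net$edges$rho < 0))
  expect_true(all(net$edges$p < net$alpha))
  expect_equal(anyDuplicated(paste(net$edges$mirna, net$edges$gene)), 0L)
  expect_setequal(net$mirna_nodes, unique(net$edges$mirna))
  expect_setequal(net$gene_nodes, unique(net$edges$gene))
  # bipartite: no candidate id among gene nodes
  expect_length(intersect(net$mirna_nodes, net$gene_nodes), 0)
})

test_that("planted repression pairs of candidate miRNAs are recovered as edges", {
  hits <- c()
  for (seed in 1:5) {
    co <- simulate_cohort(sim_config_small(seed = seed))
    sc <- screen(correlate_matrix(co$mirna, co$samples, "tumor"),
                 correlate_matrix(co$mirna, co$samples, "normal"))
    net <- suppressMessages(suppressWarnings(build_integration_network(
      co$mirna, co$gene, sc$tumor_specific_candidates, co$targets,
      co$samples)))
    planted <- co$truth$repression
    planted <- planted[planted$mirna %in% sc$tumor_specific_candidates, ]
    if (nrow(planted) == 0L) next
    key <- paste(net$edges$mirna, net$edges$gene)
    hits <- c(hits, paste(planted$mirna, planted$gene) %in% key)
  }
  expect_gte(mean(hits), 0.8)
})

test_that("exports count edges correctly and GraphML round-trips", {
  x <- toy_network_inputs()
  # two retained edges: make gB anti-correlated as well
  x$gene["gB", ] <- c(5.5, 6.2, 4.1, 3.3, 1.9, 1.2)
  net <- build_integration_network(x$mirna, x$gene, "m1", x$targets,
                                   x$samples)
  expect_equal(nrow(net$edges), 2L)
  d <- withr::local_tempdir()

  sif <- file.path(d, "net.sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 2L)
  expect_true(file.exists(file.path(d, "net_edge_attributes.tsv")))

  gml <- file.path(d, "net.graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_equal(nrow(back$nodes), length(net$mirna_nodes) + length(net$gene_nodes))
  ord <- match(paste(net$edges$mirna, net$edges$gene),
               paste(back$edges$mirna, back$edges$gene))
  expect_equal(back$edges$rho[ord], net$edges$rho, tolerance = 1e-9)

  expect_error(export_network(net, file.path(d, "x.bin"), "xlsx"),
               "supported formats", class = "agemirnet_usage_error")
})

test_that("an empty network warns but exports valid files", {
  x <- toy_network_inputs()
  x$gene["gA", ] <- c(1, 2, 3, 4, 5, 6)  # positive tracking only
  x$targets <- x$targets[1, , drop = FALSE]
  expect_warning(
    net <- build_integration_network(x$mirna, x$gene, "m1", x$targets,
                                     x$samples),
    "empty network")
  d <- withr::local_tempdir()
  gml <- file.path(d, "empty.graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_equal(nrow(back$nodes), 0L)
  expect_equal(nrow(back$edges), 0L)
})
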
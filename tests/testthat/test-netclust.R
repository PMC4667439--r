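test_that("correlation graphs match a brute-force all-pairs scan", {
  base <- c(1, 2, 3, 4, 5)
  m <- rbind(a = base, b = base * 2 + 1, c = rev(base))
  colnames(m) <- paste0("s", 1:5)
  g <- correlationGraph(m, min_r = 0.85)
  expect_identical(nrow(g@edges), 1L)           # only a-b
  expect_equal(g@edges$weight, 1)
  expect_false(any(g@edges$from == "c" | g@edges$to == "c"))  # r = -1
  ## zero-variance genes are excluded with a warning
  m2 <- rbind(m, flat = rep(2, 5))
  expect_warning(g2 <- correlationGraph(m2, 0.85), "zero-variance")
  expect_false("flat" %in% g2@nodes)
  ## brute force on random genes + threshold monotonicity
  set.seed(21)
  mr <- matrix(rnorm(50 * 8), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  gg <- correlationGraph(mr, 0.5)
  cc <- cor(t(mr))
  brute <- which(upper.tri(cc) & cc >= 0.5)
  expect_identical(nrow(gg@edges), length(brute))
  for (k in seq_len(nrow(gg@edges)))
    expect_gte(cc[gg@edges$from[k], gg@edges$to[k]], 0.5)
  g_hi <- correlationGraph(mr, 0.7)
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(g_hi@edges) %in% key(gg@edges)))
})

test_that("MCL separates obvious cluster structure", {
  tri <- function(p) data.frame(from = p[c(1, 1, 2)], to = p[c(2, 3, 3)],
                                weight = 1)
  g <- CorrelationGraph(nodes = letters[1:6],
                        edges = rbind(tri(letters[1:3]), tri(letters[4:6])),
                        minR = 0.85)
  cs <- mcl(g)
  expect_length(clusters(cs), 2L)
  expect_setequal(lengths(clusters(cs)), c(3L, 3L))
  expect_length(unassigned(cs), 0L)
  ## single edge: one cluster of two
  g2 <- CorrelationGraph(nodes = c("x", "y"),
                         edges = data.frame(from = "x", to = "y",
                                            weight = 0.9),
                         minR = 0.85)
  cs2 <- mcl(g2)
  expect_identical(lengths(clusters(cs2)), 2L)
  ## isolated node lands in unassigned
  g3 <- CorrelationGraph(nodes = c("x", "y", "z"),
                         edges = data.frame(from = "x", to = "y",
                                            weight = 0.9),
                         minR = 0.85)
  expect_identical(unassigned(mcl(g3)), "z")
})

test_that("MCL clusters refine connected components", {
  set.seed(33)
  for (i in 1:5) {
    n <- 25
    nodes <- paste0("n", 1:n)
    npairs <- t(utils::combn(n, 2))
    sel <- npairs[runif(nrow(npairs)) < 0.12, , drop = FALSE]
    edges <- data.frame(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                        weight = runif(nrow(sel), 0.85, 1))
    g <- CorrelationGraph(nodes = nodes, edges = edges, minR = 0.85)
    cs <- mcl(g)
    ## partition covers the node set
    expect_setequal(c(unlist(clusters(cs)), unassigned(cs)), nodes)
    ## every cluster sits inside one connected component
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = nodes)
    comp <- igraph::components(ig)$membership
    for (cl in clusters(cs))
      expect_length(unique(comp[cl]), 1L)
  }
})

test_that("the SOM trains deterministically and organizes identical input", {
  set.seed(2)
  pops <- cxPopulations()
  ## all genes identical: everything maps to a single unit
  one <- matrix(rep(rnorm(10), each = 30), 30, 10,
                dimnames = list(paste0("g", 1:30),
                                paste0(rep(pops, each = 2), "_R", 1:2)))
  sg <- somTrain(one, population = rep(pops, each = 2), n_units = 9,
                 iterations = 500, seed = 4)
  expect_length(unique(somAssignment(sg)), 1L)
  ## determinism under a fixed seed
  zm <- matrix(rnorm(60 * 10), 60, 10,
               dimnames = list(paste0("g", 1:60),
                               paste0(rep(pops, each = 2), "_R", 1:2)))
  s1 <- somTrain(zm, n_units = 25, iterations = 800, seed = 7)
  s2 <- somTrain(zm, n_units = 25, iterations = 800, seed = 7)
  expect_identical(somAssignment(s1), somAssignment(s2))
  expect_false(identical(
    somAssignment(s1),
    somAssignment(somTrain(zm, n_units = 25, iterations = 800, seed = 8))))
  ## quantization error on structured profiles: improves over training
  ## and never degrades much between checkpoints (online updates are
  ## stochastic, hence the small slack)
  sim <- generateRNA(n_genes = 300, n_sig = 40, n_modules = 2,
                     reps_per_group = 2, seed = 12)
  zs <- zTransform(log2(pmax(
    SummarizedExperiment::assay(normalizeCounts(sim$counts)), 1)))
  st <- somTrain(zs, population = populations(sim$counts),
                 n_units = 25, iterations = 4000, seed = 3)
  qe <- st@qeHistory
  expect_length(qe, 10L)
  expect_lt(qe[10], qe[1])
  expect_true(all(diff(qe) <= 0.02 * qe[1]))
  ## fewer genes than units warns
  expect_warning(somTrain(zm[1:5, ], n_units = 25, iterations = 50,
                          seed = 1), "fewer genes")
})

test_that("network modules recover a noiseless two-block planted partition", {
  set.seed(14)
  f1 <- rnorm(20); f2 <- rnorm(20)
  b1 <- outer(runif(60, 0.5, 2), f1)        # scaled copies: r = 1 inside
  b2 <- outer(runif(60, 0.5, 2), f2)
  m <- rbind(b1, b2) + 5
  rownames(m) <- paste0("g", 1:120)
  colnames(m) <- paste0("s", 1:20)
  ms <- wcna(m, power = 7, min_module = 30, mediss = 0.3)
  expect_length(modules(ms), 2L)
  expect_setequal(lengths(modules(ms)), c(60L, 60L))
  truth <- rep(1:2, each = 60)
  found <- rep(NA_integer_, 120)
  for (k in seq_along(modules(ms)))
    found[match(modules(ms)[[k]], rownames(m))] <- k
  expect_equal(randIndex(truth, found), 1)
  ## eigengene of a coherent module correlates perfectly with members
  eg <- eigengenes(ms)[, 1]
  members <- modules(ms)[[1]]
  cors <- abs(cor(t(m[members, ]), eg))
  expect_true(all(cors > 0.999))
  ## merging with mediss = 0 is a no-op
  ms0 <- wcna(m, power = 7, min_module = 30, mediss = 0)
  expect_identical(lengths(modules(ms0)), lengths(modules(ms)))
  ## degenerate input errors with gene names
  m2 <- m; m2[3, ] <- 7
  expect_error(wcna(m2, power = 7, min_module = 30), "g3")
})

test_that("effector-cluster selection maximizes the specificity score", {
  pops <- cxPopulations()
  ## profiles stated per population (naive last in the constructed matrix)
  profA <- c(NAIVE = -1.5, CX3CR1P_CD62LHI = 1.2, CX3CR1P_CD62LLO = 1.1,
             CX3CR1N_CD62LHI = -0.2, CX3CR1N_CD62LLO = -0.3)
  profB <- c(NAIVE = -1.0, CX3CR1P_CD62LHI = 0.5, CX3CR1P_CD62LLO = 0.5,
             CX3CR1N_CD62LHI = 0.5, CX3CR1N_CD62LLO = -0.5)
  gmz <- rbind(matrix(rep(profA, each = 3), 3, 5,
                      dimnames = list(paste0("a", 1:3), names(profA))),
               matrix(rep(profB, each = 3), 3, 5,
                      dimnames = list(paste0("b", 1:3), names(profB))))
  sel <- selectEffectorCluster(list(A = paste0("a", 1:3),
                                    B = paste0("b", 1:3)), gmz)
  expect_identical(sel$genes, paste0("a", 1:3))
  expect_equal(sel$score, 1.1 - (-0.2))     # min(CX3+) - max(others)
  expect_equal(sort(sel$scores), sort(c(1.3, 0)))
  ## single cluster: returned as-is
  one <- selectEffectorCluster(list(only = paste0("a", 1:3)), gmz)
  expect_identical(one$genes, paste0("a", 1:3))
  ## ties break to the larger cluster
  gmz2 <- rbind(gmz, matrix(rep(profA, each = 2), 2, 5,
                            dimnames = list(paste0("c", 1:2),
                                            names(profA))))
  tie <- selectEffectorCluster(list(small = paste0("c", 1:2),
                                    big = paste0("a", 1:3)), gmz2)
  expect_identical(tie$genes, paste0("a", 1:3))
})

test_that("the planted effector module is the one selected", {
  hits <- 0
  for (s in 1:5) {
    sim <- generateRNA(n_genes = 500, n_sig = 50, n_modules = 2,
                       reps_per_group = 5, seed = 300 + s)
    em <- normalizeCounts(sim$counts)
    l2 <- log2(pmax(SummarizedExperiment::assay(em), 1))
    ms <- wcna(l2, power = 7, min_module = 30, mediss = 0.3)
    gmz <- cx3sig:::groupMeanZ(l2, populations(em))
    sel <- selectEffectorCluster(ms, gmz)
    sg <- signatureGenes(sim$truth)
    if (mean(sg %in% sel$genes) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 5 * 0.95 - 1)  # allow one miss in five runs
})
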
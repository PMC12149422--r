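test_that("soft-threshold selection stays inside the grid and degrades gracefully", {
  spec <- cohort_spec(n_genes = 300L, module_sizes = c(100L, 100L))
  set.seed(1)
  ge <- generate_expression(spec, rnorm(60))
  st <- suppressWarnings(pick_soft_threshold(ge$expr))
  expect_true(st$beta %in% 1:20)
  expect_true(any(!is.na(st$rsq_by_power)))
  # raising beta never increases an off-diagonal adjacency (|r| <= 1)
  a1 <- st$cor_mat^2; a2 <- st$cor_mat^6
  expect_true(all(a2 <= a1 + 1e-12))
  # near-orthogonal genes: fallback to the max-R^2 path without exception
  set.seed(2)
  noise <- matrix(rnorm(40 * 60), 40, 60)
  rownames(noise) <- paste0("g", 1:40)
  expect_error(st2 <- suppressWarnings(pick_soft_threshold(noise)), NA)
  expect_true(st2$beta %in% 1:20)
  # constant gene refused
  bad <- noise; bad[1, ] <- 5
  expect_error(suppressWarnings(pick_soft_threshold(bad)), "zero-variance")
})

test_that("TOM matches its definition on hand-built and random graphs", {
  # two genes connected only to each other with full weight
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  tom <- tom_matrix(a)
  expect_equal(tom[1, 2], 1)
  # uniform 0.5 adjacency on 4 nodes: off-diagonal 0.5 by symmetry
  a2 <- matrix(0.5, 4, 4); diag(a2) <- 0
  tom2 <- tom_matrix(a2)
  expect_true(all(abs(tom2[upper.tri(tom2)] - 0.5) < 1e-12))
  # zero adjacency: identity
  a3 <- matrix(0, 5, 5)
  expect_equal(tom_matrix(a3), diag(5))
  # brute-force triple-sum oracle on random 5-node valid adjacencies
  set.seed(3)
  for (rep in 1:5) {
    r <- matrix(runif(25, -1, 1), 5); r <- (r + t(r)) / 2
    a <- abs(r)^4; diag(a) <- 0
    expect_equal(tom_matrix(a), oracle_tom(a), tolerance = 1e-12)
    tm <- tom_matrix(a)
    expect_true(all(tm >= 0 & tm <= 1))
    expect_equal(tm, t(tm), tolerance = 1e-12)
  }
  expect_error(tom_matrix(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(tom_matrix(matrix(c(1, 0, 0, 1), 2)), "zero diagonal")
  expect_error(tom_matrix(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
})

make_planted_tom <- function(seed = 4, n_samples = 80) {
  spec <- cohort_spec(n_genes = 320L, module_sizes = c(110L, 100L),
                      module_loading = 0.9)
  set.seed(seed)
  ge <- generate_expression(spec, rnorm(n_samples))
  cm <- abs(cor(t(ge$expr)))
  adj <- cm^6; diag(adj) <- 0
  tom <- tom_matrix(adj)
  rownames(tom) <- colnames(tom) <- rownames(ge$expr)
  list(tom = tom, truth = ge$module_truth, expr = ge$expr)
}

test_that("module detection recovers planted structure and is order invariant", {
  pt <- make_planted_tom()
  det <- detect_modules(pt$tom, min_module_size = 100L)
  expect_gte(oracle_ari(pt$truth, det$modules), 0.8)
  # permuting gene order yields the same partition
  per <- sample(nrow(pt$tom))
  det2 <- detect_modules(pt$tom[per, per], min_module_size = 100L)
  expect_equal(oracle_ari(det$modules, det2$modules[names(det$modules)]), 1)
  # duplicate gene rows are each other's closest neighbours in TOM space
  expr <- pt$expr[1:50, ]
  expr <- rbind(expr, dup = expr[1, ])
  cm <- abs(cor(t(expr))); adj <- cm^6; diag(adj) <- 0
  tomd <- tom_matrix(adj)
  off <- tomd[1, -1]
  expect_equal(unname(which.max(off)), 50L)   # the duplicate (row 51)
  hc <- hclust(as.dist(1 - tomd), method = "average")
  expect_equal(unname(cutree(hc, k = 50)[1]), unname(cutree(hc, k = 50)[51]))
})

test_that("module labels follow descending size with grey leftovers", {
  pt <- make_planted_tom()
  det <- detect_modules(pt$tom, min_module_size = 100L)
  sizes <- table(det$modules)
  named <- sizes[setdiff(names(sizes), "grey")]
  expect_true("turquoise" %in% names(named))
  if (length(named) > 1)
    expect_gte(named[["turquoise"]], max(named[setdiff(names(named), "turquoise")]))
})

test_that("module-trait selection finds the planted trait-linked module", {
  spec <- cohort_spec(module_trait_cor = -0.5)
  set.seed(5)
  trait <- rnorm(100)
  ge <- generate_expression(spec, trait)
  ma <- coexpression_analysis(ge$expr, data.frame(radscore = trait))
  sel_genes <- names(ma$modules)[ma$modules == ma$selected_module]
  planted1 <- names(ge$module_truth)[ge$module_truth == "planted1"]
  expect_gt(length(intersect(sel_genes, planted1)) / length(planted1), 0.5)
  r_sel <- ma$module_trait$r[ma$module_trait$module == ma$selected_module &
                               ma$module_trait$trait == "radscore"]
  expect_equal(r_sel, -0.5, tolerance = 0.15)
  expect_output(print(ma), "Selected module")
  # p-values agree with an independent correlation test
  for (i in seq_len(nrow(ma$module_trait))) {
    row <- ma$module_trait[i, ]
    ct <- cor.test(ma$eigengenes[, row$module], trait)
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }
  # trait sign flip leaves |r| and p unchanged
  ma2 <- module_trait(ge$expr, ma$modules, data.frame(radscore = -trait))
  expect_equal(abs(ma2$module_trait$r), abs(ma$module_trait$r), tolerance = 1e-12)
  expect_equal(ma2$module_trait$p, ma$module_trait$p, tolerance = 1e-12)
})

test_that("an unlinked trait is not called significant at 0.001", {
  spec <- cohort_spec(module_trait_cor = 0)
  set.seed(6)
  ge <- generate_expression(spec, rnorm(100))
  ma <- coexpression_analysis(ge$expr, data.frame(radscore = rnorm(100)))
  pmin_ <- min(ma$module_trait$p[ma$module_trait$trait == "radscore"])
  expect_gt(pmin_, 0.001)
})

test_that("eigengenes are unit-norm and oriented toward their members", {
  pt <- make_planted_tom()
  det <- detect_modules(pt$tom, min_module_size = 100L)
  eg <- module_eigengenes(pt$expr, det$modules)
  for (m in colnames(eg)) {
    expect_equal(sum(eg[, m]^2), 1, tolerance = 1e-10)
    members <- pt$expr[names(det$modules)[det$modules == m], , drop = FALSE]
    expect_gt(mean(cor(eg[, m], t(members))), 0)
  }
})

test_that("hub genes follow degree ranking with lexicographic ties", {
  # star graph: the centre is hub number one
  edges <- data.frame(a = rep("gC", 4), b = paste0("g", 1:4))
  hubs <- hub_genes(c("gC", paste0("g", 1:4)), edges = edges)
  expect_equal(hubs[1], "gC")
  # degrees (4,3,2,1,1) -> top-2 are the degree-4 and degree-3 genes
  e2 <- data.frame(a = c("g1", "g1", "g1", "g1", "g2", "g2", "g3"),
                   b = c("g2", "g3", "g4", "g5", "g3", "g4", "g5"))
  expect_equal(hub_genes(paste0("g", 1:5), edges = e2), c("g1", "g2"))
  # an isolated extra gene changes nothing
  expect_equal(hub_genes(paste0("g", 1:6), edges = e2), c("g1", "g2"))
  # no-match edge list: warning, adjacency fallback
  adj <- matrix(0.1, 3, 3, dimnames = list(paste0("h", 1:3), paste0("h", 1:3)))
  adj["h2", "h3"] <- adj["h3", "h2"] <- 0.9
  expect_warning(hb <- hub_genes(paste0("h", 1:3),
                                 edges = data.frame(a = "zz", b = "yy"),
                                 adjacency = adj),
                 "fall")
  expect_setequal(hb, c("h2", "h3"))
  expect_error(hub_genes(character(0)), "empty")
})

test_that("hypergeometric enrichment matches the tail-sum oracle", {
  universe <- sprintf("g%03d", 1:100)
  module <- universe[1:10]
  ann <- rbind(
    data.frame(term_id = "T1", term_name = "planted",
               gene = universe[c(1:3, 40:56)]),           # overlap 3 of 20
    data.frame(term_id = "T2", term_name = "exact module",
               gene = universe[1:10]),
    data.frame(term_id = "T3", term_name = "background",
               gene = universe[60:90]))
  enr <- hypergeom_enrichment(module, ann, universe)
  t1 <- enr$table[enr$table$term_id == "T1", ]
  expect_equal(t1$p, oracle_hyper_tail(3, 20, 10, 100), tolerance = 1e-12)
  expect_equal(t1$overlap, 3)
  expect_equal(t1$expected, 10 * 20 / 100)
  # the exact-module term ranks first
  expect_equal(enr$table$term_id[1], "T2")
  expect_lte(nrow(enr$top), 5)
  expect_true(all(enr$top$p < 0.05))
  # BH never decreases p
  expect_true(all(enr$table$fdr >= enr$table$p - 1e-15))
  expect_error(hypergeom_enrichment(module, ann[0, ], universe), "empty")
  expect_error(hypergeom_enrichment(c("zz"), ann, universe), "universe")
})

test_that("random modules are rarely called enriched after BH", {
  universe <- sprintf("g%03d", 1:200)
  set.seed(7)
  ann <- do.call(rbind, lapply(1:12, function(i)
    data.frame(term_id = paste0("T", i), term_name = paste0("t", i),
               gene = sample(universe, 25))))
  hits <- replicate(30, {
    module <- sample(universe, 15)
    min(hypergeom_enrichment(module, ann, universe)$table$fdr) < 0.05
  })
  expect_lt(mean(hits), 0.4)
})
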
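test_that("counts fixtures respect the configured panel and gap", {
  sim <- small_counts_sim()
  cfg <- sim$config
  tt <- sim$gene_truth
  expect_equal(sum(tt$category == "pre_jump"), cfg$n_pre_jump)
  expect_equal(sum(tt$category == "jump"), cfg$n_jump)
  expect_equal(sum(tt$category == "post_jump"), cfg$n_post_jump)
  expect_equal(sum(tt$dependence_truth == "failed_repression"),
               cfg$n_pre_dependent)
  expect_equal(sum(tt$dependence_truth == "partial_induction"),
               cfg$n_jump_partial)
  expect_equal(sum(tt$dependence_truth == "retained"), cfg$n_post_retained)
  for (cond in names(sim$conditions)) {
    s <- sim$conditions[[cond]]$cell_meta$pseudotime
    expect_equal(sum(s > cfg$jump_position - cfg$gap_halfwidth &
                     s < cfg$jump_position + cfg$gap_halfwidth), 0)
    counts <- sim$conditions[[cond]]$counts
    expect_true(all(counts@x >= 0 & counts@x == round(counts@x)))
    expect_false(any(duplicated(colnames(counts))))
    expect_false(any(duplicated(rownames(counts))))
  }
  # determinism under the seed
  again <- simulate_counts(small_counts_cfg())
  expect_identical(as.matrix(sim$conditions$WT$counts),
                   as.matrix(again$conditions$WT$counts))
})

test_that("normalisation equalises library sizes and preserves structure", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  # equal row sums on the linear scale
  tot <- colSums(norm$linear_mat)
  expect_lt(diff(range(tot)) / median(tot), 1e-8)
  # proportional cells normalise identically
  m <- matrix(c(2, 4, 6, 1, 2, 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  nm <- normalize_counts(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(nm$log_mat[, 1], nm$log_mat[, 2])
  # all-zero genes stay zero
  m2 <- rbind(m, z = 0)
  expect_true(all(normalize_counts(Matrix::Matrix(m2, sparse = TRUE))$log_mat["z", ] == 0))
  # gene means track the generating programs
  s <- sim$conditions$WT$cell_meta$pseudotime
  tt <- sim$gene_truth
  mu_bar <- vapply(seq_len(nrow(tt)), function(g) {
    p <- tt[g, ]
    mean(switch(p$direction,
                flat = rep(p$low, length(s)),
                up = p$low + (p$high - p$low) * nichejump:::sigmoid(s, p$centre, p$slope),
                down = p$low + (p$high - p$low) * (1 - nichejump:::sigmoid(s, p$centre, p$slope))))
  }, numeric(1))
  emp <- rowMeans(norm$linear_mat)[tt$gene]
  expect_gte(cor(emp, mu_bar, method = "spearman"), 0.95)
})

test_that("PC1 tracks developmental progression and embedding is well behaved", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
  s <- sim$conditions$WT$cell_meta$pseudotime
  expect_gte(abs(cor(emb$scores[, 1], s)), 0.9)
  # orientation: PC1 increases with progression (ribosomal score falls)
  expect_gt(cor(emb$scores[, 1], s), 0.9)
  # duplicated cells get identical scores; permuting genes changes nothing
  counts <- sim$conditions$WT$counts
  dup <- cbind(counts, dup_cell = counts[, 17])
  colnames(dup)[ncol(dup)] <- "dup_cell"
  emb2 <- embed_cells(normalize_counts(dup))
  expect_equal(emb2$scores[17, ], emb2$scores[ncol(dup), ],
               ignore_attr = TRUE)
  perm <- counts[sample(nrow(counts)), ]
  expect_equal(abs(embed_cells(normalize_counts(perm))$scores[, 1]),
               abs(embed_cells(normalize_counts(counts))$scores[, 1]),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("gene-set scores behave and feeding genes fall along progression", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  expect_error(gene_set_score(norm, character(0)), "empty")
  expect_error(gene_set_score(norm, "nonexistent_gene"), "unknown")
  one <- gene_set_score(norm, "hk001")
  expect_equal(one, norm$log_mat["hk001", ])
  s <- sim$conditions$WT$cell_meta$pseudotime
  feeding <- gene_set_score(norm, ribo_genes(norm))
  expect_lte(cor(feeding, s, method = "spearman"), -0.8)
})

test_that("the jump is called on gapped data and maps to the true position", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
  jc <- detect_jump(emb)
  expect_true(jc$jump)
  expect_gte(jc$prominence, 2)
  s <- sim$conditions$WT$cell_meta$pseudotime
  # map the valley through the monotone PC1-pseudotime relation
  s_valley <- approx(sort(emb$scores[, 1]), s[order(emb$scores[, 1])],
                     xout = jc$valley, rule = 2)$y
  cfg <- sim$config
  expect_lte(abs(s_valley - cfg$jump_position), cfg$gap_halfwidth)
  # side labels partition the cells
  expect_equal(jc$n_pre + jc$n_post, length(s))
  expect_gte(min(jc$n_pre, jc$n_post), 0.2 * length(s))
})

test_that("jump detection is invariant to cell order and PC1 sign", {
  norm <- small_counts_norm()
  emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
  pc1 <- emb$scores[, 1]
  a <- detect_jump(pc1)
  b <- detect_jump(sample(pc1))
  c <- detect_jump(-pc1)
  expect_equal(a$jump, b$jump)
  expect_equal(a$valley, b$valley)
  expect_equal(a$jump, c$jump)
  expect_equal(a$valley, -c$valley, tolerance = 1e-8)
  expect_equal(a$n_pre, c$n_post)
})

test_that("no jump is called on unimodal data", {
  expect_false(detect_jump(withr::with_seed(5, rnorm(2000)))$jump)
  # ungapped fixture (single broad pseudotime component) over several seeds
  for (s in 1:3) {
    # no concerted jump: graded programs (gentle slopes), one broad
    # pseudotime component, no gap
    cfg <- counts_config(replicate_sizes = c(500L, 400L), gap_halfwidth = 0,
                         state_centres = rep(0.5, 4),
                         state_sds = rep(0.2, 4), slope = 8, ribo_slope = 8,
                         rng_seed = s, conditions = "WT")
    sim <- simulate_counts(cfg)
    norm <- normalize_counts(sim$conditions$WT)
    emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
    expect_false(detect_jump(emb)$jump)
  }
})

test_that("correlation clustering separates constructed blobs and flags blobs-free data", {
  set.seed(7)
  blob <- function(mu, n) {
    matrix(rnbinom(60 * n, mu = rep(mu, n), size = 10), ncol = n)
  }
  mu1 <- runif(60, 1, 8)
  mu2 <- sample(mu1)                                  # distinct profile
  counts <- cbind(blob(mu1, 80), blob(mu2, 80))
  dimnames(counts) <- list(sprintf("g%02d", 1:60), sprintf("c%03d", 1:160))
  cl <- correlation_clusters(normalize_counts(Matrix::Matrix(counts, sparse = TRUE)),
                             k_range = 2:5)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, each = 80)
  expect_gte(adjusted_rand_index(cl$labels, truth), 0.95)
  expect_false(cl$low_confidence)
  # a single blob: silhouette flat and low -> low-confidence flag
  single <- cbind(blob(mu1, 120))
  dimnames(single) <- list(sprintf("g%02d", 1:60), sprintf("s%03d", 1:120))
  cl1 <- correlation_clusters(normalize_counts(Matrix::Matrix(single, sparse = TRUE)),
                              k_range = 2:5)
  expect_true(cl1$low_confidence)
})

test_that("gene categorisation follows the window rules", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
  jc <- detect_jump(emb)
  ord <- order(emb$scores[, 1])
  cats <- categorize_genes(norm, ord, jc$n_pre)
  # constant genes are unclassified
  hk <- cats$category[startsWith(cats$gene, "hk")]
  expect_true(all(hk == "unclassified"))
  # panel recovery on this fixture
  tt <- sim$gene_truth
  panel <- tt$category %in% c("pre_jump", "jump", "post_jump")
  hit <- cats$category[match(tt$gene[panel], cats$gene)] ==
    tt$category[panel]
  expect_gte(mean(hit), 0.95)
})

test_that("categories are invariant to scaling all counts of a cell", {
  sim <- small_counts_sim()
  counts <- sim$conditions$WT$counts
  scaled <- counts
  scaled[, 5] <- scaled[, 5] * 7
  scaled[, 104] <- scaled[, 104] * 3
  norm_a <- normalize_counts(counts)
  norm_b <- normalize_counts(scaled)
  emb <- embed_cells(norm_a, orient_genes = ribo_genes(norm_a))
  ord <- order(emb$scores[, 1])
  boundary <- detect_jump(emb)$n_pre
  a <- categorize_genes(norm_a, ord, boundary)
  b <- categorize_genes(norm_b, ord, boundary)
  expect_equal(a$category, b$category)
})

test_that("dependence classification implements the stated effect-size rules", {
  sim <- small_counts_sim()
  norm <- small_counts_norm()
  emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
  jc <- detect_jump(emb)
  ord <- order(emb$scores[, 1])
  cats <- categorize_genes(norm, ord, jc$n_pre)
  pw <- expression_profiles(norm, ord)
  # KO identical to WT: induced genes retained, pre-jump repression intact
  self <- classify_dependence(pw, pw, cats)
  expect_true(all(self$dependence[self$category %in% c("jump", "post_jump")] ==
                    "retained"))
  expect_true(all(self$dependence[self$category == "pre_jump"] %in%
                    "repression_intact"))
  # KO flat at the early level: complete loss for a post-jump panel gene
  ko_flat <- pw
  post_genes <- intersect(cats$gene[cats$category == "post_jump"],
                          sim$gene_truth$gene[sim$gene_truth$category ==
                                                "post_jump"])
  # knockout with essentially no expression: induction completely lost
  ko_flat[post_genes, ] <- 0.05
  flat <- classify_dependence(pw, ko_flat, cats)
  expect_true(all(flat$dependence[flat$gene %in% post_genes] ==
                    "complete_loss"))
})

test_that("the full pipeline recovers truth categories and the gap end to end", {
  for (seed in 1:3) {
    sim <- simulate_counts(small_counts_cfg(rng_seed = seed))
    norm <- normalize_counts(sim$conditions$WT)
    emb <- embed_cells(norm, orient_genes = ribo_genes(norm))
    jc <- detect_jump(emb)
    expect_true(jc$jump)
    ord <- order(emb$scores[, 1])
    cats <- categorize_genes(norm, ord, jc$n_pre)
    tt <- sim$gene_truth
    panel <- tt$category %in% c("pre_jump", "jump", "post_jump")
    hit <- cats$category[match(tt$gene[panel], cats$gene)] ==
      tt$category[panel]
    expect_gte(mean(hit), 0.95)
  }
})
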
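# Scoring inferred networks: precision/recall, ROC, baselines.

toy_truth <- function() {
  gene_network(letters[1:5],
               data.frame(regulator = c("a", "a", "b", "c", "d", "e", "a", "b", "c", "d"),
                          target    = c("b", "c", "c", "d", "e", "a", "d", "e", "e", "b")))
}

test_that("precision and recall follow their definitions on toy networks", {
  truth <- toy_truth()  # 10 edges over 5 genes
  res <- score_network(truth, truth)
  expect_equal(res$precision, 1.0)
  expect_equal(res$recall, 1.0)
  # 5 inferred, 2 true positives, truth size 10 -> precision 0.4, recall 0.2
  inferred <- gene_network(truth$genes,
                           data.frame(regulator = c("a", "b", "c", "d", "e"),
                                      target    = c("b", "c", "b", "c", "b")))
  res2 <- score_network(inferred, truth)
  expect_equal(res2$tp, 2L)
  expect_equal(res2$precision, 0.4)
  expect_equal(res2$recall, 0.2)
  # disjoint: direction must match, reversed edges are not credited
  disjoint <- gene_network(truth$genes,
                           data.frame(regulator = c("d", "c"), target = c("c", "b")))
  expect_equal(score_network(disjoint, truth)$precision, 0)
})

test_that("gene-label mismatches are reported", {
  truth <- toy_truth()
  alien <- gene_network(c("a", "z"), data.frame(regulator = "z", target = "a"))
  expect_error(score_network(alien, truth), "z")
})

test_that("perfectly separating scores give AUROC 1", {
  truth <- gene_network(c("g1", "g2", "g3"),
                        data.frame(regulator = c("g1", "g2"), target = c("g2", "g3")))
  C <- matrix(0.01, 3, 3); diag(C) <- 0
  C[2, 1] <- 5; C[3, 2] <- 4   # true edges scored highest
  cm <- cm_from_matrix(C, gene_ids = c("g1", "g2", "g3"))
  roc <- roc_curve(cm, truth)
  expect_equal(roc$auroc, 1.0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("ROC curve equals exhaustive threshold enumeration on 3 genes", {
  set.seed(5)
  C <- matrix(rnorm(9), 3, 3); diag(C) <- 0
  ids <- c("g1", "g2", "g3")
  truth <- gene_network(ids, data.frame(regulator = c("g1", "g3"),
                                        target = c("g3", "g2")))
  cm <- cm_from_matrix(C, gene_ids = ids)
  roc <- roc_curve(cm, truth)
  or <- roc_oracle(C, paste(truth$edges$regulator, truth$edges$target, sep = "\r"), ids)
  expect_equal(roc$points$fpr, or$points$fpr, tolerance = 1e-12)
  expect_equal(roc$points$tpr, or$points$tpr, tolerance = 1e-12)
  expect_equal(roc$auroc, or$auroc, tolerance = 1e-12)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  l <- 8
  C <- matrix(rnorm(l * l), l, l); diag(C) <- 0
  ids <- default_ids <- sprintf("g%d", 1:l)
  truth_pairs <- expand.grid(j = ids, i = ids, stringsAsFactors = FALSE)
  truth_pairs <- truth_pairs[truth_pairs$i != truth_pairs$j, ]
  lab <- runif(nrow(truth_pairs)) < 0.3
  truth <- gene_network(ids, data.frame(regulator = truth_pairs$j[lab],
                                        target = truth_pairs$i[lab]))
  cm <- cm_from_matrix(C, gene_ids = ids)
  roc <- roc_curve(cm, truth)
  scores <- abs(C[cbind(match(truth_pairs$i, ids), match(truth_pairs$j, ids))])
  ref <- pROC::auc(pROC::roc(response = as.integer(lab), predictor = scores,
                             direction = "<", quiet = TRUE))
  expect_equal(roc$auroc, as.numeric(ref), tolerance = 1e-10)
})

test_that("random scores against random truth give chance-level AUROC", {
  set.seed(7)
  ids <- sprintf("g%d", 1:10)
  aucs <- replicate(200, {
    C <- matrix(rnorm(100), 10, 10); diag(C) <- 0
    pairs <- expand.grid(i = 1:10, j = 1:10)
    pairs <- pairs[pairs$i != pairs$j, ]
    pick <- sample(nrow(pairs), 20)
    truth <- gene_network(ids, data.frame(regulator = ids[pairs$j[pick]],
                                          target = ids[pairs$i[pick]]))
    roc_curve(cm_from_matrix(C, gene_ids = ids), truth)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(8)
  C <- matrix(rnorm(25), 5, 5); diag(C) <- 0
  ids <- sprintf("g%d", 1:5)
  truth <- gene_network(ids, data.frame(regulator = ids[c(1, 2, 4)],
                                        target = ids[c(3, 5, 1)]))
  a1 <- roc_curve(cm_from_matrix(C, ids), truth)$auroc
  a2 <- roc_curve(cm_from_matrix(sign(C) * (exp(abs(C)) - 0.5), ids), truth)$auroc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("ROC averaging is the pointwise mean on the grid", {
  diagonal <- structure(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                             auroc = 0.5), class = "roc_result")
  perfect <- structure(list(points = data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)),
                            auroc = 1.0), class = "roc_result")
  one <- average_roc(list(diagonal))
  expect_equal(one$points$tpr, one$points$fpr, tolerance = 1e-12)
  two <- average_roc(list(diagonal, diagonal))
  expect_equal(two$auroc, 0.5, tolerance = 1e-12)
  mix <- average_roc(list(diagonal, perfect))
  expect_equal(mix$auroc, 0.75, tolerance = 0.01)
  expect_error(average_roc(list()), "at least one")
})

test_that("random-guess baseline equals gold-standard edge density", {
  ids <- sprintf("g%d", 1:3)
  all_pairs <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$i != all_pairs$j, ]
  saturated <- gene_network(ids, data.frame(regulator = all_pairs$j,
                                            target = all_pairs$i))
  expect_equal(random_baseline_precision(saturated), 1.0)
  expect_equal(random_baseline_precision(gene_network(ids)), 0.0)
  # 50 genes, 169 true edges -> 169/2450
  net50 <- generate_network(50, 169, seed = 1)
  expect_equal(random_baseline_precision(net50), 169 / 2450)
  expect_equal(round(random_baseline_precision(net50), 3), 0.069)
})

test_that("top-k true-positive count is non-decreasing in k", {
  set.seed(9)
  C <- matrix(rnorm(64), 8, 8); diag(C) <- 0
  ids <- sprintf("g%d", 1:8)
  cm <- cm_from_matrix(C, ids)
  truth <- generate_network(8, 15, seed = 2)
  truth <- gene_network(ids, data.frame(
    regulator = ids[match(truth$edges$regulator, truth$genes)],
    target = ids[match(truth$edges$target, truth$genes)]))
  tps <- vapply(0:56, function(k)
    score_network(edges_top_k(cm, k), truth)$tp, integer(1))
  expect_true(all(diff(tps) >= 0))
})
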
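test_that("shannon entropy matches hand-computed histogram values", {
  expect_equal(shannon_entropy(rep(3.7, 50)), 0)

  # 4 equally filled bins -> log2(4) = 2 bits
  x <- c(0.1, 0.1, 1.1, 1.1, 2.1, 2.1, 3.1, 3.1)
  expect_equal(shannon_entropy(x, n_bins = 4), 2)

  # fixed 10-value column, 4 bins: counts (4, 3, 2, 1) over [0, 4]
  x10 <- c(0.1, 0.2, 0.5, 0.9, 1.2, 1.5, 1.9, 2.3, 2.7, 4.0)
  p <- c(4, 3, 2, 1) / 10
  expect_equal(shannon_entropy(x10, n_bins = 4), -sum(p * log2(p)))
})

test_that("the entropy filter drops constants and is idempotent", {
  set.seed(3)
  X <- cbind(a = rnorm(50), b = rnorm(50), const = rep(2, 50))
  f1 <- shannon_entropy_filter(X, n_bins = 10, min_entropy = 0.5)
  expect_identical(f1$dropped, "const")
  expect_equal(f1$report$entropy[f1$report$descriptor == "const"], 0)
  f2 <- shannon_entropy_filter(f1$X, n_bins = 10, min_entropy = 0.5)
  expect_length(f2$dropped, 0)
  expect_identical(colnames(f2$X), colnames(f1$X))
})

test_that("gini_best_split finds the exact enumeration optimum", {
  # values (1,2,3,4), labels (A,A,B,B): threshold 2.5, decrease 0.5
  s <- gini_best_split(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gini_decrease, 0.5)
  expect_equal(unname(s$left_counts), c(2, 0))
  expect_equal(unname(s$right_counts), c(0, 2))

  # pure node and unsplittable node
  expect_null(gini_best_split(c(1, 2, 3), c(1, 1, 1)))
  expect_null(gini_best_split(c(2, 2, 2, 2), c(0, 1, 0, 1)))

  # random nodes against the exhaustive scan
  for (s in 1:40) {
    set.seed(1200 + s)
    n <- sample(2:100, 1)
    vals <- if (s %% 2) rnorm(n) else sample(1:6, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    got <- gini_best_split(vals, y)
    want <- brute_gini_scan(vals, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gini_decrease, want$gini_decrease, tolerance = 1e-12)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
    }
  }
})

test_that("grow_tree fits separable and XOR patterns exactly", {
  ctrl <- df_control(min_leaf = 1, min_descriptors = 0)
  # linearly separable single descriptor -> depth-1 tree
  X <- cbind(d1 = c(1, 2, 3, 10, 11, 12))
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- grow_tree(X, y, control = ctrl)
  expect_identical(tr$descriptor_set, "d1")
  expect_identical(tr$root$left$type, "leaf")
  expect_identical(tr$root$right$type, "leaf")
  expect_equal(predict(structure(list(trees = list(tr),
                                      descriptor_union = "d1"),
                                 class = "decision_forest"), X)$class,
               as.integer(y))

  # XOR with unequal cell counts (a balanced XOR has zero first-level Gini
  # gain for any axis split, so greedy impurity cannot start)
  cells <- expand.grid(a = c(0, 1), b = c(0, 1))
  reps <- c(7, 5, 6, 9)
  Xx <- as.matrix(cells[rep(1:4, reps), ])
  yx <- as.integer(xor(Xx[, "a"] == 1, Xx[, "b"] == 1))
  trx <- grow_tree(Xx, yx, control = ctrl)
  expect_setequal(trx$descriptor_set, c("a", "b"))
  pred <- predict(structure(list(trees = list(trx),
                                 descriptor_union = c("a", "b")),
                            class = "decision_forest"), Xx)
  expect_identical(pred$class, yx)
})

test_that("grow_tree honors the descriptor budget and exclusions", {
  set.seed(41)
  n <- 200
  y <- sample(0:1, n, replace = TRUE)
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("d", 1:12)))
  X[, 1:6] <- X[, 1:6] + 0.8 * y
  tr <- grow_tree(X, y, control = df_control(max_descriptors = 3,
                                             min_descriptors = 0))
  expect_lte(length(tr$descriptor_set), 3L)

  tr2 <- grow_tree(X, y, excluded = paste0("d", 1:6),
                   control = df_control(min_descriptors = 0))
  expect_length(intersect(tr2$descriptor_set, paste0("d", 1:6)), 0)

  expect_error(grow_tree(X, y, excluded = colnames(X)), "excluded")
  # small-tree flag is recorded, not warned, at the tree level
  expect_true(grow_tree(cbind(d1 = c(1, 2, 3, 10, 11, 12)),
                        c(0, 0, 0, 1, 1, 1),
                        control = df_control(min_leaf = 1))$below_min_descriptors)
})

test_that("forest trees use pairwise disjoint descriptor sets", {
  dd <- generate_descriptor_dataset(descriptor_sim_config(
    n_compounds = 200, n_descriptors = 80, n_informative = 30, n_blocks = 5,
    block_rho = 0.7, effect_size = 1.5, seed = 19))
  fo <- suppressWarnings(fit_forest(dd$X, dd$labels, n_trees = 5))
  sets <- lapply(fo$trees, `[[`, "descriptor_set")
  expect_identical(sum(lengths(sets)), length(unique(unlist(sets))))
  expect_identical(fo$descriptor_union, unlist(sets))

  # single-tree forest reproduces that tree's leaf probability
  fo1 <- suppressWarnings(fit_forest(dd$X, dd$labels, n_trees = 1))
  manual <- predict(fo1, dd$X)$p_positive
  tree_only <- predict(structure(list(trees = fo1$trees,
                                      descriptor_union = fo1$descriptor_union),
                                 class = "decision_forest"), dd$X)$p_positive
  expect_equal(manual, tree_only)

  expect_error(fit_forest(dd$X, dd$labels, n_trees = 0), "n_trees")
})

test_that("consensus is the mean of tree probabilities with ties negative", {
  leaf_tree <- function(p) {
    structure(list(root = list(type = "leaf", n = 10, n_pos = round(10 * p),
                               prob = p),
                   descriptor_set = character(0)),
              class = "gini_tree")
  }
  forest <- structure(list(trees = lapply(c(1, 0, 1, 0, 0.5), leaf_tree),
                           descriptor_union = character(0)),
                      class = "decision_forest")
  x <- matrix(0, 1, 1, dimnames = list(NULL, "any"))
  pred <- predict(forest, x)
  expect_equal(pred$p_positive, 0.5)
  expect_identical(pred$class, 0L)  # tie -> non-inhibitor

  all_pos <- structure(list(trees = lapply(rep(1, 5), leaf_tree),
                            descriptor_union = character(0)),
                       class = "decision_forest")
  expect_identical(predict(all_pos, x)$class, 1L)

  # raising one tree's probability cannot decrease the consensus
  bumped <- forest
  bumped$trees[[2]] <- leaf_tree(0.8)
  expect_gte(predict(bumped, x)$p_positive, pred$p_positive)
})

test_that("consensus training accuracy is not behind the first tree", {
  for (s in c(7, 8)) {
    dd <- generate_descriptor_dataset(descriptor_sim_config(
      n_compounds = 250, n_descriptors = 100, n_informative = 40,
      n_blocks = 5, block_rho = 0.8, effect_size = 1.5, seed = s))
    fo <- suppressWarnings(fit_forest(dd$X, dd$labels, n_trees = 5))
    consensus_acc <- mean(predict(fo, dd$X)$class == dd$labels)
    t1 <- structure(list(trees = fo$trees[1],
                         descriptor_union = fo$trees[[1]]$descriptor_set),
                    class = "decision_forest")
    tree1_acc <- mean(predict(t1, dd$X)$class == dd$labels)
    expect_gte(consensus_acc, tree1_acc - 0.01)
  }
})

test_that("forests survive a JSON round trip and dump readably", {
  dd <- generate_descriptor_dataset(descriptor_sim_config(
    n_compounds = 150, n_descriptors = 40, n_informative = 12, n_blocks = 3,
    block_rho = 0.6, effect_size = 1.5, seed = 23))
  fo <- suppressWarnings(fit_forest(dd$X, dd$labels, n_trees = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(fo, path)
  back <- read_forest(path)
  expect_identical(back$descriptor_union, fo$descriptor_union)
  expect_equal(predict(back, dd$X), predict(fo, dd$X))

  dump <- withr::local_tempfile(fileext = ".txt")
  write_forest_dump(fo, dump)
  expect_true(any(grepl("tree 1", readLines(dump))))
})
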
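test_that("feature ranking sorts by sensor then compute cost, stably", {
  ranked <- rank_features(default_feature_costs())
  expect_equal(ranked[1:2], c("Pd", "Pdabs"))   # barometer before accelerometer
  expect_equal(ranked, c("Pd", "Pdabs", "Ymeans", "Twave", "Xmeans", "Zmeans"))

  costs <- data.frame(feature = c("b", "a"), sensor_rank = 1L,
                      compute_rank = c(2L, 1L))
  expect_equal(rank_features(costs), c("a", "b"))
  expect_equal(rank_features(costs[1, ]), "b")
  expect_error(rank_features(rbind(costs, costs[1, ])), class = "har_param_error")
})

test_that("2-means split scores purity and balance on separated data", {
  cand <- kmeans_split(c(0, 0, 0, 10, 10, 10),
                       c("s", "s", "s", "r", "r", "r"), seed = 1)
  expect_equal(cand$purity, 1.0)
  expect_equal(cand$balance, 0.5)
  expect_equal(cand$classes_a, "s")          # A = smaller centroid
  expect_equal(cand$classes_b, "r")
  expect_error(kmeans_split(rep(3, 6), c("a", "a", "a", "b", "b", "b")),
               class = "har_degenerate_split")
})

test_that("on six-class data Pdabs splits stairs from flat and Pd isolates downstairs", {
  ft <- training_features_1hz()
  stairs <- c("downstairs", "upstairs")
  flat <- c("running", "sitting", "standing", "walking")

  cand_abs <- kmeans_split(ft$Pdabs, ft$label, seed = 1, features = "Pdabs")
  groups_abs <- list(cand_abs$classes_a, cand_abs$classes_b)
  expect_true(any(vapply(groups_abs, identical, logical(1), stairs)))
  expect_true(any(vapply(groups_abs, identical, logical(1), flat)))
  expect_gte(cand_abs$purity, 0.95)
  expect_equal(cand_abs$balance, 2 / 6)

  cand_pd <- kmeans_split(ft$Pd, ft$label, seed = 1, features = "Pd")
  expect_true(identical(cand_pd$classes_a, "downstairs") ||
              identical(cand_pd$classes_b, "downstairs"))
  expect_equal(cand_pd$balance, 1 / 6)
})

test_that("split selection maximises balance above the purity threshold", {
  ft <- training_features_1hz()
  mk <- function(f) kmeans_split(ft[[f]], ft$label, seed = 1, features = f)
  cands <- lapply(c("Pd", "Pdabs", "Ymeans", "Twave"), mk)
  chosen <- select_split(cands, 0.95)
  expect_equal(chosen$features, "Pdabs")     # balance 2/6 beats three 1/6 splits

  expect_identical(select_split(cands[2], 0.95), cands[[2]])

  # ties in purity and balance fall back to candidate (priority) order
  cand <- kmeans_split(c(0, 0, 1, 1), c("a", "a", "b", "b"), seed = 1,
                       features = "first")
  cand2 <- cand
  cand2$features <- "second"
  expect_equal(select_split(list(cand, cand2), 0.95)$features, "first")

  # nothing reaches the threshold: warn and fall back to maximal purity
  noisy <- kmeans_split(c(0, 1, 0, 1, 0.4, 0.6), c("a", "a", "b", "b", "a", "b"),
                        seed = 1, features = "noisy")
  expect_warning(out <- select_split(list(noisy), purity_threshold = 0.99),
                 "falling back")
  expect_equal(out$features, "noisy")
})

test_that("a binary node separates cleanly split 1-D data perfectly", {
  feats <- data.frame(x = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)))
  labels <- rep(c("low", "high"), each = 20)
  node <- train_node(feats, labels, "low", "high", "x", seed = 1)
  expect_equal(node$accuracy, 1.0)
  expect_equal(node$n_train + node$n_test, 40)
  dec <- vapply(feats$x, function(v)
    sum(((v - node$center) / node$scale) * node$weights) + node$bias, numeric(1))
  expect_true(all((dec >= 0) == (labels == "low")))
  expect_error(train_node(feats, labels, c("low", "high"), character(0), "x"),
               class = "har_param_error")
})

test_that("the six-class tree has five nodes, one leaf per class, and the paper's top splits", {
  ft <- training_features_1hz()
  tree <- train_tree(ft, seed = 1)
  expect_s3_class(tree, "hsvm_tree")
  expect_equal(n_nodes(tree), 5)

  leaves <- function(node) {
    if (is.character(node)) return(node)
    c(leaves(node$child_a), leaves(node$child_b))
  }
  expect_setequal(leaves(tree$root), activity_names())
  expect_length(leaves(tree$root), 6)

  expect_equal(tree$root$features, "Pdabs")  # root detects stair climbing
  # the stairs subtree separates up from down on signed Pd
  stairs_child <- if (setequal(tree$root$classes_a, c("downstairs", "upstairs")))
    tree$root$child_a else tree$root$child_b
  expect_equal(stairs_child$features, "Pd")
  # standing vs walking is decided on the motion wave
  find_node <- function(node) {
    if (is.character(node)) return(NULL)
    if (setequal(c(node$classes_a, node$classes_b), c("standing", "walking")))
      return(node)
    c0 <- find_node(node$child_a)
    if (!is.null(c0)) c0 else find_node(node$child_b)
  }
  sw <- find_node(tree$root)
  expect_false(is.null(sw))
  expect_equal(sw$features, "Twave")
})

test_that("two classes give a single node and training is seed-reproducible", {
  ft <- training_features_1hz()
  ft2 <- ft[ft$label %in% c("standing", "walking"), ]
  tree2 <- train_tree(ft2, seed = 5)
  expect_equal(n_nodes(tree2), 1)

  ta <- train_tree(ft, seed = 9)
  tb <- train_tree(ft, seed = 9)
  expect_identical(predict(ta, ft), predict(tb, ft))
  pa <- withr::local_tempfile(fileext = ".json")
  pb <- withr::local_tempfile(fileext = ".json")
  write_hsvm(ta, pa); write_hsvm(tb, pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("tree training rejects under-populated classes", {
  ft <- training_features_1hz()
  ft_bad <- rbind(ft[ft$label != "running", ],
                  ft[ft$label == "running", ][1, ])
  expect_error(train_tree(ft_bad, seed = 1), "at least 2 windows",
               class = "har_param_error")
  expect_error(train_tree(ft[ft$label == "sitting", ], seed = 1),
               class = "har_param_error")
})

test_that("classify agrees with an exhaustive composition of the node rules", {
  ft <- training_features_1hz()
  tree <- train_tree(ft, seed = 1)
  # independent oracle: evaluate every node's linear rule directly and
  # compose the routing table by hand
  oracle <- function(node, fv) {
    if (is.character(node)) return(node)
    z <- (fv[node$features] - node$center) / node$scale
    d <- sum(z * node$weights) + node$bias
    if (d >= 0) oracle(node$child_a, fv) else oracle(node$child_b, fv)
  }
  fvs <- ft[, c("Pd", "Pdabs", "Xmeans", "Ymeans", "Zmeans", "Twave")]
  got <- predict(tree, fvs)
  want <- vapply(seq_len(nrow(fvs)),
                 function(i) oracle(tree$root, unlist(fvs[i, ])), character(1))
  expect_identical(got, want)
  # windows from pure, well-separated regions recover their own class
  expect_gte(mean(got == ft$label), 0.95)
})

test_that("routing the training set reproduces each node's recorded decision counts", {
  ft <- training_features_1hz()
  tree <- train_tree(ft, seed = 1)
  fvs <- ft[, c("Pd", "Pdabs", "Xmeans", "Ymeans", "Zmeans", "Twave")]
  dec <- vapply(seq_len(nrow(fvs)), function(i) {
    z <- (unlist(fvs[i, ])[tree$root$features] - tree$root$center) / tree$root$scale
    sum(z * tree$root$weights) + tree$root$bias
  }, numeric(1))
  expect_equal(unname(tree$root$train_routing["A"]), sum(dec >= 0))
  expect_equal(unname(tree$root$train_routing["B"]), sum(dec < 0))
})

test_that("a serialised tree classifies identically after reload", {
  ft <- training_features_1hz()
  tree <- train_tree(ft, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_hsvm(tree, path)
  tree2 <- read_hsvm(path)
  expect_equal(tree2$classes, tree$classes)
  expect_equal(tree2$n_nodes, tree$n_nodes)
  fvs <- ft[, c("Pd", "Pdabs", "Xmeans", "Ymeans", "Zmeans", "Twave")]
  expect_identical(predict(tree2, fvs), predict(tree, fvs))
  expect_error(read_hsvm(withr::local_tempfile(lines = "{\"format\": \"other\"}",
                                               fileext = ".json")))
})

test_that("classify with large Pdabs and negative Pd lands on upstairs", {
  ft <- training_features_1hz()
  tree <- train_tree(ft, seed = 1)
  fv <- c(Pd = -0.15, Pdabs = 0.15, Xmeans = 0, Ymeans = 9.7, Zmeans = 0,
          Twave = 9)
  expect_equal(classify(tree, fv), "upstairs")
  out <- classify(tree, fv, path = TRUE)
  expect_equal(out$label, "upstairs")
  expect_length(out$decisions, 2)          # two decisions: root, then stairs node
})
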
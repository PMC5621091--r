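#' Feature cost table and ranking
#'
#' Tree construction considers cheap features first.  Each feature carries a
#' sensor rank (lower = cheaper sensor: the barometer draws far less power
#' than the accelerometer) and a compute rank (lower = cheaper to extract;
#' ties in sensor rank are broken by compute rank).  The default table
#' prioritises, in order: `Pd`, `Pdabs` (barometer), then `Ymeans`,
#' `Twave`, `Xmeans`, `Zmeans`.  Among the accelerometer features the
#' vertical axis is ranked first because, for a phone carried upright in a
#' pocket, it carries the gravity signal that distinguishes postures; the
#' table is plain data and can be replaced wholesale.
#'
#' @return `default_feature_costs()` returns a data.frame with columns
#'   `feature`, `sensor_rank`, `compute_rank`.
#' @export
default_feature_costs <- function() {
  data.frame(
    feature = c("Pd", "Pdabs", "Ymeans", "Twave", "Xmeans", "Zmeans"),
    sensor_rank = c(1L, 1L, 2L, 2L, 2L, 2L),
    compute_rank = c(1L, 2L, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE)
}

#' @rdname default_feature_costs
#' @param costs a feature-cost data.frame (`feature`, `sensor_rank`,
#'   `compute_rank`), one row per feature.
#' @return `rank_features()` returns the feature names sorted by
#'   `(sensor_rank, compute_rank)`, stable for ties.
#' @export
rank_features <- function(costs) {
  har_assert(all(c("feature", "sensor_rank", "compute_rank") %in% names(costs)),
             "`costs` needs columns feature, sensor_rank, compute_rank")
  if (anyDuplicated(costs$feature)) {
    har_error("duplicate feature ids in cost table", "har_param_error")
  }
  costs$feature[order(costs$sensor_rank, costs$compute_rank)]
}

#' Candidate binary split from 2-means clustering
#'
#' Clusters the training windows into two groups on the given feature
#' values (k = 2, multiple restarts), then scores the candidate by
#' * purity: the fraction of windows lying in their own class's majority
#'   cluster, and
#' * balance ("equilibrium"): `min(#classes on side A, #classes on side B)
#'   / #classes`, where each class is assigned to the side holding the
#'   majority of its windows.
#'
#' Cluster labels are canonicalised so that side A has the smaller centroid
#' (mean across standardised feature dimensions).
#'
#' @param values numeric vector or matrix (windows x features) of feature
#'   values.
#' @param labels class label per window.
#' @param seed integer seed for the k-means restarts.
#' @param features optional character vector naming the feature subset
#'   (metadata only).
#' @return A `split_candidate`: list with `features`, `cluster` (factor
#'   "A"/"B" per window), `classes_a`, `classes_b`, `purity`, `balance`.
#' @export
kmeans_split <- function(values, labels, seed = 1L, features = NULL) {
  x <- as.matrix(values)
  labels <- as.character(labels)
  har_assert(nrow(x) >= 2, "need at least 2 windows to split")
  har_assert(length(unique(labels)) >= 2, "need at least 2 distinct classes to split")
  har_assert(nrow(x) == length(labels), "one label per window required")
  sds <- apply(x, 2, sd)
  if (all(sds < .Machine$double.eps^0.5)) {
    har_error("degenerate split: all feature values identical", "har_degenerate_split")
  }
  keep <- sds > 0
  xs <- scale(x[, keep, drop = FALSE])
  set.seed(as.integer(seed))
  km <- kmeans(xs, centers = 2, nstart = 10, iter.max = 100)
  # Canonical order: cluster A = smaller centroid.
  a_id <- which.min(rowMeans(km$centers))
  cl <- factor(ifelse(km$cluster == a_id, "A", "B"), levels = c("A", "B"))
  # Majority side per class; ties go to A.
  classes <- sort(unique(labels))
  side <- vapply(classes, function(cls) {
    in_a <- sum(cl[labels == cls] == "A")
    if (in_a * 2 >= sum(labels == cls)) "A" else "B"
  }, character(1))
  purity <- mean(cl == side[labels])
  n_a <- sum(side == "A")
  balance <- min(n_a, length(classes) - n_a) / length(classes)
  structure(list(features = features, cluster = cl,
                 classes_a = classes[side == "A"],
                 classes_b = classes[side == "B"],
                 purity = purity, balance = balance),
            class = "split_candidate")
}

#' Select the best split candidate
#'
#' Among candidates whose purity reaches the threshold, returns the one
#' with maximal class balance; ties are broken by candidate order, which by
#' convention follows the feature priority ranking.  If no candidate
#' reaches the threshold the maximal-purity candidate is returned with a
#' warning.  Candidates that put every class on one side cannot form a
#' tree node and are ignored.
#'
#' @param candidates list of `split_candidate` objects, in feature priority
#'   order.
#' @param purity_threshold minimum acceptable purity (default 0.95).
#' @return The chosen `split_candidate`.
#' @export
select_split <- function(candidates, purity_threshold = 0.95) {
  har_assert(length(candidates) >= 1, "no split candidates supplied")
  usable <- Filter(function(cand) cand$balance > 0, candidates)
  har_assert(length(usable) >= 1,
             "no candidate split separates the classes into two non-empty groups",
             "har_degenerate_split")
  purity <- vapply(usable, `[[`, numeric(1), "purity")
  balance <- vapply(usable, `[[`, numeric(1), "balance")
  ok <- purity >= purity_threshold
  if (any(ok)) {
    idx <- which(ok)[which.max(balance[ok])]
  } else {
    warning(sprintf(
      "no split candidate reaches purity %.2f (best %.3f); falling back to maximal purity",
      purity_threshold, max(purity)))
    idx <- which.max(purity)
  }
  usable[[idx]]
}

# Seeded stratified 80/20 split; every class keeps at least one training row.
stratified_split <- function(labels, train_frac, seed) {
  set.seed(as.integer(seed))
  test <- logical(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    n_test <- floor(length(idx) * (1 - train_frac))
    n_test <- min(n_test, length(idx) - 1L)
    if (n_test > 0) test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Train one binary SVM node
#'
#' Fits a soft-margin linear SVM separating the windows of class group A
#' from those of group B on the given feature subset.  Features are
#' standardised with statistics from a seeded, class-stratified 80% training
#' split; the held-out 20% provides the reported node accuracy.  The fitted
#' rule is stored as an explicit weight vector and bias (oriented so a
#' positive decision value means side A), so a serialised tree reproduces
#' in-memory decisions exactly.
#'
#' @param feats data.frame of feature columns (at least the subset used).
#' @param labels class label per row of `feats`.
#' @param classes_a,classes_b the two class groups; they must cover all
#'   labels and both be non-empty.
#' @param features character vector of feature column names the node uses.
#' @param cost soft-margin cost C (default 1).
#' @param seed seed for the 80/20 split.
#' @param train_frac fraction used for fitting (default 0.8).
#' @return An `hsvm_node` (children unset; see [train_tree()]).
#' @export
train_node <- function(feats, labels, classes_a, classes_b, features,
                       cost = 1, seed = 1L, train_frac = 0.8) {
  labels <- as.character(labels)
  har_assert(length(classes_a) > 0 && length(classes_b) > 0,
             "both class groups must be non-empty")
  har_assert(all(labels %in% c(classes_a, classes_b)),
             "every window's class must belong to one of the two groups")
  har_assert(all(features %in% names(feats)),
             "feature subset not present in the feature table")
  x <- as.matrix(feats[, features, drop = FALSE])
  y <- factor(ifelse(labels %in% classes_a, "A", "B"), levels = c("A", "B"))
  is_test <- stratified_split(labels, train_frac, seed)
  xtr <- x[!is_test, , drop = FALSE]
  ytr <- y[!is_test]
  center <- colMeans(xtr)
  scl <- apply(xtr, 2, sd)
  scl[scl < .Machine$double.eps^0.5] <- 1
  xs <- sweep(sweep(xtr, 2, center), 2, scl, "/")
  fit <- e1071::svm(xs, ytr, kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # Orient the rule so positive decision values mean side A.
  dec <- drop(xs %*% w) + b
  if (mean(dec[ytr == "A"]) < mean(dec[ytr == "B"])) {
    w <- -w
    b <- -b
  }
  decide <- function(m) drop(sweep(sweep(m, 2, center), 2, scl, "/") %*% w) + b
  test_acc <- if (any(is_test)) {
    mean((decide(x[is_test, , drop = FALSE]) >= 0) == (y[is_test] == "A"))
  } else NA_real_
  routed_a <- sum(decide(x) >= 0)
  structure(list(features = features, center = center, scale = scl,
                 weights = w, bias = b,
                 classes_a = classes_a, classes_b = classes_b,
                 accuracy = test_acc,
                 n_train = sum(!is_test), n_test = sum(is_test),
                 train_routing = c(A = routed_a, B = nrow(x) - routed_a),
                 child_a = NULL, child_b = NULL),
            class = "hsvm_node")
}

# Candidate feature subsets: singletons of the top-m ranked features, then
# unordered pairs, in priority order; or all non-empty subsets when the
# full power set is requested.
candidate_subsets <- function(ranked, m_top, full_powerset = FALSE) {
  top <- head(ranked, m_top)
  if (full_powerset) {
    subs <- unlist(lapply(seq_along(top), function(k)
      combn(top, k, simplify = FALSE)), recursive = FALSE)
    return(subs)
  }
  singles <- lapply(top, identity)
  pairs <- if (length(top) >= 2) combn(top, 2, simplify = FALSE) else list()
  c(singles, pairs)
}

#' Train the hierarchical SVM tree
#'
#' Builds a binary tree of linear SVM nodes over the class set.  At each
#' node, candidate feature subsets (singletons of the top-m cost-ranked
#' features, then their unordered pairs) are clustered with 2-means; the
#' candidate split with sufficient purity and maximal class balance is
#' chosen ([select_split()]) and a binary SVM is trained on the resulting
#' two class groups ([train_node()]).  Recursion continues until every
#' group holds a single class, so an N-class problem yields exactly N-1
#' internal nodes.
#'
#' @param feats feature table (e.g. from [feature_table()]) with a `label`
#'   column and the six feature columns.
#' @param costs feature-cost table; see [default_feature_costs()].
#' @param seed integer seed; per-node sub-seeds are derived from it, so the
#'   tree is reproducible.
#' @param purity_threshold minimum split purity (default 0.95).
#' @param cost SVM soft-margin cost C (default 1).
#' @param m_top how many top-ranked features to consider (default 4).
#' @param full_powerset if `TRUE`, search all non-empty subsets of the
#'   top-m features instead of singletons + pairs.
#' @return An `hsvm_tree`: list with `root`, `classes`, `n_nodes`, and
#'   training metadata.
#' @export
train_tree <- function(feats, costs = default_feature_costs(), seed = 1L,
                       purity_threshold = 0.95, cost = 1, m_top = 4,
                       full_powerset = FALSE) {
  har_assert("label" %in% names(feats), "feature table needs a `label` column")
  labels <- as.character(feats$label)
  classes <- sort(unique(labels))
  har_assert(length(classes) >= 2, "need at least 2 classes to train a tree")
  tab <- table(labels)
  if (any(tab < 2)) {
    har_error(sprintf("every class needs at least 2 windows; short: %s",
                      paste(names(tab)[tab < 2], collapse = ", ")),
              "har_param_error")
  }
  ranked <- rank_features(costs)
  ranked <- ranked[ranked %in% names(feats)]
  subsets <- candidate_subsets(ranked, m_top, full_powerset)
  node_counter <- 0L
  max_depth <- length(classes)

  build <- function(rows, depth) {
    labs <- labels[rows]
    cls <- sort(unique(labs))
    if (length(cls) == 1) return(cls)
    if (depth > max_depth) {
      har_error("tree construction exceeded the maximum depth (one level per class); the splits are not separating the classes",
                "har_nontermination")
    }
    node_counter <<- node_counter + 1L
    node_seed <- as.integer((seed + 7919 * node_counter) %% .Machine$integer.max)
    cands <- list()
    for (sub in subsets) {
      cand <- tryCatch(
        kmeans_split(as.matrix(feats[rows, sub, drop = FALSE]), labs,
                     seed = node_seed, features = sub),
        har_degenerate_split = function(e) NULL)
      if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
    }
    chosen <- select_split(cands, purity_threshold)
    node <- train_node(feats[rows, , drop = FALSE], labs,
                       chosen$classes_a, chosen$classes_b, chosen$features,
                       cost = cost, seed = node_seed)
    node$split_purity <- chosen$purity
    node$split_balance <- chosen$balance
    node$child_a <- build(rows[labs %in% chosen$classes_a], depth + 1L)
    node$child_b <- build(rows[labs %in% chosen$classes_b], depth + 1L)
    node
  }

  root <- build(seq_along(labels), 1L)
  structure(list(root = root, classes = classes, n_nodes = node_counter,
                 meta = list(seed = as.integer(seed),
                             purity_threshold = purity_threshold,
                             cost = cost, m_top = m_top,
                             full_powerset = full_powerset)),
            class = "hsvm_tree")
}

#' @export
print.hsvm_tree <- function(x, ...) {
  cat(sprintf("<hsvm_tree> %d classes, %d binary SVM nodes (seed %d)\n",
              length(x$classes), x$n_nodes, x$meta$seed))
  describe <- function(node, indent) {
    if (is.character(node)) {
      cat(sprintf("%s* %s\n", indent, node))
      return(invisible())
    }
    cat(sprintf("%s[%s] {%s} | {%s}  acc=%s\n", indent,
                paste(node$features, collapse = "+"),
                paste(node$classes_a, collapse = ","),
                paste(node$classes_b, collapse = ","),
                ifelse(is.na(node$accuracy), "NA", sprintf("%.2f", node$accuracy))))
    describe(node$child_a, paste0(indent, "  "))
    describe(node$child_b, paste0(indent, "  "))
  }
  describe(x$root, "")
  invisible(x)
}

# Count internal nodes of a tree.
#' @rdname train_tree
#' @param tree an `hsvm_tree`.
#' @export
n_nodes <- function(tree) tree$n_nodes

node_decide <- function(node, fv) {
  x <- (unlist(fv)[node$features] - node$center) / node$scale
  sum(x * node$weights) + node$bias
}

#' Classify a feature vector with the tree
#'
#' Walks from the root, evaluating one binary SVM per level: a
#' non-negative decision value descends to side A, negative to side B.
#' Only the features on the root-to-leaf path are consulted, which is what
#' makes the hierarchy cheap at run time.
#'
#' @param tree an `hsvm_tree` from [train_tree()] or [read_hsvm()].
#' @param fv named numeric feature vector (or single-row data.frame)
#'   containing the features the path needs.
#' @param path if `TRUE`, also return the sequence of node decisions.
#' @return The activity label; with `path = TRUE`, a list
#'   `(label, decisions)`.
#' @export
classify <- function(tree, fv, path = FALSE) {
  if (is.data.frame(fv)) {
    fv <- unlist(fv[1, vapply(fv, is.numeric, logical(1)), drop = FALSE])
  }
  node <- tree$root
  decisions <- character(0)
  while (!is.character(node)) {
    d <- node_decide(node, fv)
    side <- if (d >= 0) "A" else "B"
    decisions <- c(decisions, sprintf("%s:%s", paste(node$features, collapse = "+"), side))
    node <- if (d >= 0) node$child_a else node$child_b
  }
  if (path) list(label = node, decisions = decisions) else node
}

#' @rdname classify
#' @param object an `hsvm_tree`.
#' @param newdata data.frame of feature rows.
#' @param ... unused.
#' @return `predict()` returns a character vector of labels, one per row.
#' @export
predict.hsvm_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)),
         function(i) classify(object, newdata[i, , drop = FALSE]),
         character(1))
}

node_to_list <- function(node) {
  if (is.character(node)) return(list(leaf = node))
  list(features = node$features,
       center = as.list(node$center), scale = as.list(node$scale),
       weights = as.list(node$weights), bias = node$bias,
       classes_a = node$classes_a, classes_b = node$classes_b,
       accuracy = node$accuracy,
       child_a = node_to_list(node$child_a),
       child_b = node_to_list(node$child_b))
}

node_from_list <- function(x) {
  if (!is.null(x$leaf)) return(x$leaf)
  structure(list(features = unlist(x$features),
                 center = unlist(x$center), scale = unlist(x$scale),
                 weights = unlist(x$weights), bias = x$bias,
                 classes_a = unlist(x$classes_a), classes_b = unlist(x$classes_b),
                 accuracy = if (is.null(x$accuracy)) NA_real_ else x$accuracy,
                 child_a = node_from_list(x$child_a),
                 child_b = node_from_list(x$child_b)),
            class = "hsvm_node")
}

#' Serialise a trained tree to JSON
#'
#' The model file is versioned JSON holding the class list and, per node,
#' the feature subset, standardisation constants, weights, bias and
#' children.  A round-tripped tree reproduces the in-memory tree's
#' classifications exactly.
#'
#' @param tree an `hsvm_tree`.
#' @param path file path.
#' @export
write_hsvm <- function(tree, path) {
  obj <- list(format = "harsvm-tree", version = "1.0",
              classes = tree$classes, n_nodes = tree$n_nodes,
              meta = tree$meta, root = node_to_list(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hsvm
#' @export
read_hsvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  har_assert(identical(obj$format, "harsvm-tree"),
             "not a harsvm tree model file")
  structure(list(root = node_from_list(obj$root),
                 classes = unlist(obj$classes),
                 n_nodes = obj$n_nodes,
                 meta = obj$meta),
            class = "hsvm_tree")
}
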
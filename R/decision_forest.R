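#' Shannon entropy of one descriptor
#'
#' Entropy \eqn{H = -\sum_i p_i \log_2 p_i} of the descriptor's values over
#' an equal-width histogram spanning its observed range. A constant
#' descriptor has H = 0; a descriptor uniform over the bins attains the
#' maximum \eqn{\log_2 n_{bins}}.
#'
#' @param x Numeric vector.
#' @param n_bins Number of equal-width histogram bins (>= 2).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, n_bins = 10L) {
  stopifnot(n_bins >= 2L, all(is.finite(x)))
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  # right-closed cut except the first bin; top edge included in last bin
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' Filter low-information descriptors by Shannon entropy
#'
#' Drops descriptors whose histogram entropy falls below \code{min_entropy}
#' bits; constant columns always have H = 0 and are removed whenever
#' \code{min_entropy > 0}. Filtering an already-filtered table drops
#' nothing further (the entropy of a kept column is unchanged).
#'
#' @param X Numeric matrix or data.frame of descriptors (columns named).
#' @param n_bins Histogram bins per descriptor (default 10).
#' @param min_entropy Threshold in bits (default 0.5).
#' @return List with \code{X} (reduced matrix), \code{report} (data.frame of
#'   all descriptors: name, entropy, kept flag), \code{dropped} (names).
#' @export
shannon_entropy_filter <- function(X, n_bins = 10L, min_entropy = 0.5) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  H <- apply(X, 2L, shannon_entropy, n_bins = n_bins)
  keep <- H >= min_entropy
  list(X = X[, keep, drop = FALSE],
       report = data.frame(descriptor = colnames(X), entropy = unname(H),
                           kept = unname(keep), stringsAsFactors = FALSE),
       dropped = colnames(X)[!keep])
}

#' Gini impurity of a set of binary labels
#' @param y Binary labels.
#' @return \eqn{1 - \sum_k p_k^2} in [0, 0.5] for two classes.
#' @export
gini_impurity <- function(y) {
  y <- as_binary(y)
  p <- mean(y == 1L)
  1 - p^2 - (1 - p)^2
}

#' Best Gini split of one descriptor at a node
#'
#' Scans the midpoints between consecutive distinct sorted values and
#' returns the threshold maximizing the decrease in Gini impurity
#' (parent impurity minus the size-weighted child impurities). Rows go left
#' when \code{value < threshold}.
#'
#' @param values Numeric vector (the node's rows for one descriptor).
#' @param y Binary labels at the node.
#' @param min_leaf Minimum rows required on each side of the split.
#' @return \code{NULL} if the node is pure, unsplittable (all values
#'   identical) or no split improves; otherwise a list with
#'   \code{threshold}, \code{gini_decrease}, and left/right class counts.
#' @export
gini_best_split <- function(values, y, min_leaf = 1L) {
  y <- as_binary(y)
  n <- length(values)
  stopifnot(length(y) == n, n >= 2L)
  parent <- gini_impurity(y)
  if (parent == 0) return(NULL)

  o <- order(values)
  v <- values[o]; ys <- y[o]
  # candidate cut positions: after row i when v[i] < v[i+1]
  cum_pos <- cumsum(ys)
  i <- seq_len(n - 1L)
  valid <- v[i] < v[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  nl <- i[valid]
  pos_l <- cum_pos[nl]
  pos_r <- cum_pos[n] - pos_l
  nr <- n - nl
  gini_l <- 1 - (pos_l / nl)^2 - ((nl - pos_l) / nl)^2
  gini_r <- 1 - (pos_r / nr)^2 - ((nr - pos_r) / nr)^2
  dec <- parent - (nl * gini_l + nr * gini_r) / n
  # ties (within float noise) break to the smallest threshold
  best <- which(dec >= max(dec) - 1e-12)[1L]
  if (dec[best] <= 0) return(NULL)
  cut <- nl[best]
  list(threshold = (v[cut] + v[cut + 1L]) / 2,
       gini_decrease = dec[best],
       left_counts = c(`0` = cut - pos_l[best], `1` = pos_l[best]),
       right_counts = c(`0` = (n - cut) - pos_r[best], `1` = pos_r[best]))
}

#' Tree-growing constraints
#'
#' Defaults are calibrated so trees on realistic descriptor tables land in
#' the 6-17 distinct descriptors range used by the consensus models.
#'
#' @param min_leaf Minimum rows per leaf (default 5).
#' @param min_decrease Minimum Gini decrease to accept a split.
#' @param max_descriptors Maximum distinct descriptors per tree (default 17).
#' @param min_descriptors Trees using fewer distinct descriptors are flagged
#'   (default 6).
#' @return List of class \code{"df_control"}.
#' @export
df_control <- function(min_leaf = 5L, min_decrease = 1e-6,
                       max_descriptors = 17L, min_descriptors = 6L) {
  stopifnot(min_leaf >= 1L, min_decrease >= 0, max_descriptors >= 1L)
  structure(list(min_leaf = as.integer(min_leaf), min_decrease = min_decrease,
                 max_descriptors = as.integer(max_descriptors),
                 min_descriptors = as.integer(min_descriptors)),
            class = "df_control")
}

#' Grow one Gini decision tree
#'
#' Recursive binary partitioning with the rule "go left iff value <
#' threshold". Growth stops at pure nodes, nodes too small to split under
#' \code{min_leaf}, or when no available descriptor yields a Gini decrease
#' above \code{min_decrease}. Once \code{max_descriptors} distinct
#' descriptors are in use, further splits may only reuse them. Trees ending
#' with fewer than \code{min_descriptors} distinct descriptors carry a
#' \code{below_min_descriptors} flag (warned about at the forest level).
#'
#' @param X Numeric descriptor matrix (columns named).
#' @param y Binary labels.
#' @param excluded Descriptor names this tree must not use (disjointness
#'   with earlier trees in a forest).
#' @param control A [df_control()].
#' @return Object of class \code{"gini_tree"}: nested node list, the
#'   \code{descriptor_set} used, and the flag above.
#' @export
grow_tree <- function(X, y, excluded = character(), control = df_control()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  y <- as_binary(y)
  stopifnot(nrow(X) == length(y))
  avail <- setdiff(colnames(X), excluded)
  if (!length(avail)) stop("all descriptors are excluded")
  if (min(table(factor(y, levels = 0:1))) < control$min_leaf) {
    stop(sprintf("need at least min_leaf = %d rows per class", control$min_leaf))
  }
  used <- character(0)

  build <- function(rows) {
    yn <- y[rows]
    leaf <- function() list(type = "leaf", n = length(rows),
                            n_pos = sum(yn == 1L), prob = mean(yn == 1L))
    if (length(rows) < 2L * control$min_leaf || gini_impurity(yn) == 0) {
      return(leaf())
    }
    # descriptor budget: at the cap, only already-used descriptors may split
    cand <- if (length(used) >= control$max_descriptors) {
      used
    } else {
      avail
    }
    best <- NULL; best_var <- NULL
    for (d in cand) {
      s <- gini_best_split(X[rows, d], yn, min_leaf = control$min_leaf)
      if (!is.null(s) && s$gini_decrease > control$min_decrease &&
          (is.null(best) || s$gini_decrease > best$gini_decrease)) {
        best <- s; best_var <- d
      }
    }
    if (is.null(best)) return(leaf())
    used <<- union(used, best_var)
    go_left <- X[rows, best_var] < best$threshold
    list(type = "split", variable = best_var, threshold = best$threshold,
         gini_decrease = best$gini_decrease, n = length(rows),
         left = build(rows[go_left]), right = build(rows[!go_left]))
  }

  root <- build(seq_len(nrow(X)))
  structure(list(root = root, descriptor_set = used,
                 below_min_descriptors = length(used) < control$min_descriptors,
                 control = control),
            class = "gini_tree")
}

#' @export
print.gini_tree <- function(x, ...) {
  cat(sprintf("gini_tree: %d distinct descriptors%s\n",
              length(x$descriptor_set),
              if (x$below_min_descriptors) " (below the 6-descriptor flag)" else ""))
  cat(format_tree_node(x$root, indent = 0L), sep = "\n")
  invisible(x)
}

format_tree_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    sprintf("%sleaf: n=%d, P(inhibitor)=%.3f", pad, node$n, node$prob)
  } else {
    c(sprintf("%s%s < %g  (n=%d, dGini=%.4f)", pad, node$variable,
              node$threshold, node$n, node$gini_decrease),
      format_tree_node(node$left, indent + 1L),
      format_tree_node(node$right, indent + 1L))
  }
}

predict_tree_prob <- function(tree, X) {
  walk <- function(node, i) {
    if (node$type == "leaf") return(node$prob)
    if (X[i, node$variable] < node$threshold) walk(node$left, i)
    else walk(node$right, i)
  }
  vapply(seq_len(nrow(X)), function(i) walk(tree$root, i), numeric(1))
}

#' Fit a decision forest
#'
#' An ordered ensemble of Gini trees over mutually disjoint descriptor
#' subsets: tree \emph{t} is grown with every descriptor already used by
#' trees 1..t-1 excluded, so the trees are distinct yet comparable, and the
#' consensus is the arithmetic mean of the trees' leaf probabilities.
#' Fitting stops early with a warning when a new tree cannot reach
#' \code{min_tree_accuracy} on the training data with the remaining
#' descriptors.
#'
#' @param X Numeric descriptor matrix, typically after
#'   [shannon_entropy_filter()].
#' @param y Binary labels (inhibitor = 1).
#' @param n_trees Number of trees (default 5, the consensus size used for
#'   the CYP models).
#' @param control A [df_control()].
#' @param min_tree_accuracy Training accuracy a candidate tree must reach to
#'   join the forest (default 0.5).
#' @return Object of class \code{"decision_forest"}: the tree list, the
#'   union of descriptors, and the entropy-filter record when supplied.
#' @export
fit_forest <- function(X, y, n_trees = 5L, control = df_control(),
                       min_tree_accuracy = 0.5) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  y <- as_binary(y)
  trees <- list()
  excluded <- character(0)
  for (t in seq_len(n_trees)) {
    if (length(setdiff(colnames(X), excluded)) == 0L) {
      warning(sprintf("stopping at %d trees: no descriptors left", t - 1L))
      break
    }
    tree <- grow_tree(X, y, excluded = excluded, control = control)
    acc <- mean((predict_tree_prob(tree, X) > 0.5) == (y == 1L))
    if (acc < min_tree_accuracy) {
      warning(sprintf(
        "stopping at %d trees: next tree reaches training accuracy %.3f < %.3f",
        t - 1L, acc, min_tree_accuracy))
      break
    }
    if (tree$below_min_descriptors) {
      warning(sprintf("tree %d uses %d distinct descriptors (flagged: < %d)",
                      t, length(tree$descriptor_set),
                      control$min_descriptors))
    }
    trees[[t]] <- tree
    excluded <- c(excluded, tree$descriptor_set)
  }
  if (!length(trees)) stop("no tree reached the minimum training accuracy")
  structure(list(trees = trees, descriptor_union = excluded,
                 control = control, n_requested = as.integer(n_trees)),
            class = "decision_forest")
}

#' @export
print.decision_forest <- function(x, ...) {
  cat(sprintf("decision_forest: %d trees, %d descriptors total (disjoint sets)\n",
              length(x$trees), length(x$descriptor_union)))
  for (t in seq_along(x$trees)) {
    cat(sprintf("  tree %d: %d descriptors\n", t,
                length(x$trees[[t]]$descriptor_set)))
  }
  invisible(x)
}

#' Consensus prediction from a decision forest
#'
#' The consensus probability is the unweighted mean of the trees' leaf
#' probabilities for the positive (inhibitor) class; the label is positive
#' iff the consensus exceeds 0.5 (ties classify as non-inhibitor).
#'
#' @param object A \code{"decision_forest"}.
#' @param newdata Matrix or data.frame covering every descriptor the forest
#'   uses.
#' @param ... Unused.
#' @return data.frame with \code{class} (0/1) and \code{p_positive}.
#' @export
predict.decision_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$descriptor_union, colnames(newdata))
  if (length(missing)) {
    stop(sprintf("newdata lacks descriptors: %s",
                 paste(missing, collapse = ", ")))
  }
  probs <- vapply(object$trees,
                  function(tr) predict_tree_prob(tr, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  consensus <- rowMeans(probs)
  data.frame(class = as.integer(consensus > 0.5),
             p_positive = unname(consensus))
}

# -- serialization ----------------------------------------------------------

#' Write / read a decision forest as JSON
#' @param forest A \code{"decision_forest"}.
#' @param path File path.
#' @return \code{read_forest} returns the restored forest.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "decision_forest"))
  payload <- list(
    type = "decision_forest",
    control = unclass(forest$control),
    n_requested = forest$n_requested,
    trees = lapply(forest$trees, function(tr) {
      list(root = tr$root, descriptor_set = tr$descriptor_set,
           below_min_descriptors = tr$below_min_descriptors)
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(j$type, "decision_forest"))
  control <- do.call(df_control, j$control)
  fix_node <- function(node) {
    if (identical(node$type, "leaf")) {
      list(type = "leaf", n = as.integer(node$n),
           n_pos = as.integer(node$n_pos), prob = as.numeric(node$prob))
    } else {
      list(type = "split", variable = node$variable,
           threshold = as.numeric(node$threshold),
           gini_decrease = as.numeric(node$gini_decrease),
           n = as.integer(node$n),
           left = fix_node(node$left), right = fix_node(node$right))
    }
  }
  trees <- lapply(j$trees, function(tr) {
    structure(list(root = fix_node(tr$root),
                   descriptor_set = as.character(unlist(tr$descriptor_set)),
                   below_min_descriptors = isTRUE(tr$below_min_descriptors),
                   control = control),
              class = "gini_tree")
  })
  structure(list(trees = trees,
                 descriptor_union = unlist(lapply(trees, `[[`, "descriptor_set")),
                 control = control,
                 n_requested = as.integer(j$n_requested)),
            class = "decision_forest")
}

#' Human-readable dump of a forest's trees
#' @param forest A \code{"decision_forest"}.
#' @param path Text file to write.
#' @return The path, invisibly.
#' @export
write_forest_dump <- function(forest, path) {
  lines <- unlist(lapply(seq_along(forest$trees), function(t) {
    c(sprintf("tree %d (%d descriptors):", t,
              length(forest$trees[[t]]$descriptor_set)),
      format_tree_node(forest$trees[[t]]$root, indent = 1L), "")
  }))
  writeLines(lines, path)
  invisible(path)
}
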
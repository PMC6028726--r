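#' Parameters of the recursive cluster refinement
#'
#' @param min_cluster_size Smallest admissible subgroup; a split producing a
#'   smaller child is rejected.
#' @param min_deg Minimum number of DEGs (see [count_degs()]) between the
#'   two refined children for a split to be accepted.
#' @param reps Number of repetitions of the k-fold cross-validated vote
#'   estimate (the full-scale setting is 100; desk-scale runs use fewer).
#' @param folds Cross-validation folds.
#' @param ntree Trees per random forest.
#' @param vote_train Vote-probability threshold above which a cell joins the
#'   training set for the refinement classifier (strict `>`).
#' @param vote_abandon Vote-probability threshold below which a cell is
#'   abandoned (strict `<`).
#' @param max_features Cap on the number of feature genes kept from the
#'   importance ranking.
#' @param linkage Agglomeration method for the bisection dendrogram.
#' @param seed Integer seed governing every random draw in the recursion.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_cluster_size = 20, min_deg = 10, reps = 100,
                           folds = 10, ntree = 500, vote_train = 0.6,
                           vote_abandon = 0.55, max_features = 200,
                           linkage = c("average", "complete", "ward.D2"),
                           seed = 1) {
  linkage <- match.arg(linkage)
  stopifnot(min_cluster_size >= 2, min_deg >= 0, reps >= 1, folds >= 2,
            ntree >= 1, vote_train >= 0, vote_train <= 1,
            vote_abandon >= 0, vote_abandon <= 1, max_features >= 2)
  structure(list(min_cluster_size = min_cluster_size, min_deg = min_deg,
                 reps = reps, folds = folds, ntree = ntree,
                 vote_train = vote_train, vote_abandon = vote_abandon,
                 max_features = max_features, linkage = linkage,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Bisect cells by hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of cells under the distance
#' `d = 1 - Pearson correlation` computed over highly variable genes, with
#' the dendrogram cut at its top split into exactly two groups.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param cells Cell ids to cluster (default: all columns).
#' @param hvgs Feature genes; when `NULL` they are selected on this cell
#'   subset by [select_hvg_cv2()] (with the expression prefilter), falling
#'   back to all genes with positive variance if the fit cannot be made.
#' @param linkage Agglomeration method.
#' @return A list with `left` and `right` cell-id vectors (`left` contains
#'   the lexicographically smallest cell) and the `hvgs` used. Signals an
#'   error of class `no_split` when fewer than 2 cells are given.
#' @export
bisect_cells <- function(expr, cells = NULL, hvgs = NULL,
                         linkage = "average") {
  m <- .expr_of(expr)
  if (is.null(cells)) cells <- colnames(m)
  cells <- sort(cells)
  if (length(cells) < 2)
    stop(structure(class = c("no_split", "error", "condition"),
                   list(message = "no-split: need at least 2 cells",
                        call = sys.call())))
  sub <- m[, cells, drop = FALSE]
  if (is.null(hvgs)) hvgs <- .node_features(sub)
  sub <- as.matrix(sub[hvgs, , drop = FALSE])
  cc <- suppressWarnings(stats::cor(sub))
  cc[!is.finite(cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - cc), method = linkage)
  grp <- stats::cutree(hc, k = 2)
  left <- sort(cells[grp == grp[1]])
  right <- sort(setdiff(cells, left))
  list(left = left, right = right, hvgs = hvgs)
}

# Internal: feature genes for one recursion node -- CV2 HVGs with the
# expression prefilter, falling back to all genes with positive variance.
.node_features <- function(sub) {
  hv <- tryCatch(select_hvg_cv2(sub, prefilter = TRUE)$genes,
                 error = function(e) character(0))
  if (length(hv) >= 2) return(hv)
  v <- .row_stats(sub)$var
  rownames(sub)[!is.na(v) & v > 0]
}

#' Refine a two-group split with random-forest vote probabilities
#'
#' Implements the vote-probability refinement of an initial bisection:
#' (i) a `folds`-fold cross-validated random forest over the candidate
#' genes yields per-fold impurity importances, and feature genes are those
#' with mean importance more than one standard deviation above the mean
#' (capped at `max_features`); (ii) cells whose held-out vote probability
#' for their own group exceeds `vote_train` form the training set of an
#' optimized classifier that re-predicts all remaining cells; (iii) the
#' vote probability of every cell is then finalized as the mean held-out
#' vote fraction over `reps` repetitions of `folds`-fold cross-validation
#' on the refined labels; cells below `vote_abandon` are abandoned.
#' Forests use balanced class weights and `sqrt(p)` candidate features per
#' node; everything is seeded.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param left,right Cell ids of the initial two groups.
#' @param params A [cluster_params()].
#' @param features Candidate genes for the forest (default: node features as
#'   in [bisect_cells()]).
#' @param seed Seed for this refinement (default `params$seed`).
#' @return A list of class `SplitResult`: `status` (`"ok"` or
#'   `"unstable-split"` when a class has an empty training set), refined
#'   `left`/`right` (non-abandoned cells), `feature_genes`, `vote_prob`
#'   (named over all input cells), `abandoned`, and `initial_vote`.
#' @export
rf_refine <- function(expr, left, right, params = cluster_params(),
                      features = NULL, seed = params$seed) {
  m <- .expr_of(expr)
  stopifnot(length(intersect(left, right)) == 0)
  if (length(left) < params$min_cluster_size ||
      length(right) < params$min_cluster_size)
    stop("both groups must have at least min_cluster_size cells")
  cells <- sort(c(left, right))
  if (is.null(features)) features <- .node_features(m[, cells, drop = FALSE])
  x <- t(as.matrix(m[features, cells, drop = FALSE]))
  lab <- factor(ifelse(cells %in% left, "g1", "g2"), levels = c("g1", "g2"))
  set.seed(seed)

  # (i) feature selection from a cross-validated forest
  cv1 <- .rf_cv(x, lab, params, importance = TRUE)
  imp <- colMeans(cv1$importance)
  sel <- imp > mean(imp) + stats::sd(imp)
  if (sum(sel) < 2) sel <- rank(-imp, ties.method = "first") <= min(10, ncol(x))
  feature_genes <- names(sort(imp[sel], decreasing = TRUE))
  feature_genes <- feature_genes[seq_len(min(length(feature_genes),
                                             params$max_features))]

  # (ii) optimal classifier from confidently voted cells
  train <- cv1$vote > params$vote_train
  if (!any(train & lab == "g1") || !any(train & lab == "g2"))
    return(structure(list(status = "unstable-split", left = left,
                          right = right, feature_genes = feature_genes,
                          vote_prob = cv1$vote, abandoned = character(0),
                          initial_vote = cv1$vote),
                     class = "SplitResult"))
  xf <- x[, feature_genes, drop = FALSE]
  fit <- .rf_fit(xf[train, , drop = FALSE], droplevels(lab[train]), params)
  refined <- lab
  if (any(!train)) {
    pr <- stats::predict(fit, data = data.frame(xf[!train, , drop = FALSE],
                                                check.names = FALSE))
    prob <- .vote_of(pr$predictions, levels(lab))
    refined[!train] <- factor(ifelse(prob[, "g1"] >= prob[, "g2"],
                                     "g1", "g2"), levels = levels(lab))
  }
  if (min(table(refined)) < 2)
    return(structure(list(status = "unstable-split", left = left,
                          right = right, feature_genes = feature_genes,
                          vote_prob = cv1$vote, abandoned = character(0),
                          initial_vote = cv1$vote),
                     class = "SplitResult"))

  # (iii) final vote probabilities over repeated cross-validation
  votes <- matrix(NA_real_, length(cells), params$reps)
  for (r in seq_len(params$reps))
    votes[, r] <- .rf_cv(xf, refined, params, importance = FALSE)$vote
  vote_prob <- stats::setNames(rowMeans(votes), cells)
  abandoned <- cells[vote_prob < params$vote_abandon]
  keep <- !(cells %in% abandoned)
  structure(list(status = "ok",
                 left = cells[keep & refined == "g1"],
                 right = cells[keep & refined == "g2"],
                 feature_genes = feature_genes, vote_prob = vote_prob,
                 abandoned = abandoned, initial_vote = cv1$vote),
            class = "SplitResult")
}

# Internal: one ranger fit with balanced class weights and sqrt(p) mtry.
.rf_fit <- function(x, y, params) {
  cw <- as.numeric(length(y) / (nlevels(y) * table(y)[levels(y)]))
  ranger::ranger(x = data.frame(x, check.names = FALSE), y = y,
                 num.trees = params$ntree, probability = TRUE,
                 mtry = max(1, floor(sqrt(ncol(x)))),
                 class.weights = cw, num.threads = 1,
                 seed = sample.int(.Machine$integer.max, 1))
}

# Internal: stratified k-fold CV; returns per-cell held-out vote
# probability for its own label and (optionally) per-fold importances.
.rf_cv <- function(x, y, params, importance = FALSE) {
  n <- length(y)
  folds <- min(params$folds, min(table(y)))
  fold_id <- integer(n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  vote <- numeric(n)
  imp <- if (importance) matrix(0, folds, ncol(x),
                                dimnames = list(NULL, colnames(x)))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    cw <- as.numeric(sum(!te) /
                       (nlevels(y) * table(y[!te])[levels(y)]))
    fit <- ranger::ranger(x = data.frame(x[!te, , drop = FALSE],
                                         check.names = FALSE),
                          y = droplevels(y[!te]),
                          num.trees = params$ntree, probability = TRUE,
                          mtry = max(1, floor(sqrt(ncol(x)))),
                          class.weights = cw[!is.na(cw)], num.threads = 1,
                          importance = if (importance) "impurity" else "none",
                          seed = sample.int(.Machine$integer.max, 1))
    pr <- stats::predict(fit, data = data.frame(x[te, , drop = FALSE],
                                                check.names = FALSE))
    prob <- .vote_of(pr$predictions, levels(y))
    vote[te] <- prob[cbind(seq_len(sum(te)), match(y[te], levels(y)))]
    if (importance) imp[f, ] <- ranger::importance(fit)[colnames(x)]
  }
  list(vote = vote, importance = imp)
}

# Internal: prediction matrix with a column per class level, filling absent
# classes with zero probability.
.vote_of <- function(pred, levels) {
  out <- matrix(0, nrow(pred), length(levels),
                dimnames = list(NULL, levels))
  out[, colnames(pred)] <- pred
  out
}

#' Recursive binary clustering with random-forest refinement
#'
#' Applies [bisect_cells()] followed by [rf_refine()] recursively from the
#' root. A split is accepted only when both refined children have at least
#' `min_cluster_size` cells and the children differ by at least `min_deg`
#' DEGs under the marker gates ([count_degs()]); otherwise the node becomes
#' a leaf with a recorded stop reason. Cells abandoned during an accepted
#' refinement are excluded from all leaves. The recursion is deterministic
#' given the seed and invariant to the input cell order.
#'
#' @param expr An [expr_matrix()] or plain matrix of normalized expression.
#' @param cells Cells to cluster (default all).
#' @param params A [cluster_params()].
#' @return An object of class `ClusterTree` with elements `root` (nested
#'   nodes), `leaves` (named list, depth-first labels `SC1`, `SC2`, ...),
#'   `abandoned`, `params`, and `cells` (the input set). See
#'   [cluster_assignments()].
#' @export
recursive_cluster <- function(expr, cells = NULL, params = cluster_params()) {
  m <- .expr_of(expr)
  if (is.null(cells)) cells <- colnames(m)
  cells <- sort(cells)
  state <- new.env(parent = emptyenv())
  state$node <- 0L
  state$abandoned <- character(0)
  root <- .cluster_node(m, cells, params, state,
                        vote = stats::setNames(rep(NA_real_, length(cells)),
                                               cells))
  leaves <- list()
  collect <- function(node) {
    if (node$type == "leaf") leaves[[length(leaves) + 1L]] <<- node
    else { collect(node$left); collect(node$right) }
  }
  collect(root)
  names(leaves) <- sprintf("SC%d", seq_along(leaves))
  structure(list(root = root,
                 leaves = lapply(leaves, function(nd) nd$cells),
                 leaf_info = leaves, abandoned = sort(state$abandoned),
                 params = params, cells = cells),
            class = "ClusterTree")
}

.cluster_node <- function(m, cells, params, state, vote) {
  state$node <- state$node + 1L
  node_seed <- params$seed + 7919L * state$node
  leaf <- function(reason)
    list(type = "leaf", cells = cells, stop_reason = reason,
         vote_prob = vote[cells])
  if (length(cells) < 2 * params$min_cluster_size)
    return(leaf("min-size"))
  sub <- m[, cells, drop = FALSE]
  hvgs <- .node_features(sub)
  if (length(hvgs) < 2) return(leaf("degenerate"))
  bi <- tryCatch(bisect_cells(m, cells, hvgs = hvgs,
                              linkage = params$linkage),
                 no_split = function(e) NULL)
  if (is.null(bi)) return(leaf("min-size"))
  if (min(length(bi$left), length(bi$right)) < params$min_cluster_size)
    return(leaf("rejected: min-size"))
  sr <- rf_refine(m, bi$left, bi$right, params, features = hvgs,
                  seed = node_seed)
  if (sr$status != "ok") return(leaf("rejected: unstable-split"))
  if (min(length(sr$left), length(sr$right)) < params$min_cluster_size)
    return(leaf("rejected: min-size"))
  n_deg <- count_degs(m, sr$left, sr$right)
  if (n_deg < params$min_deg) return(leaf("rejected: too-few-DEGs"))
  state$abandoned <- c(state$abandoned, sr$abandoned)
  vote[names(sr$vote_prob)] <- sr$vote_prob
  list(type = "split", cells = cells, stop_reason = "accepted",
       feature_genes = sr$feature_genes, vote_prob = sr$vote_prob,
       abandoned = sr$abandoned, n_deg = n_deg,
       left = .cluster_node(m, sr$left, params, state, vote),
       right = .cluster_node(m, sr$right, params, state, vote))
}

#' Per-cell assignments of a cluster tree
#'
#' @param tree A `ClusterTree` from [recursive_cluster()].
#' @return A `data.frame` with `cell_id`, `cluster` (leaf label, `NA` for
#'   abandoned cells), `vote_prob` (from the deepest refinement that scored
#'   the cell; `NA` if the root was never split), and `abandoned`.
#' @export
cluster_assignments <- function(tree) {
  stopifnot(inherits(tree, "ClusterTree"))
  out <- data.frame(cell_id = tree$cells, cluster = NA_character_,
                    vote_prob = NA_real_, abandoned = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (lab in names(tree$leaves)) {
    idx <- match(tree$leaves[[lab]], out$cell_id)
    out$cluster[idx] <- lab
    out$vote_prob[idx] <- tree$leaf_info[[lab]]$vote_prob
  }
  ab <- match(tree$abandoned, out$cell_id)
  out$abandoned[ab] <- TRUE
  out
}

#' @export
print.ClusterTree <- function(x, ...) {
  sizes <- lengths(x$leaves)
  cat(sprintf("ClusterTree: %d cells -> %d leaves (%s), %d abandoned\n",
              length(x$cells), length(x$leaves),
              paste(sizes, collapse = ", "), length(x$abandoned)))
  invisible(x)
}
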
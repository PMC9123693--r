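# Methodology-replication utilities: grid-point labelling against ground
# truth, from-scratch depth-limited CART threshold discovery (the procedure
# that produced the detector's raw thresholds), and the starting-temperature
# vs cooling-rate regression.

TUNING_FEATURES <- c("sd_x", "sd_y", "sd_z", "temp_smooth", "roc_1min",
                     "roc_5min")

#' Label feature grid points against ground-truth non-wear intervals
#'
#' Each grid point is labelled `wear`, `nw_start` (first 10 minutes of a
#' non-wear period), `nw_middle` (beyond the first 10 minutes) or `nw_end`
#' (the 10 minutes following the period's end).  A period shorter than
#' 10 minutes is therefore all `nw_start`.
#'
#' @param features a `FeatureSeries`.
#' @param truth an `AnnotationSet` of reference non-wear intervals.
#' @return factor vector of length `nrow(features)`.
#' @export
label_grid_points <- function(features, truth) {
  step <- attr(features, "period_s")
  t0 <- as.numeric(attr(features, "start_time"))
  t <- t0 + features$time_s
  lab <- rep("wear", nrow(features))
  for (i in seq_len(nrow(truth))) {
    s <- as.numeric(as_utc(truth$start[i]))
    e <- as.numeric(as_utc(truth$end[i]))
    inside <- t >= s & t < e
    lab[inside & t < s + 600] <- "nw_start"
    lab[inside & t >= s + 600] <- "nw_middle"
    lab[t >= e & t < e + 600 & lab == "wear"] <- "nw_end"
  }
  factor(lab, levels = c("wear", "nw_start", "nw_middle", "nw_end"))
}

#' Build the start- and end-task training tables
#'
#' The start task contrasts `wear` against `nw_start` rows; the end task
#' contrasts `nw_middle` against `nw_end` rows.  Rows with any masked
#' feature are dropped.
#'
#' @param recordings list of `(recording, truth)` pairs as returned by
#'   [generate_recording()], or a single such pair.
#' @param params a [preprocess_params()] object.
#' @return list with data.frames `start` and `end` (feature columns plus a
#'   `label` factor) of class `LabeledWindowTable`, and `all` (every row
#'   with its four-way label).
#' @export
build_training_table <- function(recordings, params = preprocess_params()) {
  if (!is.null(recordings$recording)) recordings <- list(recordings)
  rows <- lapply(recordings, function(rt) {
    f <- extract_features(rt$recording, params)
    df <- as.data.frame(f)[, TUNING_FEATURES]
    df$label <- label_grid_points(f, rt$truth)
    df[stats::complete.cases(df), , drop = FALSE]
  })
  all <- do.call(rbind, rows)
  if (!any(all$label != "wear"))
    stop("ground truth contains no non-wear: both tasks would be empty")
  mk <- function(keep) {
    d <- all[all$label %in% keep, , drop = FALSE]
    d$label <- droplevels(d$label)
    structure(d, class = c("LabeledWindowTable", "data.frame"))
  }
  list(start = mk(c("wear", "nw_start")),
       end = mk(c("nw_middle", "nw_end")),
       all = all)
}

# --- from-scratch depth-limited CART ---------------------------------------

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p * p)
}

entropy_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Exhaustive best split for one node: candidate thresholds are midpoints of
# adjacent distinct observed values per feature; ties broken by lowest
# feature index, then lowest threshold.
best_split <- function(x, y, impurity) {
  n <- length(y)
  classes <- levels(y)
  best <- NULL
  for (j in seq_along(x)) {
    v <- x[[j]]
    o <- order(v)
    vs <- v[o]; ys <- y[o]
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0L) next
    # cumulative class counts left of each cut position
    cum <- apply(stats::model.matrix(~ ys - 1), 2, cumsum)
    colnames(cum) <- classes
    total <- cum[n, ]
    for (cut in distinct) {
      left <- cum[cut, ]
      right <- total - left
      imp <- (cut * impurity(left) + (n - cut) * impurity(right)) / n
      thr <- (vs[cut] + vs[cut + 1L]) / 2
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(feature = j, threshold = thr, impurity = imp)
      }
    }
  }
  best
}

leaf_node <- function(y) {
  counts <- table(y)
  list(leaf = TRUE, class = names(counts)[which.max(counts)],
       counts = counts, n = length(y))
}

grow_tree <- function(x, y, depth, max_depth, impurity) {
  counts <- table(y)
  if (depth >= max_depth || sum(counts > 0) < 2L || length(y) < 2L)
    return(leaf_node(y))
  sp <- best_split(x, y, impurity)
  if (is.null(sp) || sp$impurity >= gini_leaf_check(y, impurity) - 1e-12)
    return(leaf_node(y))
  go_left <- x[[sp$feature]] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       impurity = sp$impurity, n = length(y),
       left = grow_tree(lapply(x, `[`, go_left), y[go_left],
                        depth + 1L, max_depth, impurity),
       right = grow_tree(lapply(x, `[`, !go_left), y[!go_left],
                         depth + 1L, max_depth, impurity))
}

gini_leaf_check <- function(y, impurity) impurity(table(y))

#' Fit a depth-limited classification tree (from-scratch CART)
#'
#' Greedy binary splits minimising weighted Gini impurity (entropy by
#' option), exhaustive threshold search over midpoints of adjacent distinct
#' feature values, ties broken by lowest feature index then lowest
#' threshold, depth capped (default 3), no pruning and no class weighting.
#'
#' @param table a `LabeledWindowTable` (or any data.frame with numeric
#'   feature columns and a `label` factor).
#' @param depth maximum tree depth (root split = depth 1).
#' @param criterion `"gini"` (default) or `"entropy"`.
#' @return an object of class `DecisionTreeModel`.
#' @export
fit_cart <- function(table, depth = 3L, criterion = c("gini", "entropy")) {
  criterion <- match.arg(criterion)
  impurity <- if (criterion == "gini") gini_impurity else entropy_impurity
  y <- droplevels(factor(table$label))
  feats <- names(table)[vapply(table, is.numeric, TRUE)]
  x <- as.list(table[feats])
  root <- if (nlevels(y) < 2L) leaf_node(y) else
    grow_tree(x, y, 0L, depth, impurity)
  structure(list(root = root, features = feats, classes = levels(y),
                 depth = depth, criterion = criterion),
            class = "DecisionTreeModel")
}

#' Predict classes from a fitted tree
#'
#' @param object a `DecisionTreeModel`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.DecisionTreeModel <- function(object, newdata, ...) {
  one <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
    }
    node$class
  }
  x <- as.matrix(newdata[object$features])
  out <- vapply(seq_len(nrow(x)), function(i) one(object$root, x[i, ]), "")
  factor(out, levels = object$classes)
}

#' Render a fitted tree as human-readable threshold rules
#'
#' One line per leaf: the conjunction of split conditions on the path,
#' with units, and the leaf class.
#'
#' @param model a `DecisionTreeModel`.
#' @param units named character vector of units per feature (defaults cover
#'   the standard feature set).
#' @return character vector of rules.
#' @export
extract_rules <- function(model,
                          units = c(sd_x = "mg", sd_y = "mg", sd_z = "mg",
                                    temp_smooth = "degC",
                                    roc_1min = "degC/min",
                                    roc_5min = "degC/min")) {
  if (is.null(model$root)) stop("model has no fitted tree")
  feats <- model$features
  walk <- function(node, conds) {
    if (node$leaf) {
      lhs <- if (length(conds)) paste(conds, collapse = " AND ") else "TRUE"
      return(sprintf("%s -> %s", lhs, node$class))
    }
    f <- feats[node$feature]
    u <- units[f]
    u <- if (is.na(u)) "" else paste0(" ", u)
    c(walk(node$left, c(conds, sprintf("%s <= %g%s", f, node$threshold, u))),
      walk(node$right, c(conds, sprintf("%s > %g%s", f, node$threshold, u))))
  }
  walk(model$root, character(0))
}

#' Cross-validate tree depth
#'
#' K-fold cross-validated accuracy for a range of depth caps, mirroring the
#' depth-selection procedure that settled on depth 3.
#'
#' @param table a `LabeledWindowTable`.
#' @param depths integer vector of depth caps to evaluate.
#' @param k folds.
#' @param criterion split criterion.
#' @return data.frame with `depth` and mean cross-validated `accuracy`.
#' @export
cv_tree_depth <- function(table, depths = 1:5, k = 5L,
                          criterion = c("gini", "entropy")) {
  criterion <- match.arg(criterion)
  n <- nrow(table)
  fold <- rep_len(seq_len(k), n)[sample.int(n)]
  acc <- vapply(depths, function(d) {
    mean(vapply(seq_len(k), function(f) {
      tr <- table[fold != f, , drop = FALSE]
      te <- table[fold == f, , drop = FALSE]
      m <- fit_cart(tr, depth = d, criterion = criterion)
      mean(predict(m, te) == te$label)
    }, 0))
  }, 0)
  data.frame(depth = depths, accuracy = acc)
}

#' Starting-temperature vs cooling-rate regression
#'
#' Ordinary least squares of the maximum negative temperature
#' rate-of-change within each horizon after removal onset on the
#' temperature at removal onset, one fit per horizon.
#'
#' @param events data.frame with column `start_temp` (degC) and one column
#'   per horizon of maximum negative rate (degC/min), e.g. `roc_1`,
#'   `roc_3`, `roc_5`, `roc_10`.
#' @return data.frame with one row per horizon: `horizon`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
rate_regression <- function(events) {
  if (nrow(events) < 3L) stop("need at least 3 removal events")
  if (stats::var(events$start_temp) == 0)
    stop("starting temperatures are degenerate (zero variance)")
  horizons <- setdiff(names(events), "start_temp")
  rows <- lapply(horizons, function(h) {
    fit <- stats::lm(events[[h]] ~ events$start_temp)
    data.frame(horizon = h, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared)
  })
  do.call(rbind, rows)
}

#' Extract removal-edge events from features and ground truth
#'
#' For each reference non-wear interval, records the smoothed temperature
#' at onset and the maximum negative 1-minute rate-of-change within each
#' horizon (minutes) after onset.
#'
#' @param features a `FeatureSeries`.
#' @param truth an `AnnotationSet`.
#' @param horizons horizons in minutes.
#' @return data.frame suitable for [rate_regression()].
#' @export
removal_edge_events <- function(features, truth, horizons = c(1, 3, 5, 10)) {
  step <- attr(features, "period_s")
  t0 <- as.numeric(attr(features, "start_time"))
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    s_idx <- round((as.numeric(as_utc(truth$start[i])) - t0) / step) + 1L
    if (s_idx < 1L || s_idx > nrow(features)) return(NULL)
    out <- list(start_temp = features$temp_smooth[s_idx])
    for (h in horizons) {
      hi <- min(nrow(features), s_idx + round(h * 60 / step) - 1L)
      r <- features$roc_1min[s_idx:hi]
      out[[sprintf("roc_%g", h)]] <- suppressWarnings(min(r, na.rm = TRUE))
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
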
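# Window labelling, from-scratch CART against independent oracles, rule
# rendering, depth cross-validation and the edge-rate regression.


test_that("grid labels stratify truth intervals by the 10-minute rule", {
  f <- fake_features(rep(29, 24 * 900))        # 24 h grid
  truth <- annotation_set("p1", T0 + 2 * 3600, T0 + 2 * 3600 + 30 * 60,
                          source = "synthetic_truth")
  lab <- label_grid_points(f, truth)
  expect_equal(sum(lab == "nw_start"), 150)    # first 10 min at 0.25 Hz
  expect_equal(sum(lab == "nw_middle"), 300)   # remaining 20 min
  expect_equal(sum(lab == "nw_end"), 150)      # 10 min after the end
  expect_equal(sum(lab == "wear"), 24 * 900 - 600)
  # a removal under 10 minutes is all nw_start with an empty middle
  short <- annotation_set("p1", T0 + 3600, T0 + 3600 + 8 * 60,
                          source = "synthetic_truth")
  lab2 <- label_grid_points(f, short)
  expect_equal(sum(lab2 == "nw_start"), 120)
  expect_equal(sum(lab2 == "nw_middle"), 0)
  # two removals: strata sum to expected totals
  two <- annotation_set("p1", T0 + c(2, 6) * 3600,
                        T0 + c(2, 6) * 3600 + c(30, 15) * 60,
                        source = "synthetic_truth")
  lab3 <- label_grid_points(f, two)
  expect_equal(sum(lab3 != "wear"), (30 + 10 + 15 + 10) * 15)
})

test_that("training tables split into start and end tasks", {
  g <- generate_recording(synthetic_config(seed = 14, duration_h = 8,
                                           sleep_blocks = NULL,
                                           n_removals = 2, skin_c_sd = 0))
  tab <- build_training_table(g)
  expect_setequal(levels(tab$start$label), c("wear", "nw_start"))
  expect_setequal(levels(tab$end$label), c("nw_middle", "nw_end"))
  expect_true(all(c("sd_x", "roc_5min", "temp_smooth") %in% names(tab$start)))
  # no non-wear at all is an error, not an empty table
  g0 <- generate_recording(synthetic_config(seed = 15, duration_h = 6,
                                            sleep_blocks = NULL,
                                            n_removals = 0))
  expect_error(build_training_table(g0), "no non-wear")
})

test_that("CART finds the unique split of perfectly separable data", {
  df <- data.frame(x = c(1, 2, 3, 4, 6, 7, 8, 9),
                   label = factor(rep(c("A", "B"), each = 4)))
  m <- fit_cart(df, depth = 3)
  expect_false(m$root$leaf)
  expect_equal(m$root$threshold, 5)
  expect_true(m$root$left$leaf)
  expect_equal(as.character(predict(m, data.frame(x = c(0, 10)))),
               c("A", "B"))
  # a pure table collapses to a single leaf
  pure <- data.frame(x = 1:5, label = factor(rep("A", 5)))
  mp <- fit_cart(pure)
  expect_true(mp$root$leaf)
  expect_equal(mp$root$class, "A")
})

test_that("CART matches the exhaustive-split oracle on random small tables", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    df <- data.frame(a = round(rnorm(n), 2), b = round(runif(n, 0, 10), 1),
                     label = factor(sample(c("A", "B"), n, TRUE)))
    m <- fit_cart(df, depth = 1)
    if (m$root$leaf) {
      expect_gte(oracle_best_gini(df), gini_impurity(table(df$label)) - 1e-12)
    } else {
      expect_equal(tree_root_impurity(m), oracle_best_gini(df),
                   tolerance = 1e-12)
    }
  }
})

test_that("CART agrees with rpart on a clean two-feature problem", {
  skip_if_not_installed("rpart")
  set.seed(8)
  df <- data.frame(x = c(rnorm(60, 0), rnorm(60, 6)),
                   z = rnorm(120),
                   label = factor(rep(c("A", "B"), each = 60)))
  mine <- fit_cart(df, depth = 1)
  rp <- rpart::rpart(label ~ x + z, df, method = "class",
                     control = rpart::rpart.control(maxdepth = 1,
                                                    minsplit = 2, cp = 0))
  expect_equal(mine$features[mine$root$feature], "x")
  expect_equal(mine$root$threshold, rp$splits[1, "index"], tolerance = 1e-9)
})

test_that("tie-breaking picks the lowest feature index, then lowest threshold", {
  # two identical features: both yield the same impurity; feature 1 wins
  df <- data.frame(f1 = c(1, 2, 8, 9), f2 = c(1, 2, 8, 9),
                   label = factor(c("A", "A", "B", "B")))
  m <- fit_cart(df, depth = 1)
  expect_equal(m$root$feature, 1L)
})

test_that("the synthetic start task recovers stillness plus cooling-rate structure", {
  gs <- lapply(1:3, function(i)
    generate_recording(synthetic_config(seed = 400 + i, duration_h = 12,
                                        sleep_blocks = NULL,
                                        n_removals = 3)))
  # reference-style minute-precision labels blur the strata the way the
  # expert annotations do
  gs <- lapply(gs, function(g) {
    tr <- g$truth
    g$truth <- annotation_set(
      tr$participant_id[1],
      as.POSIXct(round(as.numeric(tr$start) / 60) * 60, tz = "UTC",
                 origin = "1970-01-01"),
      as.POSIXct(round(as.numeric(tr$end) / 60) * 60, tz = "UTC",
                 origin = "1970-01-01"),
      source = "synthetic_truth")
    g
  })
  tab <- build_training_table(gs)
  m <- fit_cart(tab$start, depth = 3)
  internal_nodes <- function(node) {
    if (node$leaf) return(NULL)
    rbind(data.frame(feature = m$features[node$feature],
                     threshold = node$threshold),
          internal_nodes(node$left), internal_nodes(node$right))
  }
  nodes <- internal_nodes(m$root)
  # root: relative inactivity at a quiet threshold
  expect_match(nodes$feature[1], "^sd_")
  expect_lt(nodes$threshold[1], 8)
  # and a cooling-rate split in the plausible band of the removal edges
  roc <- nodes[nodes$feature == "roc_5min", , drop = FALSE]
  expect_gte(nrow(roc), 1L)
  expect_true(any(roc$threshold >= -0.45 & roc$threshold <= -0.15))
})

test_that("rules render as threshold conjunctions with units", {
  df <- data.frame(roc_5min = c(-0.5, -0.4, 0, 0.1),
                   sd_x = c(2, 3, 50, 60),
                   label = factor(c("nw_start", "nw_start", "wear", "wear")))
  m <- fit_cart(df, depth = 2)
  rules <- extract_rules(m)
  expect_length(rules, 2L)
  expect_true(any(grepl("roc_5min <= .* degC/min -> nw_start", rules)))
  expect_error(extract_rules(structure(list(root = NULL),
                                       class = "DecisionTreeModel")),
               "no fitted tree")
})

test_that("depth cross-validation reports accuracy per depth", {
  set.seed(5)
  df <- data.frame(x = rnorm(200), label = factor(sample(c("A", "B"), 200,
                                                         TRUE)))
  df$label[df$x > 0.5] <- "B"
  cv <- cv_tree_depth(df, depths = 1:3, k = 4)
  expect_equal(cv$depth, 1:3)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
})

test_that("edge-rate regression recovers exact fits and null behaviour", {
  ev <- data.frame(start_temp = c(26, 28, 30, 32),
                   roc_5 = -0.1 - 0.05 * c(26, 28, 30, 32))
  fit <- suppressWarnings(rate_regression(ev))   # exact fit warns in summary.lm
  expect_equal(fit$slope, -0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(10)
  null <- data.frame(start_temp = rnorm(200, 29, 2), roc_5 = rnorm(200))
  expect_lt(rate_regression(null)$r_squared, 0.05)
  expect_error(rate_regression(ev[1:2, ]), "at least 3")
  degenerate <- data.frame(start_temp = rep(29, 5), roc_5 = rnorm(5))
  expect_error(rate_regression(degenerate), "degenerate")
})

test_that("synthetic removal edges show hotter-starts-cool-faster", {
  gs <- lapply(1:4, function(i)
    generate_recording(synthetic_config(seed = 500 + i, duration_h = 12,
                                        sleep_blocks = NULL, n_removals = 3,
                                        skin_c_sd = 2.5)))
  events <- do.call(rbind, lapply(gs, function(g)
    removal_edge_events(extract_features(g$recording), g$truth)))
  fit <- rate_regression(events[, c("start_temp", "roc_5")])
  expect_lt(fit$slope, 0)
})
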
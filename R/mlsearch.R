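## Two-stage model-combination search over the presence-absence matrix:
## stage 1 ranks gene families by a selector's importance, stage 2 evaluates
## a classifier on incrementally larger feature batches under stratified CV.
## Saltwater is the positive class (saltwater=1 / freshwater=0) throughout.

ML_ALGORITHMS <- c("random_forest", "lasso", "ridge", "elastic_net",
                   "linear_boosting", "svm_linear", "knn", "naive_bayes",
                   "gradient_boosting", "decision_tree")
# algorithms yielding sparse or importance-ranked solutions
SELECTOR_CAPABLE <- c("random_forest", "lasso", "elastic_net",
                      "linear_boosting", "gradient_boosting", "decision_tree")
# classifiers whose fit is itself sparse (no batch search needed)
SPARSE_CLASSIFIERS <- c("lasso", "elastic_net")
# classifiers with signed per-feature weights
SIGNED_CLASSIFIERS <- c("lasso", "ridge", "elastic_net", "svm_linear",
                        "linear_boosting")

#' Describe one model for the two-stage search
#'
#' @param algorithm one of `"random_forest"`, `"lasso"`, `"ridge"`,
#'   `"elastic_net"`, `"linear_boosting"`, `"svm_linear"`, `"knn"`,
#'   `"naive_bayes"`, `"gradient_boosting"`, `"decision_tree"`.
#' @param alpha elastic-net mixing parameter in (0, 1); required for
#'   `"elastic_net"`.
#' @param ... further hyperparameters (e.g. `k` for knn, `ntree`).
#' @return a `model_spec`.
#' @export
model_spec <- function(algorithm, alpha = NULL, ...) {
  algorithm <- match.arg(algorithm, ML_ALGORITHMS)
  hp <- list(...)
  if (algorithm == "elastic_net") {
    if (is.null(alpha) || alpha <= 0 || alpha >= 1)
      stop("elastic_net requires alpha in (0, 1)")
    hp$alpha <- alpha
  } else if (!is.null(alpha)) hp$alpha <- alpha
  structure(list(algorithm = algorithm, hyperparams = hp,
                 embedded_selection = algorithm %in% SPARSE_CLASSIFIERS),
            class = "model_spec")
}

spec_label <- function(spec) {
  if (is.null(spec)) return("none")
  if (spec$algorithm == "elastic_net")
    sprintf("elastic_net[%.1f]", spec$hyperparams$alpha)
  else spec$algorithm
}

#' Build the (selector, classifier) combination registry
#'
#' The default registry pairs every importance- or sparsity-capable selector
#' (random forest, lasso, elastic net over the alpha grid, linear boosting,
#' gradient boosting, decision tree) with every classifier, and adds one
#' classifier-only entry (no pre-selection) per classifier. The total count
#' is logged, never hard-coded.
#'
#' @param selectors list of `model_spec` selectors (NULL entries allowed for
#'   classifier-only combos); default = full capable set.
#' @param classifiers list of `model_spec` classifiers; default = all
#'   algorithms with elastic net at alpha 0.2/0.4/0.6/0.8.
#' @param alpha_grid elastic-net mixing values used in the defaults.
#' @return ordered list of `list(selector=, classifier=)` pairs.
#' @export
build_registry <- function(selectors = NULL, classifiers = NULL,
                           alpha_grid = c(0.2, 0.4, 0.6, 0.8)) {
  if (is.null(classifiers)) {
    classifiers <- list()
    for (a in setdiff(ML_ALGORITHMS, "elastic_net"))
      classifiers[[length(classifiers) + 1L]] <- model_spec(a)
    for (al in alpha_grid)
      classifiers[[length(classifiers) + 1L]] <- model_spec("elastic_net", al)
  }
  if (is.null(selectors)) {
    selectors <- list()
    for (a in setdiff(SELECTOR_CAPABLE, "elastic_net"))
      selectors[[length(selectors) + 1L]] <- model_spec(a)
    for (al in alpha_grid)
      selectors[[length(selectors) + 1L]] <- model_spec("elastic_net", al)
  }
  registry <- list()
  for (s in selectors) for (cl in classifiers)
    registry[[length(registry) + 1L]] <- list(selector = s, classifier = cl)
  for (cl in classifiers)
    registry[[length(registry) + 1L]] <- list(selector = NULL, classifier = cl)
  sa_log("registry built: ", length(registry), " model combinations")
  registry
}

#' Deterministic stratified cross-validation folds
#'
#' Fold assignment is a pure function of the seed and the sample order, so
#' every combination in one search sees identical folds.
#'
#' @param labels factor or character class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample.
#' @export
make_cv_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  if (min(table(labels)) < k)
    stop("cv_folds exceeds the smallest class count")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

## ---- learner wrappers ---------------------------------------------------

# y: factor with levels c("freshwater", "saltwater"); x: numeric matrix.
# Returns list(predict = function(newx) factor, weights = named signed
# numeric or NULL).
fit_learner <- function(spec, x, y, seed) {
  alg <- spec$algorithm
  set.seed(seed)
  lv <- levels(y)
  if (alg %in% c("lasso", "ridge", "elastic_net")) {
    alpha <- switch(alg, lasso = 1, ridge = 0, spec$hyperparams$alpha)
    nf <- max(3L, min(5L, min(table(y))))
    foldid <- make_cv_folds(y, nf, seed)
    feats <- colnames(x)
    xg <- x
    if (ncol(xg) < 2)  # glmnet needs >= 2 columns; pad with a null feature
      xg <- cbind(xg, `.pad.` = 0)
    fit <- glmnet::cv.glmnet(xg, y, family = "binomial", alpha = alpha,
                             foldid = foldid, standardize = FALSE)
    w <- as.numeric(coef(fit, s = "lambda.min"))[-1L]
    names(w) <- colnames(xg)
    w <- w[feats]
    list(predict = function(newx) {
      nx <- newx[, feats, drop = FALSE]
      if (ncol(nx) < 2) nx <- cbind(nx, `.pad.` = 0)
      p <- predict(fit, nx, s = "lambda.min", type = "class")
      factor(as.character(p), levels = lv)
    }, weights = w)
  } else if (alg == "random_forest") {
    fit <- randomForest::randomForest(
      x, y, ntree = spec$hyperparams$ntree %||% 500L, importance = FALSE)
    list(predict = function(newx)
      factor(as.character(predict(fit, newx[, colnames(x), drop = FALSE])),
             levels = lv),
      weights = NULL,
      importance = fit$importance[, "MeanDecreaseGini"])
  } else if (alg == "svm_linear") {
    fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    names(w) <- colnames(x)
    # e1071 orients the decision value toward the first factor level;
    # flip so positive weight pushes toward the second (saltwater) level
    if (fit$labels[1L] == 1L) w <- -w
    list(predict = function(newx)
      factor(as.character(predict(fit, newx[, colnames(x), drop = FALSE])),
             levels = lv),
      weights = w)
  } else if (alg == "knn") {
    kk <- spec$hyperparams$k %||% 5L
    list(predict = function(newx)
      factor(as.character(class::knn(x, newx[, colnames(x), drop = FALSE],
                                     y, k = kk)), levels = lv),
      weights = NULL)
  } else if (alg == "naive_bayes") {
    df <- as.data.frame(lapply(as.data.frame(x), function(v)
      factor(as.character(v), levels = c("0", "1"))))
    names(df) <- colnames(x)
    fit <- e1071::naiveBayes(df, y, laplace = 1)
    list(predict = function(newx) {
      nd <- as.data.frame(lapply(
        as.data.frame(newx[, colnames(x), drop = FALSE]),
        function(v) factor(as.character(v), levels = c("0", "1"))))
      names(nd) <- colnames(x)
      factor(as.character(predict(fit, nd)), levels = lv)
    }, weights = NULL)
  } else if (alg %in% c("gradient_boosting", "linear_boosting")) {
    booster <- if (alg == "gradient_boosting") "gbtree" else "gblinear"
    params <- list(objective = "binary:logistic", booster = booster,
                   nthread = 1L, seed = seed)
    if (booster == "gbtree") { params$max_depth <- 3L; params$eta <- 0.3 }
    dm <- xgboost::xgb.DMatrix(x, label = as.integer(y == lv[2L]),
                               nthread = 1L)
    fit <- xgboost::xgb.train(params = params, data = dm,
                              nrounds = spec$hyperparams$nrounds %||% 50L,
                              verbose = 0)
    w <- NULL
    if (booster == "gblinear") {
      imp <- xgboost::xgb.importance(model = fit)
      w <- numeric(ncol(x)); names(w) <- colnames(x)
      w[imp$Feature] <- imp$Weight
    }
    list(predict = function(newx) {
      p <- predict(fit, xgboost::xgb.DMatrix(
        newx[, colnames(x), drop = FALSE], nthread = 1L))
      factor(ifelse(p > 0.5, lv[2L], lv[1L]), levels = lv)
    }, weights = w, model = fit)
  } else if (alg == "decision_tree") {
    df <- data.frame(x, check.names = FALSE); df$.y <- y
    fit <- rpart::rpart(.y ~ ., df, method = "class",
                        control = rpart::rpart.control(xval = 0))
    list(predict = function(newx)
      factor(as.character(predict(fit, data.frame(newx[, colnames(x),
                                                       drop = FALSE],
                                                  check.names = FALSE),
                                  type = "class")), levels = lv),
      weights = NULL,
      importance = fit$variable.importance)
  } else stop("unknown algorithm: ", alg)
}

## ---- stage 1: feature ranking -------------------------------------------

#' Rank gene families by a selector model's importance
#'
#' Tree and forest selectors rank by impurity importance; sparse linear
#' selectors rank by |coefficient| at a CV-chosen penalty and return only
#' families with nonzero coefficients. Deterministic given the seed.
#'
#' @param pam presence-absence matrix restricted to labeled species.
#' @param labels factor with levels freshwater/saltwater, one per species.
#' @param selector a `model_spec`.
#' @param seed integer seed.
#' @param max_rank cap on the number of returned families.
#' @return data frame (family_id, score) in decreasing importance order.
#' @export
stage1_select <- function(pam, labels, selector, seed, max_rank = 300L) {
  x <- pam$values
  y <- as_habitat_factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("labels must contain two classes")
  if (!selector$algorithm %in% SELECTOR_CAPABLE)
    stop(selector$algorithm, " cannot act as a selector")
  alg <- selector$algorithm
  set.seed(seed)
  if (alg %in% c("lasso", "elastic_net")) {
    fit <- fit_learner(selector, x, y, seed)
    sc <- abs(fit$weights)
  } else if (alg == "random_forest") {
    set.seed(seed)
    rf <- randomForest::randomForest(x, y, ntree = 500L)
    sc <- rf$importance[, "MeanDecreaseGini"]
  } else if (alg == "decision_tree") {
    fit <- fit_learner(selector, x, y, seed)
    sc <- numeric(ncol(x)); names(sc) <- colnames(x)
    vi <- fit$importance
    sc[names(vi)] <- vi
  } else if (alg == "linear_boosting") {
    fit <- fit_learner(selector, x, y, seed)
    sc <- abs(fit$weights)
  } else if (alg == "gradient_boosting") {
    fit <- fit_learner(selector, x, y, seed)
    imp <- xgboost::xgb.importance(model = fit$model)
    sc <- numeric(ncol(x)); names(sc) <- colnames(x)
    sc[imp$Feature] <- imp$Gain
  }
  sc[apply(x, 2L, function(v) length(unique(v)) == 1L)] <- 0  # constants carry no signal
  keep <- which(sc > 0)
  ord <- keep[order(-sc[keep])]
  ord <- ord[seq_len(min(length(ord), max_rank))]
  data.frame(family_id = colnames(x)[ord], score = unname(sc[ord]),
             row.names = NULL)
}

as_habitat_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("freshwater", "saltwater"))
  if (anyNA(f)) stop("labels must be freshwater/saltwater only")
  f
}

## ---- stage 2: batched CV evaluation -------------------------------------

#' Evaluate a classifier on incrementally larger feature batches
#'
#' Sparse classifiers (lasso, elastic net) are fit on the whole stage-1
#' candidate set; all other classifiers are evaluated on the top-k ranked
#' features for k = batch, 2*batch, ... (plus the full set) and the k with
#' the best mean stratified-CV accuracy is kept (ties favor smaller k).
#'
#' @param pam presence-absence matrix restricted to labeled species.
#' @param labels habitat labels.
#' @param ranking stage-1 output (data frame family_id, score), or NULL to
#'   use every family with no pre-selection.
#' @param classifier a `model_spec`.
#' @param cv_folds number of CV folds.
#' @param batch_size feature batch size.
#' @param seed integer seed.
#' @param folds optional precomputed fold ids (shared across combos).
#' @return a `combo_result`.
#' @export
stage2_evaluate <- function(pam, labels, ranking, classifier, cv_folds = 5L,
                            batch_size = 50L, seed = 1L, folds = NULL) {
  x <- pam$values
  y <- as_habitat_factor(labels)
  if (is.null(folds)) folds <- make_cv_folds(y, cv_folds, seed)
  no_preselect <- is.null(ranking)
  feats <- if (no_preselect) colnames(x) else as.character(ranking$family_id)
  if (!length(feats)) stop("ranking is empty")

  if (classifier$embedded_selection || no_preselect) {
    kgrid <- length(feats)
  } else {
    kgrid <- if (length(feats) <= batch_size) length(feats) else
      unique(c(seq(batch_size, length(feats), by = batch_size),
               length(feats)))
  }

  best <- NULL
  for (k in kgrid) {
    sel <- feats[seq_len(k)]
    acc <- cv_accuracies(x[, sel, drop = FALSE], y, folds, classifier, seed)
    if (is.null(best) || mean(acc) > mean(best$acc) + 1e-12)
      best <- list(k = k, acc = acc)
  }

  sel <- feats[seq_len(best$k)]
  final <- fit_learner(classifier, x[, sel, drop = FALSE], y, seed)
  if (!is.null(final$weights)) {
    w <- final$weights
    selected <- names(w)[w != 0]
    weights <- w[selected]
    signed <- classifier$algorithm %in% SIGNED_CLASSIFIERS
  } else {
    selected <- sel
    weights <- if (no_preselect) stats::setNames(rep(NA_real_, length(sel)), sel)
               else stats::setNames(ranking$score[seq_len(best$k)], sel)
    signed <- FALSE
  }
  structure(list(
    selector = NULL, classifier = classifier,
    cv_accuracy = mean(best$acc), fold_accuracies = best$acc,
    n_features_used = length(selected),
    selected_families = selected, weights = weights,
    weights_signed = signed, k_evaluated = kgrid, k_best = best$k),
    class = "combo_result")
}

cv_accuracies <- function(x, y, folds, classifier, seed) {
  vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_learner(classifier, x[tr, , drop = FALSE], y[tr], seed)
    pred <- fit$predict(x[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
}

#' @export
print.combo_result <- function(x, ...) {
  cat(sprintf("combo_result: %s + %s | CV accuracy %.3f | %d features\n",
              spec_label(x$selector), spec_label(x$classifier),
              x$cv_accuracy, x$n_features_used))
  invisible(x)
}

## ---- full search ---------------------------------------------------------

#' Run the two-stage model-combination search
#'
#' Every combination is evaluated with identical stratified folds (a paired
#' comparison). The best combination maximizes mean CV accuracy, with ties
#' broken by fewer selected features then registry order. Outgroup species
#' are excluded from training.
#'
#' @param pam presence-absence matrix (all species).
#' @param meta species metadata.
#' @param registry output of [build_registry()].
#' @param config an [analysis_config()].
#' @return list with `best` (combo_result), `all` (list of combo_result) and
#'   `leaderboard` (data frame).
#' @export
run_combination_search <- function(pam, meta, registry,
                                   config = analysis_config()) {
  hab <- meta$habitat[match(rownames(pam$values), meta$species_id)]
  keep <- hab %in% c("saltwater", "freshwater")
  sub <- presence_absence_matrix(pam$values[keep, , drop = FALSE])
  labels <- hab[keep]
  y <- as_habitat_factor(labels)
  seed <- derive_seed(config$seed, "ml")
  folds <- make_cv_folds(y, config$cv_folds, seed)

  rankings <- list()   # cache stage-1 rankings per selector label
  results <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    combo <- registry[[i]]
    ranking <- NULL
    if (!is.null(combo$selector)) {
      lab <- spec_label(combo$selector)
      if (is.null(rankings[[lab]]))
        rankings[[lab]] <- stage1_select(sub, labels, combo$selector, seed)
      ranking <- rankings[[lab]]
    }
    res <- if (!is.null(ranking) && nrow(ranking) == 0) {
      structure(list(selector = combo$selector, classifier = combo$classifier,
                     cv_accuracy = 0, fold_accuracies = rep(0, config$cv_folds),
                     n_features_used = 0L, selected_families = character(0),
                     weights = numeric(0), weights_signed = FALSE),
                class = "combo_result")
    } else {
      stage2_evaluate(sub, labels, ranking, combo$classifier,
                      cv_folds = config$cv_folds,
                      batch_size = config$batch_size, seed = seed,
                      folds = folds)
    }
    res$selector <- combo$selector
    results[[i]] <- res
  }
  acc <- vapply(results, function(r) r$cv_accuracy, numeric(1))
  nfeat <- vapply(results, function(r) r$n_features_used, numeric(1))
  ord <- order(-acc, nfeat, seq_along(results))
  leaderboard <- data.frame(
    rank = seq_along(ord),
    selector = vapply(results[ord], function(r) spec_label(r$selector),
                      character(1)),
    classifier = vapply(results[ord], function(r) spec_label(r$classifier),
                        character(1)),
    n_features = nfeat[ord],
    cv_accuracy = acc[ord])
  list(best = results[[ord[1L]]], all = results, leaderboard = leaderboard)
}

#' Split the best combination's families by weight sign
#'
#' With saltwater as the positive class, a positive weight pushes the
#' prediction toward saltwater, so positive-weight families form the
#' saltwater group and negative-weight families the freshwater group;
#' zero-weight families are dropped.
#'
#' @param best a `combo_result` from a linear (signed-weight) classifier.
#' @param positive_class habitat treated as the positive class.
#' @return list with `salt_group` and `fresh_group` family id vectors.
#' @export
categorize_by_weight <- function(best, positive_class = "saltwater") {
  if (!isTRUE(best$weights_signed))
    stop("classifier '", spec_label(best$classifier),
         "' has no signed weights; use a linear final stage ",
         "(lasso/ridge/elastic_net/svm_linear/linear_boosting)")
  w <- best$weights[best$weights != 0]
  pos <- names(w)[w > 0]
  neg <- names(w)[w < 0]
  if (positive_class == "saltwater")
    list(salt_group = pos, fresh_group = neg)
  else
    list(salt_group = neg, fresh_group = pos)
}
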
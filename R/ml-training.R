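# Per-target classifier training: six probability-emitting algorithms, small
# hyperparameter grids, repeated stratified CV, winner by mean MCC.

# Each algorithm: fit(X, y01, w, params, seed) -> model;
# score(model, X) -> P(active) in [0,1]; grid: list of params lists.
.ALGOS <- list(
  logistic = list(
    grid = list(list()),
    fit = function(X, y, w, params, seed) {
      df <- as.data.frame(X)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial,
                                  weights = ifelse(y == 1, w, 1)))
    },
    score = function(model, X) {
      p <- suppressWarnings(
        stats::predict(model, newdata = as.data.frame(X), type = "response"))
      pmin(pmax(as.numeric(p), 0), 1)
    }
  ),
  random_forest = list(
    grid = list(list(num.trees = 300), list(num.trees = 600)),
    fit = function(X, y, w, params, seed) {
      ranger::ranger(x = as.data.frame(X),
                     y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = params$num.trees,
                     seed = seed, num.threads = 1,
                     case.weights = ifelse(y == 1, w, 1))
    },
    score = function(model, X) {
      stats::predict(model, data = as.data.frame(X),
                     num.threads = 1)$predictions[, "1"]
    }
  ),
  extra_trees = list(
    grid = list(list(num.trees = 300)),
    fit = function(X, y, w, params, seed) {
      ranger::ranger(x = as.data.frame(X),
                     y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = params$num.trees,
                     splitrule = "extratrees", num.random.splits = 1,
                     seed = seed, num.threads = 1,
                     case.weights = ifelse(y == 1, w, 1))
    },
    score = function(model, X) {
      stats::predict(model, data = as.data.frame(X),
                     num.threads = 1)$predictions[, "1"]
    }
  ),
  xgboost = list(
    grid = list(list(nrounds = 60, max_depth = 3),
                list(nrounds = 150, max_depth = 4)),
    fit = function(X, y, w, params, seed) {
      dtrain <- xgboost::xgb.DMatrix(data = X, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = params$max_depth, nthread = 1,
                      scale_pos_weight = w),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    score = function(model, X) {
      as.numeric(stats::predict(model, xgboost::xgb.DMatrix(data = X)))
    }
  ),
  # Radial SVM scored through the logistic of the decision value; the
  # downstream calibrator maps it to a probability.
  svm_radial = list(
    grid = list(list(cost = 1), list(cost = 10)),
    fit = function(X, y, w, params, seed) {
      yf <- factor(y, levels = c(0, 1))
      fit <- e1071::svm(x = X, y = yf, kernel = "radial", cost = params$cost,
                        class.weights = c(`0` = 1, `1` = w), scale = TRUE)
      # libsvm orients the decision value toward the class seen first in
      # training; record whether that is the inactive class so scores can be
      # flipped to mean "more active".
      dv <- attr(stats::predict(fit, X[1L, , drop = FALSE],
                                decision.values = TRUE), "decision.values")
      attr(fit, ".flip") <- startsWith(colnames(dv)[1L], "0")
      fit
    },
    score = function(model, X) {
      d <- attr(stats::predict(model, X, decision.values = TRUE),
                "decision.values")[, 1]
      if (isTRUE(attr(model, ".flip"))) d <- -d
      stats::plogis(as.numeric(d))
    }
  ),
  neural_net = list(
    grid = list(list(size = 3, decay = 0.1), list(size = 5, decay = 0.01)),
    fit = function(X, y, w, params, seed) {
      set.seed(seed)
      Xs <- scale(X)
      fit <- nnet::nnet(x = Xs, y = y, size = params$size,
                        decay = params$decay, maxit = 200, trace = FALSE,
                        weights = ifelse(y == 1, w, 1), entropy = TRUE)
      fit$.center <- attr(Xs, "scaled:center")
      fit$.scale <- attr(Xs, "scaled:scale")
      fit
    },
    score = function(model, X) {
      sc <- model$.scale
      sc[sc == 0] <- 1
      Xs <- scale(X, center = model$.center, scale = sc)
      pmin(pmax(as.numeric(stats::predict(model, Xs)), 0), 1)
    }
  )
)

#' Names of the candidate algorithms
#'
#' The six probability-emitting classifier families tried per target. The
#' roster is an argument of [trainTargetModel()], so any subset (or ordering)
#' can be used.
#'
#' @return character vector of algorithm names.
#' @export
availableAlgorithms <- function() names(.ALGOS)

# Assemble the descriptor design matrix and 0/1 labels for non-decoy records.
.designMatrix <- function(ds) {
  rec <- records(ds)
  rec <- rec[rec$label != "decoy", , drop = FALSE]
  X <- computeDescriptorMatrix(rec$smiles)
  keep <- match(rownames(X), rec$smiles)
  list(X = X, y = as.integer(rec$label[keep] == "active"),
       ids = rec$compound_id[keep])
}

#' Train and select a per-target classifier
#'
#' Computes 2D descriptors for all non-decoy records, prunes them
#' ([pruneDescriptors()]), then evaluates each candidate algorithm over a
#' small hyperparameter grid with stratified 5-fold cross-validation repeated
#' 3 times (seeded, identical folds for every candidate). Per-fold accuracy,
#' MCC, Cohen's kappa and AUC are recorded; the algorithm/hyperparameter
#' combination with the highest mean MCC wins, and the exported classifier is
#' the winning combination's single fold-model with the highest fold MCC. The
#' active class receives weight n_inactive / n_active during fitting.
#'
#' @param ds a curated [TargetDataset-class] with at least
#'   \code{minPerClass} members of each class.
#' @param seed integer seed controlling folds and stochastic fitters.
#' @param algorithms subset of [availableAlgorithms()] to try.
#' @param cvFolds,cvRepeats cross-validation geometry (default 5 x 3).
#' @param minPerClass minimum records per class (default 10).
#' @param pruneArgs list of arguments forwarded to [pruneDescriptors()].
#' @return a [TrainedTargetModel-class] (calibrator method "none"; fit one
#'   with [fitCalibrator()]).
#' @export
trainTargetModel <- function(ds, seed = 1L,
                             algorithms = availableAlgorithms(),
                             cvFolds = 5L, cvRepeats = 3L,
                             minPerClass = 10L, pruneArgs = list()) {
  stopifnot(is(ds, "TargetDataset"))
  algorithms <- match.arg(algorithms, names(.ALGOS), several.ok = TRUE)
  rec <- records(ds)
  n_act <- sum(rec$label == "active"); n_inact <- sum(rec$label == "inactive")
  if (min(n_act, n_inact) < minPerClass) {
    stop("target '", targetId(ds), "' has ", n_act, " actives / ", n_inact,
         " inactives (need >= ", minPerClass,
         " each); consider serving similarity-only predictions",
         call. = FALSE)
  }
  dm <- .designMatrix(ds)
  n_act <- sum(dm$y == 1); n_inact <- sum(dm$y == 0)
  w <- n_inact / n_act

  kept <- do.call(pruneDescriptors,
                  c(list(x = dm$X, y = dm$y, seed = seed), pruneArgs))
  X <- dm$X[, kept, drop = FALSE]
  y <- dm$y

  folds <- .stratifiedFolds(y, k = cvFolds, times = cvRepeats, seed = seed)

  evalConfig <- function(algo, params, keepModels = FALSE) {
    a <- .ALGOS[[algo]]
    out <- list(); models <- list(); m <- 0L
    for (rep in seq_along(folds)) {
      for (f in seq_len(cvFolds)) {
        test <- folds[[rep]] == f
        fit <- a$fit(X[!test, , drop = FALSE], y[!test], w, params,
                     seed + 7L * rep + f)
        sc <- a$score(fit, X[test, , drop = FALSE])
        met <- classificationMetrics(y[test], as.integer(sc >= 0.5), sc)
        m <- m + 1L
        out[[m]] <- data.frame(rep = rep, fold = f,
                               accuracy = met$accuracy, mcc = met$mcc,
                               kappa = met$kappa, auc = met$auc)
        if (keepModels) models[[m]] <- fit
      }
    }
    list(metrics = do.call(rbind, out), models = models)
  }

  best <- NULL
  for (algo in algorithms) {
    for (params in .ALGOS[[algo]]$grid) {
      res <- evalConfig(algo, params)
      mmcc <- mean(res$metrics$mcc)
      if (is.null(best) || mmcc > best$mmcc + 1e-12) {
        best <- list(algo = algo, params = params, mmcc = mmcc,
                     metrics = res$metrics)
      }
    }
  }

  # Re-run the winner retaining fold models; export the highest-MCC fold fit.
  res <- evalConfig(best$algo, best$params, keepModels = TRUE)
  exp_idx <- which.max(res$metrics$mcc)
  model <- res$models[[exp_idx]]

  meta <- list(
    hyperparameters = best$params,
    seed = seed,
    exported_fold = list(rep = res$metrics$rep[exp_idx],
                         fold = res$metrics$fold[exp_idx]),
    meets_accuracy_target = mean(res$metrics$accuracy) >= 0.75,
    meets_mcc_target = mean(res$metrics$mcc) >= 0.4,
    similarity_only = FALSE
  )
  new("TrainedTargetModel", targetId = targetId(ds), algorithm = best$algo,
      descriptorNames = kept, model = model,
      calibrator = new("Calibrator"), cvMetrics = res$metrics,
      classWeight = w, meta = meta)
}

#' Raw classifier scores for query descriptor rows
#'
#' Scores a descriptor matrix with a trained bundle's classifier, enforcing
#' the pruned descriptor list fixed at train time.
#'
#' @param model a [TrainedTargetModel-class].
#' @param X descriptor matrix containing at least the model's descriptors.
#' @return numeric vector of raw P(active) scores in [0, 1].
#' @export
predictRawScores <- function(model, X) {
  stopifnot(is(model, "TrainedTargetModel"))
  if (model@algorithm == "similarity-only" || is.null(model@model)) {
    stop("model '", model@targetId, "' is similarity-only: no classifier",
         call. = FALSE)
  }
  miss <- setdiff(model@descriptorNames, colnames(X))
  if (length(miss)) {
    stop("descriptor matrix lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Xp <- X[, model@descriptorNames, drop = FALSE]
  .ALGOS[[model@algorithm]]$score(model@model, Xp)
}

#' Persist and reload a trained model bundle
#'
#' \code{saveTargetModel()} writes a per-target bundle directory: the
#' serialized classifier + calibrator (\code{model.rds}) and a JSON metadata
#' file (algorithm, pruned descriptors, CV metric summary, class weight,
#' calibration method, seeds) for inspection without deserializing.
#' \code{loadTargetModel()} restores the [TrainedTargetModel-class].
#'
#' @param model a [TrainedTargetModel-class].
#' @param dir bundle directory to create/read.
#' @return the directory (save) or a [TrainedTargetModel-class] (load).
#' @export
saveTargetModel <- function(model, dir) {
  stopifnot(is(model, "TrainedTargetModel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  cv <- model@cvMetrics
  jsonlite::write_json(list(
    target_id = model@targetId,
    algorithm = model@algorithm,
    descriptors = model@descriptorNames,
    class_weight = model@classWeight,
    calibration = model@calibrator@method,
    cv_summary = if (nrow(cv)) list(
      accuracy = mean(cv$accuracy), mcc = mean(cv$mcc),
      kappa = mean(cv$kappa), auc = mean(cv$auc, na.rm = TRUE)) else NULL,
    meta = model@meta[c("seed", "meets_accuracy_target", "meets_mcc_target",
                        "similarity_only")]
  ), file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveTargetModel
#' @export
loadTargetModel <- function(dir) {
  model <- readRDS(file.path(dir, "model.rds"))
  stopifnot(is(model, "TrainedTargetModel"))
  model
}

#' A similarity-only model bundle
#'
#' Placeholder bundle for targets whose dataset is too class-starved to train
#' a classifier; the predictor then serves the similarity belief alone and
#' flags the report.
#'
#' @param targetId panel target name.
#' @return a [TrainedTargetModel-class] with \code{algorithm =
#'   "similarity-only"}.
#' @export
similarityOnlyModel <- function(targetId) {
  new("TrainedTargetModel", targetId = targetId,
      algorithm = "similarity-only", descriptorNames = character(0),
      model = NULL, calibrator = new("Calibrator"),
      cvMetrics = data.frame(), classWeight = NA_real_,
      meta = list(similarity_only = TRUE))
}
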
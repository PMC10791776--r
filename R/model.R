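#' Root mean square error
#'
#' \eqn{RMSE = \sqrt{\sum_i (x_i - y_i)^2 / n}} between observed and
#' predicted values.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return RMSE in the response's units (g/m^2 for yield).
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (!length(observed)) stop("empty vectors")
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' \eqn{R^2 = \left[\sum (x-\bar x)(y-\bar y)\right]^2 /
#' \left[\sum (x-\bar x)^2 \sum (y-\bar y)^2\right]}; bounded in [0, 1]
#' by construction.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return R^2, or \code{NA} when either vector has zero variance.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (sd(observed) == 0 || sd(predicted) == 0) return(NA_real_)
  cor(observed, predicted)^2
}

#' Classification accuracy
#'
#' (True positives + true negatives) / total, i.e. the fraction of labels
#' predicted correctly.
#'
#' @param true_labels,predicted_labels Equal-length label vectors; predicted
#'   labels must be drawn from the true label set.
#' @return Accuracy in [0, 1].
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (!length(true_labels)) stop("empty label vectors")
  if (!all(predicted_labels %in% unique(true_labels)))
    stop("predicted labels contain unseen classes")
  mean(as.character(true_labels) == as.character(predicted_labels))
}

#' Cross-validation configuration
#'
#' @param n_trees Trees per forest (default 500).
#' @param folds,repeats Outer CV folds and repeats (default 10 x 3 = 30
#'   held-out evaluations).
#' @param seed RNG seed; recorded in every result.
#' @param mtry_grid Candidate mtry values (default 1..p at fit time).
#' @param tune \code{"oob"} (default): per candidate mtry, fit one forest
#'   on the training fold and pick the mtry minimizing its out-of-bag
#'   error; \code{"inner_cv"}: nested 5-fold CV inside each training fold.
#'   With a single predictor mtry is fixed at 1 and no tuning runs.
#' @param stratify Stratify folds by class (classification only).
#' @return A list of class \code{cv_config}.
#' @export
cv_config <- function(n_trees = 500, folds = 10, repeats = 3, seed = 1,
                      mtry_grid = NULL, tune = c("oob", "inner_cv"),
                      stratify = TRUE) {
  tune <- match.arg(tune)
  stopifnot(folds >= 2, repeats >= 1, n_trees >= 1)
  structure(list(n_trees = n_trees, folds = folds, repeats = repeats,
                 seed = seed, mtry_grid = mtry_grid, tune = tune,
                 stratify = stratify),
            class = "cv_config")
}

# fold assignment: plain or stratified random partition
make_folds <- function(n, k, strata = NULL) {
  if (is.null(strata)) return(sample(rep(seq_len(k), length.out = n)))
  f <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    f[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  f
}

# pick mtry on the training data per cfg$tune
choose_mtry <- function(X, y, cfg, classification) {
  p <- ncol(X)
  grid <- cfg$mtry_grid %||% seq_len(p)
  grid <- grid[grid <= p]
  if (p == 1 || length(grid) == 1) return(grid[1])
  score <- vapply(grid, function(m) {
    if (cfg$tune == "oob") {
      fit <- randomForest::randomForest(X, y, ntree = cfg$n_trees, mtry = m)
      if (classification) fit$err.rate[cfg$n_trees, "OOB"]
      else fit$mse[cfg$n_trees]
    } else {
      inner <- make_folds(nrow(X), 5, if (classification) y else NULL)
      errs <- vapply(seq_len(5), function(f) {
        tr <- inner != f
        if (classification && length(unique(y[tr])) < 2) return(NA_real_)
        fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                          ntree = cfg$n_trees, mtry = m)
        pr <- predict(fit, X[!tr, , drop = FALSE])
        if (classification) 1 - accuracy(y[!tr], pr)
        else rmse(y[!tr], pr)
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }
  }, numeric(1))
  grid[which.min(score)] # ties: smallest mtry
}

cv_rf_engine <- function(X, y, cfg, classification, feature = NA,
                         date = NA, gdd = NA, strategy = NA) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < cfg$folds) stop("fewer rows (", n, ") than folds (", cfg$folds, ")")
  if (classification) {
    y <- factor(y)
    if (nlevels(y) < 2) stop("classification needs both classes present")
    if (cfg$stratify && min(table(y)) < cfg$folds)
      stop("smallest class (", min(table(y)), ") has fewer members than ",
           "folds (", cfg$folds, "); reduce folds or disable stratification")
  } else if (any(!is.finite(y))) stop("non-finite response values")
  set.seed(cfg$seed)
  per_fold <- vector("list", cfg$folds * cfg$repeats)
  k <- 0
  for (rep_i in seq_len(cfg$repeats)) {
    folds <- make_folds(n, cfg$folds,
                        if (classification && cfg$stratify) y else NULL)
    for (f in seq_len(cfg$folds)) {
      tr <- folds != f
      mtry <- choose_mtry(X[tr, , drop = FALSE], y[tr], cfg, classification)
      fit <- randomForest::randomForest(X[tr, , drop = FALSE], y[tr],
                                        ntree = cfg$n_trees, mtry = mtry)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      k <- k + 1
      per_fold[[k]] <- if (classification) {
        data.frame(repeat_i = rep_i, fold = f, mtry = mtry,
                   accuracy = accuracy(y[!tr], pred))
      } else {
        data.frame(repeat_i = rep_i, fold = f, mtry = mtry,
                   rmse = rmse(y[!tr], as.numeric(pred)),
                   r2 = r_squared(y[!tr], as.numeric(pred)))
      }
    }
  }
  folds_df <- do.call(rbind, per_fold)
  res <- list(task = if (classification) "classification" else "regression",
              feature = feature, date = date, gdd = gdd, strategy = strategy,
              n = n, p = ncol(X), folds = folds_df, cfg = cfg,
              mtry = as.integer(round(mean(folds_df$mtry))))
  if (classification) {
    res$mean_accuracy <- mean(folds_df$accuracy)
  } else {
    res$mean_rmse <- mean(folds_df$rmse)
    res$mean_r2 <- mean(folds_df$r2, na.rm = TRUE)
  }
  structure(res, class = "eval_result")
}

#' Random-forest yield regression under repeated cross-validation
#'
#' Repeated k-fold CV (fresh random partition per repeat) of a
#' 500-tree random forest. With more than one predictor column, mtry is
#' tuned within each training fold (see \code{\link{cv_config}}); with one
#' column mtry = 1. RMSE and R^2 are computed on each held-out fold and
#' averaged over all folds x repeats. Fully reproducible from
#' \code{cfg$seed}.
#'
#' @param X A \code{design_matrix} or numeric matrix (rows = plots).
#' @param y Yield vector aligned with \code{X}'s rows; when \code{X} is a
#'   \code{design_matrix} and \code{y} has names or is a data frame with
#'   plot ids, alignment is by plot id.
#' @param cfg A \code{\link{cv_config}}.
#' @return An \code{eval_result} with \code{mean_rmse}, \code{mean_r2} and
#'   per-fold detail in \code{$folds}.
#' @export
cv_rf_regression <- function(X, y, cfg = cv_config()) {
  a <- align_response(X, y)
  cv_rf_engine(a$X, a$y, cfg, classification = FALSE, feature = a$feature,
               date = a$date, gdd = a$gdd, strategy = a$strategy)
}

#' Random-forest yield-group classification under repeated CV
#'
#' Stratified repeated k-fold CV of a 500-tree random-forest classifier on
#' L/H yield-group labels; mean accuracy over all folds x repeats.
#'
#' @param X A \code{design_matrix} or numeric matrix.
#' @param labels Class labels (\code{"L"}/\code{"H"}) aligned like \code{y}
#'   in \code{\link{cv_rf_regression}}.
#' @param cfg A \code{\link{cv_config}}.
#' @return An \code{eval_result} with \code{mean_accuracy}.
#' @export
cv_rf_classification <- function(X, labels, cfg = cv_config()) {
  a <- align_response(X, labels)
  cv_rf_engine(a$X, a$y, cfg, classification = TRUE, feature = a$feature,
               date = a$date, gdd = a$gdd, strategy = a$strategy)
}

# align a response with a design matrix's rows (by plot id when possible)
align_response <- function(X, y) {
  if (inherits(X, "design_matrix")) {
    meta <- X
    if (!is.null(names(y))) {
      miss <- setdiff(meta$plot_id, names(y))
      if (length(miss)) stop("response missing for plot(s): ",
                             paste(miss, collapse = ", "))
      y <- y[meta$plot_id]
    } else if (length(y) != nrow(meta$X)) {
      stop("response length does not match design matrix rows")
    }
    list(X = meta$X, y = unname(y), feature = meta$feature,
         date = meta$date, gdd = meta$gdd, strategy = meta$strategy)
  } else {
    if (length(y) != nrow(X)) stop("response length does not match X rows")
    list(X = X, y = y, feature = NA, date = NA, gdd = NA, strategy = NA)
  }
}

#' @export
print.eval_result <- function(x, ...) {
  hdr <- sprintf("<eval_result> %s %s @ %s (%s): n=%d p=%d",
                 x$task, x$feature, format(x$date), x$strategy, x$n, x$p)
  cat(hdr, "\n")
  if (x$task == "regression")
    cat(sprintf("  mean RMSE %.2f g/m2, mean R2 %.3f over %d folds (mtry %d)\n",
                x$mean_rmse, x$mean_r2, nrow(x$folds), x$mtry))
  else
    cat(sprintf("  mean accuracy %.3f over %d folds (mtry %d)\n",
                x$mean_accuracy, nrow(x$folds), x$mtry))
  invisible(x)
}

#' Pearson correlation matrix of features and yield at one date
#'
#' Pairwise Pearson correlations among all features present at the date
#' plus yield, across plots (pairwise-complete observations). Zero-variance
#' columns give NA entries.
#'
#' @param table A \code{feature_table}.
#' @param date Flight date.
#' @param yields Named numeric vector of plot yields (names = plot ids).
#' @return Symmetric correlation matrix (features + \code{"yield"}).
#' @export
correlation_matrix <- function(table, date, yields) {
  date <- as.Date(date)
  sub <- table[table$date == date, ]
  if (!nrow(sub)) stop("date ", format(date), " not in table")
  feats <- unique(sub$feature)
  ids <- sort(unique(sub$plot_id))
  if (length(ids) < 3) stop("need at least 3 plots")
  wide <- sapply(feats, function(f)
    sub$value[match(paste(ids, f), paste(sub$plot_id, sub$feature))])
  wide <- cbind(wide, yield = unname(yields[ids]))
  suppressWarnings(cor(wide, use = "pairwise.complete.obs"))
}

#' Welch t-test between the high and low yield groups
#'
#' Two-sided Welch (unequal-variance) two-sample t-test. The degenerate
#' all-equal case (both groups constant at the same value) returns t = 0,
#' p = 1 instead of erroring.
#'
#' @param values_h,values_l Numeric vectors (each length >= 2) of the
#'   feature in the high and low group.
#' @return List with \code{t} and \code{p}.
#' @export
group_ttest <- function(values_h, values_l) {
  if (length(values_h) < 2 || length(values_l) < 2)
    stop("each group needs at least 2 values")
  if (sd(values_h) == 0 && sd(values_l) == 0) {
    if (mean(values_h) == mean(values_l)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(values_h) - mean(values_l)) * Inf, p = 0))
  }
  tt <- stats::t.test(values_h, values_l, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
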
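# Association tests for split selection. Both reduce to a standardized
# linear statistic with a large-sample reference distribution:
#  - continuous x: z = cor(x, y) * sqrt(n - 1), two-sided normal p-value;
#  - categorical x: (n - 1) * R^2 from the one-way mean contrast,
#    chi-squared with (levels - 1) df.
# Rows where x is missing are dropped for that predictor's test.
.assoc_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(y) == 0) return(1)
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    if (nlevels(droplevels(x)) < 2) return(1)
    x <- droplevels(x)
    gm <- tapply(y, x, mean)
    ssb <- sum(tapply(y, x, length) * (gm - mean(y))^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(1)
    stat <- (n - 1) * ssb / sst
    stats::pchisq(stat, df = nlevels(x) - 1, lower.tail = FALSE)
  } else {
    if (stats::sd(x) == 0) return(1)
    z <- stats::cor(x, y) * sqrt(n - 1)
    2 * stats::pnorm(-abs(z))
  }
}

# Best binary split of a node on one predictor, by residual-sum-of-squares
# reduction. Returns NULL when no admissible split exists.
#  - continuous: exhaustive search over midpoints between sorted unique values;
#  - categorical with <= max_subset_levels levels: all level subsets;
#  - categorical beyond that: levels ordered by mean response, ordinal search.
.best_split <- function(x, y, minbucket, max_subset_levels = 8L) {
  ok <- !is.na(x)
  if (sum(ok) < 2 * minbucket) return(NULL)
  rss <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  base <- rss(y[ok])
  best <- NULL
  consider <- function(left_mask, where) {
    nl <- sum(left_mask & ok); nr <- sum(!left_mask & ok)
    if (nl < minbucket || nr < minbucket) return()
    gain <- base - rss(y[ok & left_mask]) - rss(y[ok & !left_mask])
    if (is.null(best) || gain > best$gain + 1e-12)
      best <<- list(gain = gain, where = where)
  }
  if (is.factor(x) || is.character(x)) {
    x <- factor(x)
    lev <- levels(droplevels(x[ok]))
    if (length(lev) < 2) return(NULL)
    if (length(lev) <= max_subset_levels) {
      for (code in 1:(2^(length(lev) - 1) - 1)) {
        subset <- lev[bitwAnd(code, 2^(seq_along(lev) - 1)) > 0]
        consider(!is.na(x) & x %in% subset, subset)
      }
    } else {
      mns <- sort(tapply(y[ok], droplevels(x[ok]), mean))
      for (k in seq_len(length(mns) - 1)) {
        subset <- names(mns)[1:k]
        consider(!is.na(x) & x %in% subset, subset)
      }
    }
    if (is.null(best)) return(NULL)
    list(kind = "categorical", subset = best$where, gain = best$gain)
  } else {
    xs <- sort(unique(x[ok]))
    if (length(xs) < 2) return(NULL)
    cuts <- (xs[-1] + xs[-length(xs)]) / 2
    for (cut in cuts) consider(!is.na(x) & x <= cut, cut)
    if (is.null(best)) return(NULL)
    list(kind = "continuous", cut = best$where, gain = best$gain)
  }
}

#' Conditional-inference-style regression tree
#'
#' Recursive partitioning in which each split is preceded by a formal
#' association test: every predictor's association with the response is
#' scored (correlation-type statistic for continuous predictors, one-way
#' mean contrast for categorical ones, both with large-sample p-values) and
#' Bonferroni-corrected across predictors. The node splits on the most
#' significant predictor — at its best RSS-reducing cutpoint or level
#' subset — only if the corrected p-value passes `alpha`; otherwise the node
#' becomes a leaf. This unbiased-selection scheme avoids favouring
#' predictors with many split points when categorical and continuous
#' predictors are mixed. Ties in the selection statistic go to the
#' lowest-index predictor column.
#'
#' @param data data.frame holding response and predictors.
#' @param response Name of the numeric response column.
#' @param predictors Character vector of predictor column names (default:
#'   all other columns except `border`).
#' @param alpha Significance threshold for the Bonferroni-corrected test
#'   (default 0.05).
#' @param min_node Minimum rows for a node to be considered for splitting
#'   (default 20).
#' @param minbucket Minimum rows in a child (default `max(7, min_node %/% 3)`).
#' @return An object of class `"citree"`; see [predict.citree()].
#' @export
fit_citree <- function(data, response = "response", predictors = NULL,
                       alpha = 0.05, min_node = 20, minbucket = NULL) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), c(response, "border"))
  if (!length(predictors)) stop("no predictors")
  if (is.null(minbucket)) minbucket <- max(7L, min_node %/% 3L)
  y <- data[[response]]
  if (anyNA(y)) stop("response has missing values")
  if (nrow(data) < min_node || stats::sd(y) == 0) {
    # degenerate: root-only tree
    return(structure(list(node = list(leaf = TRUE, value = mean(y), n = length(y)),
                          predictors = predictors, response = response),
                     class = "citree"))
  }
  grow <- function(rows, depth) {
    yy <- y[rows]
    leaf <- list(leaf = TRUE, value = mean(yy), n = length(rows))
    if (length(rows) < min_node || stats::sd(yy) == 0) return(leaf)
    p <- vapply(predictors, function(v) .assoc_p(data[[v]][rows], yy), 0)
    p_adj <- pmin(1, p * length(predictors))
    j <- which.min(p)               # ties -> lowest column index (which.min)
    if (p_adj[j] > alpha) return(leaf)
    sp <- .best_split(data[[predictors[j]]][rows], yy, minbucket)
    if (is.null(sp)) return(leaf)
    xv <- data[[predictors[j]]][rows]
    left_mask <- if (sp$kind == "continuous") !is.na(xv) & xv <= sp$cut
                 else !is.na(xv) & xv %in% sp$subset
    # missing values follow the larger child
    na_mask <- is.na(xv)
    if (any(na_mask)) {
      if (sum(left_mask) >= sum(!left_mask & !na_mask)) left_mask[na_mask] <- TRUE
    }
    list(leaf = FALSE, predictor = predictors[j], split = sp,
         p_value = p_adj[j], n = length(rows),
         left = grow(rows[left_mask], depth + 1),
         right = grow(rows[!left_mask], depth + 1))
  }
  structure(list(node = grow(seq_len(nrow(data)), 1),
                 predictors = predictors, response = response),
            class = "citree")
}

#' @export
print.citree <- function(x, ...) {
  depth <- function(nd) if (nd$leaf) 0 else 1 + max(depth(nd$left), depth(nd$right))
  nleaves <- function(nd) if (nd$leaf) 1 else nleaves(nd$left) + nleaves(nd$right)
  cat(sprintf("conditional-inference regression tree: %d leaves, depth %d, n = %d\n",
              nleaves(x$node), depth(x$node), x$node$n))
  invisible(x)
}

#' Number of terminal nodes of a citree
#' @param tree A `"citree"`.
#' @return Integer leaf count (1 for a root-only tree).
#' @export
n_leaves <- function(tree) {
  cnt <- function(nd) if (nd$leaf) 1L else cnt(nd$left) + cnt(nd$right)
  cnt(tree$node)
}

#' Predict from a conditional-inference tree
#'
#' @param object A `"citree"`.
#' @param newdata data.frame with the predictor columns.
#' @param ... Unused.
#' @return Numeric predictions (leaf means).
#' @export
predict.citree <- function(object, newdata, ...) {
  out <- numeric(nrow(newdata))
  route <- function(nd, rows) {
    if (!length(rows)) return()
    if (nd$leaf) { out[rows] <<- nd$value; return() }
    xv <- newdata[[nd$predictor]][rows]
    left <- if (nd$split$kind == "continuous") !is.na(xv) & xv <= nd$split$cut
            else !is.na(xv) & xv %in% nd$split$subset
    # send missing values to the larger training child
    na <- is.na(xv)
    if (any(na)) left[na] <- nd$left$n >= nd$right$n
    route(nd$left, rows[left])
    route(nd$right, rows[!left])
  }
  route(object$node, seq_len(nrow(newdata)))
  out
}

#' Ensemble permutation variable importance
#'
#' Fits `n_iter` conditional-inference trees, each on a random subsample of
#' the rows, and scores every predictor by out-of-bag permutation
#' importance: the increase in mean squared prediction error on the held-out
#' rows when that predictor's held-out column is randomly permuted — the
#' marginal loss of prediction accuracy attributable to the predictor.
#' Overall importance is the mean over iterations.
#'
#' @param data data.frame holding response and predictors.
#' @param response Name of the numeric response column.
#' @param predictors Predictor column names (default: all others except
#'   `border`).
#' @param n_iter Number of tree iterations (default 500).
#' @param subsample Fraction of rows used to fit each tree (without
#'   replacement; default 0.632).
#' @param alpha,min_node Passed to [fit_citree()].
#' @param seed Master seed; each iteration draws from its own substream.
#' @return An object of class `"importance_result"`: `$importance` (named
#'   mean scores, response units squared), `$per_iteration` (n_iter x
#'   predictors matrix), `$ranking`.
#' @export
ensemble_importance <- function(data, response = "response", predictors = NULL,
                                n_iter = 500, subsample = 0.632,
                                alpha = 0.05, min_node = 20, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(predictors))
    predictors <- setdiff(names(data), c(response, "border"))
  if (length(predictors) < 2) stop("need at least 2 predictors")
  n <- nrow(data)
  states <- .substream_states(seed, n_iter)
  scores <- matrix(NA_real_, n_iter, length(predictors),
                   dimnames = list(NULL, predictors))
  for (it in seq_len(n_iter)) {
    .with_rng_state(states[[it]], {
      idx <- sample.int(n, max(2, floor(subsample * n)))
      oob <- setdiff(seq_len(n), idx)
      tree <- fit_citree(data[idx, , drop = FALSE], response, predictors,
                         alpha = alpha, min_node = min_node)
      if (length(oob) < 2) {
        scores[it, ] <- 0
      } else {
        hold <- data[oob, , drop = FALSE]
        base_mse <- mean((hold[[response]] - predict(tree, hold))^2)
        for (jp in seq_along(predictors)) {
          perm <- hold
          perm[[predictors[jp]]] <- perm[[predictors[jp]]][sample.int(nrow(perm))]
          scores[it, jp] <- mean((perm[[response]] - predict(tree, perm))^2) - base_mse
        }
      }
    })
  }
  imp <- colMeans(scores)
  structure(list(importance = imp,
                 per_iteration = scores,
                 ranking = names(sort(imp, decreasing = TRUE)),
                 n_iter = n_iter, response = response),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("permutation importance over %d tree iterations (mean decrease in accuracy, response units^2):\n",
              x$n_iter))
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Plot variable importance scores
#'
#' Horizontal bar chart of mean permutation importance, largest on top.
#'
#' @param x An `"importance_result"`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.importance_result <- function(x, ...) {
  v <- sort(x$importance)
  graphics::par(mar = c(4, 10, 2, 1))
  graphics::barplot(v, horiz = TRUE, las = 1,
                    xlab = "mean decrease in prediction accuracy", ...)
  invisible(x)
}

#' Write importance scores to CSV
#' @param result An `"importance_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(result, path) {
  utils::write.csv(data.frame(predictor = names(result$importance),
                              importance = unname(result$importance)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
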
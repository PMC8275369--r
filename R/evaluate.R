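#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties counting one half.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration: walking down the unique score
#' thresholds, each recall increment is weighted by the precision at that
#' threshold (average precision).
#'
#' @inheritParams auroc
#' @return auPRC in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("at least one positive required")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  # evaluate only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Cross-validation fold schemes
#'
#' `"kfold"` partitions windows at random into `k` folds (seeded);
#' `"chromosome"` and `"cell_type"` are grouped schemes where each fold
#' holds out one whole chromosome or cell type, so no group ever spans
#' training and validation.
#'
#' @param kind `"kfold"`, `"chromosome"` or `"cell_type"`.
#' @param k number of folds for `"kfold"` (default 5).
#' @param seed seed for the random k-fold partition.
#' @return list of class `"fold_scheme"`.
#' @export
fold_scheme <- function(kind = c("kfold", "chromosome", "cell_type"),
                        k = 5L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_scheme")
}

# list of validation-index vectors, one per fold
make_folds <- function(dataset, scheme) {
  n <- length(dataset$label)
  if (scheme$kind == "kfold") {
    perm <- withr::with_seed(scheme$seed, sample(n))
    return(unname(split(perm, rep_len(seq_len(scheme$k), n))))
  }
  key <- if (scheme$kind == "chromosome") dataset$chrom else dataset$cell_type
  groups <- unique(key)
  if (length(groups) < 2L) stop("grouped schemes need at least 2 groups")
  lapply(groups, function(g) which(key == g))
}

#' Grouped cross-validation of the classifier
#'
#' Trains one model per fold on the fold's training partition only and
#' reports per-fold auROC, auPRC and validation loss plus their mean and
#' standard deviation.
#'
#' @param dataset a `labeled_dataset`.
#' @param scheme a [fold_scheme()].
#' @param train_cfg a [train_config()] used for every fold.
#' @param model_cfg a [model_config()]; a fresh model is initialised per
#'   fold from `train_cfg$seed`.
#' @return list of class `"metric_report"`: `folds` data.frame and
#'   `summary` (mean/sd per metric).
#' @export
crossval <- function(dataset, scheme = fold_scheme(),
                     train_cfg = train_config(), model_cfg = model_config()) {
  folds <- make_folds(dataset, scheme)
  rows <- list()
  for (f in seq_along(folds)) {
    val <- folds[[f]]
    tr <- setdiff(seq_along(dataset$label), val)
    if (length(unique(dataset$label[val])) < 2L)
      stop("fold ", f, " contains a single class; cannot compute metrics")
    model <- build_model(model_cfg, dataset$panel, seed = train_cfg$seed)
    model <- train_model(model, subset_dataset(dataset, tr), train_cfg)
    sc <- predict(model, subset_dataset(dataset, val))
    yv <- dataset$label[val]
    eps <- 1e-12
    loss <- -mean(yv * log(pmax(sc, eps)) + (1 - yv) * log(pmax(1 - sc, eps)))
    rows[[f]] <- data.frame(fold = f, n_val = length(val),
                            auroc = auroc(yv, sc), auprc = auprc(yv, sc),
                            loss = loss)
  }
  folds_df <- do.call(rbind, rows)
  summ <- data.frame(metric = c("auroc", "auprc", "loss"),
                     mean = c(mean(folds_df$auroc), mean(folds_df$auprc),
                              mean(folds_df$loss)),
                     sd = c(sd(folds_df$auroc), sd(folds_df$auprc),
                            sd(folds_df$loss)))
  structure(list(folds = folds_df, summary = summ, scheme = scheme),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", x$scheme$kind, "CV,", nrow(x$folds), "folds\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Boundary recovery against ground-truth cores
#'
#' For each truth interval, the Jaccard index between the truth interval
#' and the union of refined intervals overlapping it, together with
#' per-enhancer precision (`|intersection| / |refined bases|`) and recall
#' (`|intersection| / |truth bases|`).  Truth intervals with no overlapping
#' refined interval score 0.
#'
#' @param refined refined annotation intervals.
#' @param truth ground-truth enhancer core intervals.
#' @return list with `per_enhancer` data.frame and `medians`.
#' @export
boundary_recovery <- function(refined, truth) {
  n <- nrow(truth)
  jac <- prec <- rec <- numeric(n)
  for (i in seq_len(n)) {
    ti <- truth[i, , drop = FALSE]
    ov <- refined[overlaps_any(refined, ti), , drop = FALSE]
    if (nrow(ov) == 0L) next
    inter <- sum(pmin(ov$end, ti$end) - pmax(ov$start, ti$start))
    ru <- sum(ov$end - ov$start)
    uni <- ru + (ti$end - ti$start) - inter
    jac[i] <- inter / uni
    prec[i] <- inter / ru
    rec[i] <- inter / (ti$end - ti$start)
  }
  per <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
                    jaccard = jac, precision = prec, recall = rec)
  list(per_enhancer = per,
       medians = c(jaccard = median(jac), precision = median(prec),
                   recall = median(rec)))
}

#' Coverage ratio of refined to original annotation
#'
#' @param refined,original interval data.frames.
#' @return total refined bases / total original bases.
#' @export
coverage_ratio <- function(refined, original) {
  co <- total_coverage(original)
  if (co == 0) stop("original annotation is empty")
  total_coverage(refined) / co
}
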
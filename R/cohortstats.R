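#' Classify subjects by the sign of an index
#'
#' A subject is predicted "cancer" when the chosen index exceeds the
#' threshold (default 0: positive NAI/CI values are associated with
#' cancer samples, negative values with healthy controls). Ties at the
#' threshold are predicted "control", which avoids inflating
#' sensitivity.
#'
#' @param records data.frame of subject records with columns
#'   \code{nai_mean}, \code{ci_mean} and/or \code{pc1}.
#' @param index which index to use: \code{"nai"}, \code{"ci"} or
#'   \code{"pc1"}.
#' @param threshold decision threshold (default 0).
#' @return Character vector of predicted labels ("cancer"/"control").
#' @export
classifyBySign <- function(records, index = c("nai", "ci", "pc1"),
                           threshold = 0) {
  index <- match.arg(index)
  col <- switch(index, nai = "nai_mean", ci = "ci_mean", pc1 = "pc1")
  v <- records[[col]]
  if (is.null(v) || anyNA(v))
    stop("index '", index, "' missing from the subject records")
  ifelse(v > threshold, "cancer", "control")
}

#' Confusion metrics of a two-class prediction
#'
#' Sensitivity = TP/(TP + FN), specificity = TN/(TN + FP), and accuracy
#' = (TP + TN)/(TP + TN + FP + FN), the proportion of true positives
#' and true negatives among all cases examined.
#'
#' @param trueLabels,predictedLabels equal-length label vectors drawn
#'   from exactly two classes.
#' @param positive the positive-class label (default "cancer").
#' @return A list with \code{sensitivity}, \code{specificity},
#'   \code{accuracy} and the counts \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}.
#' @examples
#' truth <- rep(c("cancer", "control"), each = 36)
#' pred  <- c(rep("cancer", 27), rep("control", 9),
#'            rep("control", 35), "cancer")
#' confusionMetrics(truth, pred)   # 0.75 / 0.9722 / 0.8611
#' @export
confusionMetrics <- function(trueLabels, predictedLabels,
                             positive = "cancer") {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  classes <- unique(c(trueLabels, predictedLabels))
  if (length(unique(trueLabels)) != 2L || length(classes) > 2L)
    stop("exactly two classes are required, got: ",
         paste(classes, collapse = ", "))
  if (!positive %in% trueLabels)
    stop("positive class '", positive, "' absent from the true labels")
  isPos <- trueLabels == positive
  predPos <- predictedLabels == positive
  TP <- sum(isPos & predPos);  FN <- sum(isPos & !predPos)
  TN <- sum(!isPos & !predPos); FP <- sum(!isPos & predPos)
  list(sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       accuracy = (TP + TN) / (TP + TN + FP + FN),
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over all distinct scores (a subject is
#' predicted positive when its score strictly exceeds the threshold),
#' yielding one (FPR, TPR) point per threshold plus the trivial
#' endpoints. The AUC is computed by the trapezoid rule and equals the
#' Mann-Whitney probability estimate P(score_pos > score_neg) +
#' 0.5 P(tie) on the same data.
#'
#' @param scores numeric score per subject (higher = more positive).
#' @param trueLabels true class labels.
#' @param positive the positive-class label (default "cancer").
#' @return A list with \code{curve} (data.frame threshold/fpr/tpr,
#'   ordered from (1,1) to (0,0)) and \code{auc}.
#' @examples
#' rocCurve(c(3, 2, 1, 0), c("cancer", "cancer", "control", "control"))
#' @export
rocCurve <- function(scores, trueLabels, positive = "cancer") {
  trueLabels <- as.character(trueLabels)
  isPos <- trueLabels == positive
  nP <- sum(isPos); nN <- sum(!isPos)
  if (nP == 0L || nN == 0L)
    stop("need at least one subject in each class")
  if (length(scores) != length(trueLabels))
    stop("'scores' and 'trueLabels' must have equal length")
  th <- c(-Inf, sort(unique(scores)))
  tpr <- vapply(th, function(t) sum(isPos & scores > t) / nP, numeric(1))
  fpr <- vapply(th, function(t) sum(!isPos & scores > t) / nN, numeric(1))
  curve <- data.frame(threshold = th, fpr = fpr, tpr = tpr)
  # trapezoid over decreasing fpr
  auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
             (tpr[-length(tpr)] + tpr[-1L]) / 2)
  list(curve = curve, auc = auc)
}

#' Two-variable PCA of (CI, NAI)
#'
#' Eigendecomposition of the 2 x 2 covariance matrix of the subject
#' indices, on the raw (unstandardized) scale by default since both
#' indices live on the same natural [-1, 1] range; set
#' \code{scale = TRUE} for the correlation-matrix variant. Reported
#' quantities: the variance fraction of PC1, lambda1/(lambda1 +
#' lambda2); the loading fraction of the NAI on PC1,
#' |v1_nai| / (|v1_ci| + |v1_nai|) (the absolute-loading share); and
#' per-subject component scores. The sign of PC1 is fixed so that the
#' mean score of the positive group is positive (when group labels are
#' supplied).
#'
#' @param ci,nai numeric index vectors (>= 3 subjects), or pass a
#'   two-column data.frame/matrix (ci, nai) as the first argument.
#' @param groups optional label vector used to orient PC1.
#' @param positive the positive-class label (default "cancer").
#' @param scale use the correlation matrix instead of the covariance.
#' @return A list with \code{loadings} (2 x 2, columns PC1/PC2, rows
#'   ci/nai), \code{eigenvalues}, \code{varianceFraction} (length 2,
#'   sums to 1), \code{loadingFractionNai}, \code{scores} (n x 2),
#'   \code{center}.
#' @export
pcaTwoVars <- function(ci, nai = NULL, groups = NULL, positive = "cancer",
                       scale = FALSE) {
  if (is.matrix(ci) || is.data.frame(ci)) {
    m <- as.matrix(ci)
    if (ncol(m) != 2L) stop("expected two columns (ci, nai)")
  } else {
    m <- cbind(ci = ci, nai = nai)
  }
  if (nrow(m) < 3L) stop("need at least 3 subjects for the PCA")
  colnames(m) <- c("ci", "nai")
  C <- cov(m)
  if (scale) {
    s <- sqrt(diag(C))
    if (any(s == 0)) stop("zero-variance variable; cannot use scale = TRUE")
    C <- C / outer(s, s)
    m <- sweep(m, 2L, colMeans(m)) |> sweep(2L, s, "/")
    center <- c(0, 0)
  } else {
    center <- colMeans(m)
    m <- sweep(m, 2L, center)
  }
  if (all(abs(C) < .Machine$double.eps))
    stop("degenerate (zero) covariance matrix")
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  scores <- m %*% V
  if (!is.null(groups)) {
    for (j in 1:2) {
      mu <- mean(scores[groups == positive, j])
      if (is.finite(mu) && mu < 0) {
        V[, j] <- -V[, j]; scores[, j] <- -scores[, j]
      }
    }
  }
  dimnames(V) <- list(c("ci", "nai"), c("PC1", "PC2"))
  colnames(scores) <- c("PC1", "PC2")
  list(loadings = V,
       eigenvalues = e$values,
       varianceFraction = e$values / sum(e$values),
       loadingFractionNai = abs(V["nai", "PC1"]) /
         (abs(V["ci", "PC1"]) + abs(V["nai", "PC1"])),
       scores = scores,
       center = center)
}

#' Full cohort discrimination report
#'
#' Runs the discrimination analysis on a subject table: sign
#' classification of the NAI at threshold 0, confusion metrics, ROC/AUC
#' for the CI, the NAI and PC1 of the two-index PCA, plus the PCA
#' variance and loading fractions. Subjects with a missing CI are
#' excluded from the PCA and CI-based metrics only.
#'
#' @param records subject table (one row per subject) with columns
#'   \code{group}, \code{nai_mean} and optionally \code{ci_mean}.
#' @param positive the positive-class label (default "cancer").
#' @param threshold sign-classification threshold (default 0).
#' @return A list: \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, \code{auc_nai}, \code{auc_ci}, \code{auc_pc1},
#'   \code{pc1_variance_fraction}, \code{pc1_loading_fraction_nai},
#'   \code{predictions} (per-subject predicted labels),
#'   \code{roc} (the three ROC curves), \code{pca}.
#' @export
discriminate <- function(records, positive = "cancer", threshold = 0) {
  if (!all(c("group", "nai_mean") %in% names(records)))
    stop("subject records need 'group' and 'nai_mean' columns")
  pred <- classifyBySign(records, "nai", threshold)
  cm <- confusionMetrics(records$group, pred, positive)
  rocNai <- rocCurve(records$nai_mean, records$group, positive)

  aucCi <- NA_real_; aucPc1 <- NA_real_
  rocCi <- NULL; rocPc1 <- NULL; pca <- NULL
  pc1Var <- NA_real_; pc1Load <- NA_real_
  hasCi <- !is.null(records$ci_mean) && !anyNA(records$ci_mean)
  if (hasCi) {
    rocCi <- rocCurve(records$ci_mean, records$group, positive)
    aucCi <- rocCi$auc
    pca <- pcaTwoVars(records$ci_mean, records$nai_mean,
                      groups = records$group, positive = positive)
    records$pc1 <- pca$scores[, "PC1"]
    rocPc1 <- rocCurve(records$pc1, records$group, positive)
    aucPc1 <- rocPc1$auc
    pc1Var <- pca$varianceFraction[1L]
    pc1Load <- pca$loadingFractionNai
  }

  predictions <- data.frame(
    subject_id = if (!is.null(records$subject_id)) records$subject_id
                 else seq_len(nrow(records)),
    group = records$group, predicted = pred,
    nai_mean = records$nai_mean,
    stringsAsFactors = FALSE
  )
  if (hasCi) {
    predictions$ci_mean <- records$ci_mean
    predictions$pc1 <- records$pc1
  }

  list(sensitivity = cm$sensitivity, specificity = cm$specificity,
       accuracy = cm$accuracy,
       auc_nai = rocNai$auc, auc_ci = aucCi, auc_pc1 = aucPc1,
       pc1_variance_fraction = pc1Var,
       pc1_loading_fraction_nai = pc1Load,
       predictions = predictions,
       roc = list(nai = rocNai, ci = rocCi, pc1 = rocPc1),
       pca = pca)
}
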
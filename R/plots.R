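# QC / report figures (base graphics, optional outputs of the pipeline).

#' Plot the ROC curves of a discrimination report
#'
#' Overlays the CI, NAI and PC1 ROC curves.
#'
#' @param report result of \code{\link{discriminate}}.
#' @export
plotRocCurves <- function(report) {
  plot(c(0, 1), c(0, 1), type = "n", xlab = "false positive rate",
       ylab = "true positive rate", main = "ROC")
  abline(0, 1, lty = 3, col = "grey")
  cols <- c(nai = "firebrick", ci = "steelblue", pc1 = "darkgreen")
  lab <- character(0)
  for (nm in names(cols)) {
    r <- report$roc[[nm]]
    if (is.null(r)) next
    lines(r$curve$fpr, r$curve$tpr, type = "s", col = cols[[nm]], lwd = 2)
    lab <- c(lab, sprintf("%s (AUC %.3f)", toupper(nm), r$auc))
  }
  legend("bottomright", lab, col = cols[seq_along(lab)], lwd = 2,
         bty = "n")
}

#' Plot per-group index distributions
#'
#' Histograms of the subject NAI (and CI when present) split by group,
#' mirroring the index-distribution panels of a cohort report.
#'
#' @param subjects subject table with \code{group}, \code{nai_mean} and
#'   optionally \code{ci_mean}.
#' @export
plotIndexDistributions <- function(subjects) {
  hasCi <- !is.null(subjects$ci_mean) && !anyNA(subjects$ci_mean)
  idx <- if (hasCi) c("nai_mean", "ci_mean") else "nai_mean"
  groups <- unique(subjects$group)
  op <- par(mfrow = c(length(idx), length(groups)))
  on.exit(par(op))
  for (v in idx) for (g in groups) {
    hist(subjects[[v]][subjects$group == g], breaks = seq(-1, 1, 0.1),
         xlab = sub("_mean", "", v), main = g, col = "grey80")
    abline(v = 0, lty = 2)
  }
}
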
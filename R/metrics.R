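#' ROC curve and AUC with DeLong variance
#'
#' Scores are probabilities of AD; AD is the positive class. The AUC is
#' the Mann-Whitney concordance probability (ties counted 1/2) and the
#' variance is DeLong's placement-value estimate, both computed via pROC.
#'
#' @param scores numeric prediction scores.
#' @param labels labels: 0/1 numeric (1 = AD) or "AD"/"CN".
#' @return A [ROCResult-class].
#' @export
rocAuc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.numeric(as.character(labels) == "AD")
  labels <- as.integer(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(labels)) != 2)
    stop("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  new("ROCResult", thresholds = r$thresholds,
      sensitivities = r$sensitivities, specificities = r$specificities,
      auc = as.numeric(r$auc),
      # a single-member class leaves the placement variance undefined
      aucVariance = suppressWarnings(as.numeric(pROC::var(r))),
      scores = as.numeric(scores), labels = labels)
}

#' Operating point maximising Youden's index
#'
#' Sweeps every cut-point (predict AD when score >= threshold), selects
#' the threshold maximising J = sensitivity + specificity - 1 (ties broken
#' by the lowest threshold) and reports accuracy as (TP + TN) / n at that
#' threshold.
#'
#' @param roc a [ROCResult-class].
#' @return An [OperatingPoint-class].
#' @export
youdenPoint <- function(roc) {
  scores <- roc@scores
  labels <- roc@labels
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  cand <- sort(unique(scores))
  best <- NULL
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1) / nPos
    spec <- sum(!pred & labels == 0) / nNeg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(th = th, sens = sens, spec = spec, j = j,
                   acc = (sum(pred & labels == 1) +
                            sum(!pred & labels == 0)) / length(labels))
    }
  }
  new("OperatingPoint", threshold = best$th, sensitivity = best$sens,
      specificity = best$spec, accuracy = best$acc, youdenJ = best$j)
}

#' DeLong comparison of two AUCs
#'
#' z = (AUC1 - AUC2) / sqrt(V1 + V2 - 2 Cov) for paired designs (same
#' subjects under both scores) or sqrt(V1 + V2) for independent samples,
#' with DeLong variance/covariance estimates; two-sided normal p-value.
#'
#' @param roc1,roc2 [ROCResult-class] objects.
#' @param paired TRUE when the same subjects underlie both ROC curves.
#' @return A [TestStatistic-class] (z statistic).
#' @export
delongCompare <- function(roc1, roc2, paired = FALSE) {
  v1 <- roc1@aucVariance
  v2 <- roc2@aucVariance
  if (paired) {
    if (length(roc1@labels) != length(roc2@labels) ||
        !all(roc1@labels == roc2@labels))
      stop("paired DeLong comparison requires the same subjects (labels)")
    r1 <- pROC::roc(response = roc1@labels, predictor = roc1@scores,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
    r2 <- pROC::roc(response = roc2@labels, predictor = roc2@scores,
                    levels = c(0, 1), direction = "<", quiet = TRUE)
    v <- v1 + v2 - 2 * as.numeric(pROC::cov(r1, r2))
  } else {
    v <- v1 + v2
  }
  num <- roc1@auc - roc2@auc
  z <- if (abs(num) < 1e-15) 0 else num / sqrt(max(v, .Machine$double.eps))
  new("TestStatistic", statistic = z, df = NA_real_,
      pValue = 2 * pnorm(-abs(z)), method = "DeLong test")
}

#' Normal-approximation confidence interval for an AUC
#'
#' AUC +/- z * sqrt(DeLong variance), truncated to [0, 1].
#'
#' @param roc a [ROCResult-class].
#' @param level confidence level (default 0.95).
#' @return numeric(2) interval.
#' @export
aucConfidenceInterval <- function(roc, level = 0.95) {
  if (is.na(roc@aucVariance)) return(c(0, 1))  # variance undefined
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(roc@aucVariance)
  c(max(0, roc@auc - half), min(1, roc@auc + half))
}

#' Two-sample Student's t-test from summary statistics
#'
#' Pooled-variance t with df = n1 + n2 - 2 and a two-sided p-value;
#' reproduces printed cohort-table statistics directly from means, SDs and
#' group sizes.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return A [TestStatistic-class].
#' @export
ttestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("at least one SD must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new("TestStatistic", statistic = t, df = df, pValue = 2 * pt(-abs(t), df),
      method = "Two-sample t-test (pooled variance)")
}

#' Paired t-test
#'
#' @param valuesA,valuesB paired numeric vectors (length >= 2).
#' @return A [TestStatistic-class].
#' @export
pairedTtest <- function(valuesA, valuesB) {
  if (length(valuesA) != length(valuesB) || length(valuesA) < 2)
    stop("paired t-test needs two equal-length vectors of length >= 2")
  d <- valuesA - valuesB
  if (sd(d) == 0)
    stop("paired t-test undefined: differences have zero variance")
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  new("TestStatistic", statistic = t, df = n - 1,
      pValue = 2 * pt(-abs(t), n - 1), method = "Paired t-test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return A [TestStatistic-class].
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ct <- stats::chisq.test(table, correct = FALSE)
  new("TestStatistic", statistic = as.numeric(ct$statistic),
      df = as.numeric(ct$parameter), pValue = ct$p.value,
      method = "Pearson chi-square (uncorrected)")
}

#' Mean and sample SD of per-trial metrics
#'
#' The aggregation used in the per-trial results tables: arithmetic mean
#' and (n - 1)-denominator SD.
#'
#' @param values numeric vector (length >= 2).
#' @return named numeric: mean and sd.
#' @export
trialSummary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  c(mean = mean(values), sd = sd(values))
}
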
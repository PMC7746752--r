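# Independent oracles used across tests.

# O(n^2) pair-counting AUC (Mann-Whitney concordance, ties counted 1/2).
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Elementwise binary cross-entropy with explicit clamping, coded
# independently of batchLoss.
bceOracle <- function(p, y, eps = 1e-7) {
  p <- ifelse(p < eps, eps, ifelse(p > 1 - eps, 1 - eps, p))
  s <- 0
  for (i in seq_along(p))
    s <- s - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  s / length(p)
}

# Exhaustive Youden sweep over all cut-points (predict positive at
# score >= threshold), independent of youdenPoint.
youdenOracle <- function(scores, labels) {
  best <- list(j = -Inf)
  for (th in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    j <- sens + spec - 1
    if (j > best$j + 1e-12)
      best <- list(j = j, th = th, sens = sens, spec = spec)
  }
  best
}

# Tiny toy slice dataset of two constant-intensity classes, for training
# sanity checks. Returns the dataset plus train/val subject splits.
toySliceData <- function(n = 10, size = 16L, nSlices = 4L, seed = 11,
                         sdNoise = 0.05, separation = 0.5) {
  set.seed(seed)
  cc <- classifierConfig(featureDim = 16L, inputSize = size,
                         nSlices = nSlices)
  subjects <- data.frame(subject_id = sprintf("T%02d", seq_len(2 * n)),
                         age_years = 75, sex = rep(0:1, n),
                         diagnosis = rep(c("AD", "CN"), each = n),
                         stringsAsFactors = FALSE)
  stacks <- setNames(lapply(seq_len(2 * n), function(i) {
    base <- if (i <= n) 0.5 + separation / 2 else 0.5 - separation / 2
    arr <- base + array(rnorm(size * size * nSlices, 0, sdNoise),
                        c(size, size, nSlices))
    new("SliceStack", slices = array(pmin(1, pmax(0, arr)),
                                     c(size, size, nSlices)),
        sliceIndices = seq_len(nSlices) - 1L,
        subjectRef = subjects$subject_id[i])
  }), subjects$subject_id)
  ds <- sliceDataset(stacks, subjects, cc)
  ids <- subjects$subject_id
  nTrain <- n - max(2, round(n * 0.3))
  list(ds = ds, cconfig = cc, subjects = subjects,
       train = c(ids[1:nTrain], ids[n + 1:nTrain]),
       val = c(ids[(nTrain + 1):n], ids[(n + nTrain + 1):(2 * n)]))
}
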
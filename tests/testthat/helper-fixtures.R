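# Shared fixtures. The desk-scale DnCNN is trained once per test run and
# reused by every test that needs a trained model.

.fixture_env <- new.env(parent = emptyenv())

desk_model <- function() {
  if (is.null(.fixture_env$desk)) {
    .fixture_env$desk <- train_desk_dncnn(seed = 1, steps = 200)
  }
  .fixture_env$desk
}

# inclusive-method quantile oracle: linear interpolation between order
# statistics, independent of stats::quantile
quantile_inclusive_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# exhaustive distance-to-median sort oracle for outlier exclusion, with the
# declared tie-break (larger value first, then later position)
exclude_outliers_oracle <- function(values, fraction = 0.05) {
  n <- length(values)
  k <- floor(fraction * n)
  if (k == 0) return(integer(0))
  d <- abs(values - median(values))
  key <- order(d, values, seq_len(n), decreasing = TRUE)
  sort(key[seq_len(k)])
}

# a small flat channel with one labelled region, for unit tests
flat_channel <- function(values, ncol = NULL) {
  m <- if (is.matrix(values)) values else {
    if (is.null(ncol)) matrix(values, nrow = 1) else matrix(values, ncol = ncol)
  }
  channel_image(m, bit_depth = 8, channel_role = "pgp95_red",
                pixel_size_mm = 0.001)
}

uniform_map <- function(dim, label = 1L, name = "dermis") {
  region_label_map(matrix(label, dim[1], dim[2]),
                   stats::setNames(name, label))
}
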
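# internal helpers: seeding, stratified resampling, argument checks

#' Derive a child seed from a root seed
#'
#' All stochastic stages consume seeds derived from one root seed through a
#' fixed counter scheme, so a pipeline run is reproducible from a single
#' integer and stages can be re-run in isolation. The child stays below
#' 2^31 - 1 (R's integer range).
#'
#' @param seed root seed, a non-negative integer.
#' @param offset stage counter, a small non-negative integer.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  as.integer(((seed %% 20000003) * 101 + offset) %% 2147483647)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards (generators must not disturb user RNG)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stratified holdout: returns logical vector, TRUE = calibration (frac share),
# keeping the class balance of binary labels y in both parts
stratified_split <- function(y, frac) {
  stopifnot(frac > 0, frac < 1)
  y <- as.integer(y)
  idx <- logical(length(y))
  for (cls in unique(y)) {
    which_cls <- which(y == cls)
    n_cal <- max(1L, round(frac * length(which_cls)))
    n_cal <- min(n_cal, length(which_cls) - 1L)  # keep the class on both sides
    if (length(which_cls) == 1L) n_cal <- 1L
    idx[sample(which_cls, n_cal)] <- TRUE
  }
  idx
}

# stratified k-fold assignment (integer fold id per observation)
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    which_cls <- sample(which(y == cls))
    fold[which_cls] <- rep_len(seq_len(k), length(which_cls))
  }
  fold
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
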
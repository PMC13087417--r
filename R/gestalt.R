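#' Labeled facial-embedding set
#'
#' Wraps a matrix of image embedding vectors (one 512-dimensional vector per
#' image for the facial encoder emulated here) with a per-image cohort label
#' and a per-image syndrome label (used for control pools).
#'
#' @param vectors Numeric matrix, images in rows.
#' @param cohort Character vector of cohort labels, one per row.
#' @param syndrome Character vector of syndrome labels, one per row;
#'   defaults to `cohort`.
#' @param image_id Optional image identifiers.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, cohort, syndrome = cohort,
                          image_id = NULL) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 1L) stop("embedding set needs at least one vector")
  if (length(cohort) != n || length(syndrome) != n)
    stop("labels must have one entry per embedding row")
  if (any(!nzchar(cohort)) || any(!nzchar(syndrome)))
    stop("labels must be non-empty")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero-norm embedding vector(s) at row(s) ",
                          paste(utils::head(which(nrm == 0), 3), collapse = ", "))
  if (is.null(image_id)) image_id <- sprintf("img%04d", seq_len(n))
  structure(list(vectors = vectors, cohort = as.character(cohort),
                 syndrome = as.character(syndrome),
                 image_id = as.character(image_id)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d images x %d dims | %d cohorts, %d syndromes\n",
              nrow(x$vectors), ncol(x$vectors),
              length(unique(x$cohort)), length(unique(x$syndrome))))
  invisible(x)
}

#' Subset an embedding set to one cohort's vectors
#'
#' @param set An [embedding_set()].
#' @param cohort Cohort label.
#' @return The matrix of that cohort's vectors.
#' @export
cohort_vectors <- function(set, cohort) {
  m <- set$vectors[set$cohort == cohort, , drop = FALSE]
  if (nrow(m) == 0L) stop("no images labeled with cohort '", cohort, "'")
  m
}

#' Cosine distance between two vectors
#'
#' `1 - (u . v) / (|u| |v|)`; smaller distances mean more similar faces in
#' the embedding space. Bounded in `[0, 2]`, symmetric, invariant to
#' positive rescaling of either argument.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return The cosine distance.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero-norm vector")
  d <- 1 - sum(u * v) / (nu * nv)
  min(max(d, 0), 2)  # clamp floating-point spill
}

# All pairwise cosine distances between rows of A and rows of B.
cross_cosine <- function(A, B) {
  A <- A / sqrt(rowSums(A^2))
  B <- B / sqrt(rowSums(B^2))
  d <- 1 - tcrossprod(A, B)
  pmin(pmax(d, 0), 2)
}

#' Mean pairwise cosine distance
#'
#' Between-group mode (`B` given): mean over all `|A| x |B|` cross pairs.
#' Within-group mode (`B = NULL`): mean over all unordered pairs of rows of
#' `A`, self-pairs excluded; requires at least two rows.
#'
#' @param A Matrix of vectors (rows).
#' @param B Optional second matrix.
#' @return The mean pairwise distance.
#' @export
mean_pairwise <- function(A, B = NULL) {
  A <- rbind(A)
  if (is.null(B)) {
    n <- nrow(A)
    if (n < 2L)
      stop("within-group mean pairwise distance undefined for a singleton")
    d <- cross_cosine(A, A)
    sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  } else {
    B <- rbind(B)
    mean(cross_cosine(A, B))
  }
}

#' Sample same-/different-syndrome control distance distributions
#'
#' Draws, from a control pool spanning many syndromes, pairs of equally
#' sized cohorts stemming (1) from the same syndrome and (2) from two
#' different syndromes, and records the mean intercohort cosine distance of
#' each draw. Within a draw, images are sampled without replacement. These
#' two distributions are the raw material for [derive_threshold()].
#'
#' @param pool An [embedding_set()]; its `syndrome` labels define the arms.
#' @param n_pairs Number of sampled cohort pairs per arm.
#' @param cohort_size Images per sampled cohort.
#' @param seed Integer seed; sampling is fully reproducible.
#' @return A list with numeric vectors `same` and `different`.
#' @export
build_control_distributions <- function(pool, n_pairs, cohort_size, seed) {
  stopifnot(inherits(pool, "embedding_set"), n_pairs >= 1, cohort_size >= 1)
  syn <- split(seq_along(pool$syndrome), pool$syndrome)
  big <- names(syn)[vapply(syn, length, 0L) >= 2L * cohort_size]
  if (length(big) == 0L)
    stop("no syndrome in the pool has >= ", 2L * cohort_size,
         " images for the same-syndrome arm")
  ok <- names(syn)[vapply(syn, length, 0L) >= cohort_size]
  if (length(ok) < 2L)
    stop("fewer than two syndromes with >= ", cohort_size,
         " images for the different-syndrome arm (largest deficient: ",
         names(syn)[which.min(vapply(syn, length, 0L))], ")")
  rng <- local_rng(seed)
  same <- vapply(seq_len(n_pairs), function(i) {
    s <- sample_one(big, rng)
    idx <- rng$sample(syn[[s]], 2L * cohort_size)
    mean_pairwise(pool$vectors[idx[seq_len(cohort_size)], , drop = FALSE],
                  pool$vectors[idx[-seq_len(cohort_size)], , drop = FALSE])
  }, 0)
  different <- vapply(seq_len(n_pairs), function(i) {
    ss <- rng$sample(ok, 2L)
    i1 <- rng$sample(syn[[ss[1L]]], cohort_size)
    i2 <- rng$sample(syn[[ss[2L]]], cohort_size)
    mean_pairwise(pool$vectors[i1, , drop = FALSE],
                  pool$vectors[i2, , drop = FALSE])
  }, 0)
  list(same = same, different = different)
}

# Scoped RNG helper: evaluates sampling under a private seed without
# disturbing the caller's RNG state.
local_rng <- function(seed) {
  stopifnot(!is.null(seed))
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  }
  env$with <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  env$sample <- function(x, size) env$with(function()
    x[sample.int(length(x), size)])
  env
}

sample_one <- function(x, rng) if (length(x) == 1L) x else rng$sample(x, 1L)

#' Derive a same/different decision threshold by ROC analysis
#'
#' Scans all candidate thresholds (midpoints between adjacent pooled
#' distance values, plus the extremes) and returns the one maximizing
#' Youden's J = sensitivity + specificity - 1, where
#' sensitivity = P(distance > c | different syndromes) and
#' specificity = P(distance <= c | same syndrome). Ties are broken toward
#' the larger threshold. The published operating value for the facial
#' encoder's control pool is shipped as [GESTALT_THRESHOLD].
#'
#' @param same_dists,different_dists Numeric distance vectors from
#'   [build_control_distributions()].
#' @return A list: `c`, `sensitivity`, `specificity`, `youden_j`.
#' @export
derive_threshold <- function(same_dists, different_dists) {
  if (length(same_dists) == 0L || length(different_dists) == 0L)
    stop("both distance distributions must be non-empty")
  pooled <- sort(unique(c(same_dists, different_dists)))
  if (identical(sort(same_dists), sort(different_dists))) {
    warning("same and different distributions identical; threshold at midpoint")
    cands <- stats::median(pooled)
  } else {
    mids <- if (length(pooled) > 1L)
      (pooled[-1L] + pooled[-length(pooled)]) / 2 else numeric(0)
    cands <- c(min(pooled) - .Machine$double.eps, mids, max(pooled))
  }
  sens <- vapply(cands, function(c) mean(different_dists > c), 0)
  spec <- vapply(cands, function(c) mean(same_dists <= c), 0)
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # ties toward the larger threshold
  list(c = cands[best], sensitivity = sens[best], specificity = spec[best],
       youden_j = j[best])
}

#' Published cosine-distance threshold for the same/different decision
#'
#' Operating value derived by ROC analysis on the encoder's 1,499-image /
#' 321-disorder control pool; shipped as a config constant, not recomputed
#' here (recomputation would need the original image database).
#' @export
GESTALT_THRESHOLD <- 0.896

#' Compare two cohorts in embedding space
#'
#' Computes the mean pairwise cosine distance `d(C1, C2)`, then runs
#' `n_iterations` subsampling iterations (a fraction of each cohort drawn
#' without replacement per iteration) and records the fraction of
#' subsampled comparisons exceeding the threshold `c`. If at least 50% of
#' the subsampled comparisons lie above `c`, the cohorts are decided to
#' stem from different syndromes. When control distributions are supplied,
#' a positive predictive value for the observed subsampled distance range
#' is estimated via [ppv()] with sensitivity = P(control different-syndrome
#' distance inside the range) and specificity = P(control same-syndrome
#' distance outside the range).
#'
#' @param C1,C2 Matrices of embedding vectors (rows), e.g. from
#'   [cohort_vectors()].
#' @param c Decision threshold (default [GESTALT_THRESHOLD]).
#' @param n_iterations Number of subsampling iterations (default 100).
#' @param subsample_fraction Fraction of each cohort per iteration
#'   (default 0.75, minimum 2 images where the cohort allows).
#' @param seed Integer seed.
#' @param controls Optional list with `same` and `different` distance
#'   vectors for the PPV estimate.
#' @param p Pre-test probability that two cohorts are from different
#'   syndromes (default 0.5: equal prior odds).
#' @return A list of class `cohort_comparison`: `d`, `c`,
#'   `subsampled_d` (length `n_iterations`), `fraction_above`, `decision`
#'   (`"same"`/`"different"`), `ppv` (or `NA`), `range` of subsampled
#'   distances, `seed`.
#' @export
compare_cohorts <- function(C1, C2, c = GESTALT_THRESHOLD,
                            n_iterations = 100, subsample_fraction = 0.75,
                            seed = 1, controls = NULL, p = 0.5) {
  C1 <- rbind(C1); C2 <- rbind(C2)
  if (nrow(C1) < 1L || nrow(C2) < 1L) stop("cohorts must be non-empty")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  sub_n <- function(n) min(n, max(2L, ceiling(subsample_fraction * n)))
  n1 <- sub_n(nrow(C1)); n2 <- sub_n(nrow(C2))
  if (n1 < 1L || n2 < 1L) stop("subsample size must be >= 1")
  d <- mean_pairwise(C1, C2)
  rng <- local_rng(seed)
  sub_d <- vapply(seq_len(n_iterations), function(i) {
    i1 <- rng$sample(seq_len(nrow(C1)), n1)
    i2 <- rng$sample(seq_len(nrow(C2)), n2)
    mean_pairwise(C1[i1, , drop = FALSE], C2[i2, , drop = FALSE])
  }, 0)
  fraction_above <- mean(sub_d > c)
  decision <- if (fraction_above >= 0.5) "different" else "same"
  rng_d <- range(sub_d)
  ppv_val <- NA_real_
  if (!is.null(controls)) {
    sens <- mean(controls$different >= rng_d[1] & controls$different <= rng_d[2])
    spec <- mean(controls$same < rng_d[1] | controls$same > rng_d[2])
    ppv_val <- tryCatch(ppv(sens, spec, p), error = function(e) NA_real_)
  }
  structure(list(d = d, c = c, subsampled_d = sub_d,
                 fraction_above = fraction_above, decision = decision,
                 ppv = ppv_val, range = rng_d, n_iterations = n_iterations,
                 subsample_fraction = subsample_fraction, seed = seed),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> d = %.4f vs c = %.3f | %d%% above -> %s",
              x$d, x$c, round(100 * x$fraction_above), x$decision))
  if (!is.na(x$ppv)) cat(sprintf(" | PPV = %.3f", x$ppv))
  cat("\n")
  invisible(x)
}

#' Positive predictive value of the distinctness decision
#'
#' `PPV = (sensitivity * p) / (sensitivity * p + (1 - specificity) * (1 - p))`
#' with pre-test probability `p` that two cohorts are from different
#' syndromes. At `p = 0.5` (equal prior odds) this reduces to
#' `sensitivity / (sensitivity + 1 - specificity)`.
#'
#' @param sensitivity,specificity,p Values in `[0, 1]`.
#' @return The PPV, in `[0, 1]`.
#' @export
ppv <- function(sensitivity, specificity, p) {
  if (any(c(sensitivity, specificity, p) < 0) ||
      any(c(sensitivity, specificity, p) > 1))
    stop("sensitivity, specificity and p must lie in [0, 1]")
  den <- sensitivity * p + (1 - specificity) * (1 - p)
  if (den == 0) stop("PPV undefined: denominator is zero")
  sensitivity * p / den
}

#' Within-cohort cohesion against a random-batch control distribution
#'
#' Computes the cohort's mean within-group pairwise cosine distance `d(C)`
#' and compares it to a control distribution built by repeatedly sampling
#' equally sized batches of images from a mixed-syndrome pool and computing
#' their mean pairwise distances. The result is the empirical left-tail
#' percentile of `d(C)` (mid-rank for ties, 0-100 scale): lower mean
#' distance and lower percentile indicate stronger intragroup similarity.
#'
#' @param C Matrix of the cohort's embedding vectors (>= 2 rows).
#' @param pool An [embedding_set()] control pool.
#' @param n_batches Number of random batches for the control distribution.
#' @param seed Integer seed.
#' @return A list of class `cohesion_result`: `d`, `control_distribution`,
#'   `left_tail_percentile`, `n_batches`, `seed`.
#' @export
cohesion <- function(C, pool, n_batches, seed) {
  C <- rbind(C)
  if (nrow(C) < 2L)
    stop("cohesion undefined for a singleton cohort")
  stopifnot(inherits(pool, "embedding_set"), n_batches >= 1)
  if (nrow(pool$vectors) < nrow(C))
    stop("pool smaller than the cohort batch size")
  d <- mean_pairwise(C)
  rng <- local_rng(seed)
  ctrl <- vapply(seq_len(n_batches), function(i) {
    idx <- rng$sample(seq_len(nrow(pool$vectors)), nrow(C))
    mean_pairwise(pool$vectors[idx, , drop = FALSE])
  }, 0)
  pct <- 100 * (sum(ctrl < d) + 0.5 * sum(ctrl == d)) / n_batches
  structure(list(d = d, control_distribution = ctrl,
                 left_tail_percentile = round(pct, 2),
                 n_batches = n_batches, seed = seed),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("<cohesion_result> d(C) = %.4f at the %.2fth percentile of %d control batches\n",
              x$d, x$left_tail_percentile, x$n_batches))
  invisible(x)
}

#' Read / write embedding CSV files
#'
#' CSV layout: `image_id`, `cohort`, `syndrome`, then one column per
#' embedding dimension (`e1`, `e2`, ...).
#'
#' @param path CSV file path.
#' @return An [embedding_set()].
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("image_id", "cohort", "syndrome")
  stopifnot(all(meta %in% names(df)))
  embedding_set(as.matrix(df[, setdiff(names(df), meta), drop = FALSE]),
                cohort = df$cohort, syndrome = df$syndrome,
                image_id = df$image_id)
}

#' @rdname read_embeddings
#' @param set An [embedding_set()].
#' @export
write_embeddings <- function(set, path) {
  mat <- set$vectors
  colnames(mat) <- paste0("e", seq_len(ncol(mat)))
  df <- data.frame(image_id = set$image_id, cohort = set$cohort,
                   syndrome = set$syndrome, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
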
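#' Generalized Procrustes Analysis normalization of two-channel arrays
#'
#' Each array is represented as a configuration of points, one per spot, in
#' the (A, M) plane: A = mean log2 intensity, M = log2(treatment/reference).
#' Dye-reversal arrays are re-oriented (channels swapped back) first. The
#' configurations are then aligned by translation (centering), isotropic
#' scaling (to unit centroid size) and rotation to an iteratively refined
#' consensus; iteration stops when the consensus moves less than `tol`.
#' Aligned configurations are mapped back to the common scale (mean centroid
#' size and mean centroid) and back-transformed to channel intensities.
#'
#' @param arrays Array table as produced by [simulate_microarray()] or read
#'   from `arrays.tsv` (columns `array_id`, `dye_swapped`, `spot_id`,
#'   `gene_id`, `ch_treat`, `ch_ref`; a `treatment` column is carried through
#'   if present). All arrays must share the same spot set.
#' @param tol Convergence tolerance on the consensus configuration.
#' @param max_iter Iteration cap.
#' @return A table with the same schema, normalized intensities and all
#'   arrays in treatment/reference orientation (`dye_swapped` = FALSE).
#'   Attribute `gpa_rss` holds the consensus residual sum of squares per
#'   iteration (non-increasing).
#' @export
gpa_normalize <- function(arrays, tol = 1e-13, max_iter = 200L) {
  if (any(arrays$ch_treat <= 0 | arrays$ch_ref <= 0)) {
    stop("gpa_normalize: intensities must be strictly positive", call. = FALSE)
  }
  ids <- unique(arrays$array_id)
  if (length(ids) < 2L) {
    stop("gpa_normalize: need at least 2 arrays", call. = FALSE)
  }

  # orientation-correct dye reversals, then build (A, M) configurations
  sw <- arrays$dye_swapped
  treat <- ifelse(sw, arrays$ch_ref, arrays$ch_treat)
  ref <- ifelse(sw, arrays$ch_treat, arrays$ch_ref)
  arrays$ch_treat <- treat
  arrays$ch_ref <- ref
  arrays$dye_swapped <- FALSE

  spot_order <- unique(arrays$spot_id)
  configs <- lapply(ids, function(id) {
    a <- arrays[arrays$array_id == id, ]
    a <- a[match(spot_order, a$spot_id), ]
    if (any(is.na(a$spot_id))) {
      stop("gpa_normalize: arrays do not share a common spot set", call. = FALSE)
    }
    A <- 0.5 * (log2(a$ch_treat) + log2(a$ch_ref))
    M <- log2(a$ch_treat) - log2(a$ch_ref)
    cbind(A, M)
  })

  centers <- lapply(configs, colMeans)
  centered <- mapply(function(x, m) sweep(x, 2L, m), configs, centers,
                     SIMPLIFY = FALSE)
  rho <- vapply(centered, function(x) sqrt(sum(x^2)), numeric(1))
  if (any(rho == 0)) stop("gpa_normalize: degenerate (constant) array", call. = FALSE)
  scaled <- mapply(function(x, r) x / r, centered, rho, SIMPLIFY = FALSE)

  aligned <- scaled
  consensus <- Reduce(`+`, aligned) / length(aligned)
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(scaled, procrustes_rotate, target = consensus)
    new_consensus <- Reduce(`+`, aligned) / length(aligned)
    rss <- sum(vapply(aligned, function(x) sum((x - new_consensus)^2),
                      numeric(1)))
    rss_trace <- c(rss_trace, rss)
    if (sum((new_consensus - consensus)^2) < tol) {
      consensus <- new_consensus
      break
    }
    consensus <- new_consensus
  }

  mean_rho <- mean(rho)
  grand_center <- Reduce(`+`, centers) / length(centers)
  out <- arrays
  for (j in seq_along(ids)) {
    cfg <- aligned[[j]] * mean_rho
    cfg <- sweep(cfg, 2L, grand_center, `+`)
    A <- cfg[, 1L]; M <- cfg[, 2L]
    sel <- out$array_id == ids[j]
    ord <- match(out$spot_id[sel], spot_order)
    out$ch_treat[sel] <- 2^(A + M / 2)[ord]
    out$ch_ref[sel] <- 2^(A - M / 2)[ord]
  }
  attr(out, "gpa_rss") <- rss_trace
  out
}

# rotate (orthogonal, det +1) a centered unit-size configuration onto target
procrustes_rotate <- function(x, target) {
  s <- svd(crossprod(x, target))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {  # enforce pure rotation, no reflection
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- u %*% t(s$v)
  }
  x %*% r
}

#' Collapse spot-level intensities to a gene-by-array log-ratio matrix
#'
#' Duplicate spots of a gene are averaged on the log2-ratio scale within each
#' array before any statistics are computed.
#'
#' @param arrays Array table (orientation-corrected, e.g. the output of
#'   [gpa_normalize()]; raw tables are corrected here using `dye_swapped`).
#' @return Numeric matrix, genes x arrays, of mean log2(treatment/reference).
#' @export
collapse_log_ratios <- function(arrays) {
  treat <- ifelse(arrays$dye_swapped, arrays$ch_ref, arrays$ch_treat)
  ref <- ifelse(arrays$dye_swapped, arrays$ch_treat, arrays$ch_ref)
  m <- log2(treat) - log2(ref)
  genes <- unique(arrays$gene_id)
  ids <- unique(arrays$array_id)
  out <- matrix(NA_real_, length(genes), length(ids),
                dimnames = list(genes, ids))
  agg <- tapply(m, list(arrays$gene_id, arrays$array_id), mean)
  out[rownames(agg), colnames(agg)] <- agg
  out
}

#' One-class SAM statistic
#'
#' For gene i with replicate log2 ratios x_i: d_i = rbar_i / (s_i + s0) where
#' rbar_i is the mean log ratio, s_i its standard error, and s0 the fudge
#' factor stabilizing genes with tiny scatter. By default s0 is the 5th
#' percentile of the s_i distribution; `s0_method = "cv-min"` instead picks
#' the percentile of s minimizing the coefficient of variation of the d
#' spread across s-quantile windows.
#'
#' Genes with fewer than 2 finite replicates get `d = NA` and are flagged
#' `excluded`. A gene with zero scatter and s0 = 0 gets d = +/-Inf and ranks
#' above every finite d (ties broken by gene id).
#'
#' @param x Genes-by-replicates matrix of log2 ratios (rownames = gene ids).
#' @param s0 Fudge factor; `NULL` (default) selects it by `s0_method`.
#' @param s0_method `"quantile"` (5th percentile of s) or `"cv-min"`.
#' @return `data.frame` with `gene_id`, `mean_log2`, `s` (standard error),
#'   `d`, `excluded`; attribute `s0` records the value used.
#' @export
sam_statistic <- function(x, s0 = NULL, s0_method = c("quantile", "cv-min")) {
  s0_method <- match.arg(s0_method)
  n_ok <- rowSums(is.finite(x))
  rbar <- rowMeans(x, na.rm = TRUE)
  s <- row_se(x, rbar, n_ok)
  excluded <- n_ok < 2L
  if (is.null(s0)) {
    s_ok <- s[!excluded]
    s0 <- switch(s0_method,
                 quantile = stats::quantile(s_ok, 0.05, names = FALSE),
                 `cv-min` = s0_cv_min(rbar[!excluded], s_ok))
  }
  d <- rbar / (s + s0)
  d[excluded] <- NA_real_
  out <- data.frame(gene_id = rownames(x), mean_log2 = rbar, s = s, d = d,
                    excluded = excluded, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  out
}

# standard error of each row, NA-tolerant, without per-row sd() calls
row_se <- function(x, rbar = rowMeans(x, na.rm = TRUE),
                   n_ok = rowSums(is.finite(x))) {
  ss <- rowSums((x - rbar)^2, na.rm = TRUE)
  sdv <- sqrt(ss / pmax(n_ok - 1L, 1L))
  sdv / sqrt(n_ok)
}

# pick s0 among percentiles of s to minimize the coefficient of variation of
# the median absolute d across 100 s-quantile windows
s0_cv_min <- function(rbar, s) {
  cand <- stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE)
  br <- stats::quantile(s, seq(0, 1, by = 0.01), names = FALSE)
  bin <- cut(s, unique(br), include.lowest = TRUE)
  cv <- vapply(cand, function(a) {
    d <- rbar / (s + a)
    v <- tapply(d, bin, stats::mad)
    v <- v[is.finite(v) & v > 0]
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Permutation q-values for the SAM statistic
#'
#' Null d-distributions come from random sign flips of the replicate arrays
#' (one-class design; under the null the log ratios are symmetric about 0, so
#' negating a whole array is a symmetry of the data). Each permutation draws
#' one sign per array; with k arrays there are 2^k distinct patterns and the
#' requested `n_perm` draws sample them with replacement. For each gene the
#' raw q is the median, over permutations, of the count of null |d*| at or
#' above that gene's |d|, divided by the observed count of |d| at or above
#' it; the median makes the estimate robust to the two degenerate patterns
#' (identity and global negation) that reproduce the observed statistics. A
#' step-up pass then makes q monotone non-increasing in |d| rank, and q is
#' capped at 1.
#'
#' @param x Genes-by-replicates matrix of log2 ratios.
#' @param fit Output of [sam_statistic()] on `x` (its `s0` attribute is
#'   reused for the permuted statistics).
#' @param n_perm Number of permutations (>= 100 recommended; must be >= 1).
#' @param seed Integer seed for the permutation stream.
#' @return `fit` with a `q` column added (NA for excluded genes).
#' @export
sam_qvalues <- function(x, fit, n_perm = 200L, seed = 1L) {
  if (n_perm < 1L) stop("sam_qvalues: n_perm must be >= 1", call. = FALSE)
  s0 <- attr(fit, "s0")
  ok <- !fit$excluded
  d_obs <- fit$d[ok]
  xo <- x[ok, , drop = FALSE]
  n <- nrow(xo); k <- ncol(xo)
  abs_d <- abs(d_obs)

  set.seed(seed)
  # observed count of |d| >= each gene's |d| (ties counted)
  ord <- order(abs_d, decreasing = TRUE)
  obs_count <- rank(-abs_d, ties.method = "max")

  thresholds <- sort(abs_d)  # ascending, for findInterval
  fp <- matrix(0L, n_perm, n)
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), k, replace = TRUE)
    xp <- sweep(xo, 2L, flips, `*`)
    rbar <- rowMeans(xp, na.rm = TRUE)
    s <- row_se(xp, rbar)
    d_null <- abs(rbar / (s + s0))
    # for each threshold t (each gene's |d|): count of null values >= t
    fp[b, ] <- n - findInterval(thresholds - 1e-12, sort(d_null))
  }
  med_fp <- apply(fp, 2L, stats::median)  # aligned with thresholds (ascending)
  # map back: thresholds[i] corresponds to sorted abs_d
  q_raw <- med_fp[rank(abs_d, ties.method = "min")] / obs_count

  # step-up: in decreasing-|d| order, q_k = min(raw_k, raw_{k+1}, ...)
  q_sorted <- q_raw[ord]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[ord] <- q_sorted
  q <- pmin(q, 1)

  fit$q <- NA_real_
  fit$q[ok] <- q
  fit
}

#' Signed fold change
#'
#' Expresses a positive ratio r as +r when r >= 1 and -1/r when r < 1, so a
#' negative value always means a decrease relative to control and |FC| >= 1.
#'
#' @param ratio Positive ratio(s), treatment over control.
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(c(2, 0.5, 1))  # +2, -2, +1
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio) | ratio <= 0)) {
    stop("signed_fold_change: ratio must be positive", call. = FALSE)
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Select differentially expressed transcripts
#'
#' @param results Output of [sam_qvalues()].
#' @param q_threshold Call threshold on q (strict `<`), default 0.05.
#' @return Rows of `results` with `q < q_threshold`, a `signed_fc` column
#'   added (from the mean log2 ratio), sorted by q then decreasing |d|.
#' @export
select_de <- function(results, q_threshold = 0.05) {
  sel <- results[!is.na(results$q) & results$q < q_threshold, , drop = FALSE]
  sel$signed_fc <- if (nrow(sel)) signed_fold_change(2^sel$mean_log2) else numeric(0)
  sel[order(sel$q, -abs(sel$d)), , drop = FALSE]
}

#' Microarray differential expression, end to end for one treatment
#'
#' Normalizes the arrays of one treatment by GPA, averages duplicate spots,
#' computes the one-class SAM statistic and permutation q-values, and selects
#' transcripts at `q < q_threshold`.
#'
#' @param arrays Full array table; rows with `treatment == treatment` are used.
#' @param treatment `"SKF"` or `"LY"`.
#' @param q_threshold q cutoff (default 0.05).
#' @param n_perm Permutations for the q-values.
#' @param seed Seed for the permutation stream.
#' @param normalize Apply [gpa_normalize()] first (default TRUE).
#' @return List with `results` (all genes) and `de` (selected transcripts).
#' @export
microarray_de <- function(arrays, treatment, q_threshold = 0.05,
                          n_perm = 200L, seed = 1L, normalize = TRUE) {
  stopifnot(treatment %in% TREATMENTS)
  a <- if ("treatment" %in% names(arrays)) {
    arrays[arrays$treatment == treatment, , drop = FALSE]
  } else arrays
  if (normalize) a <- gpa_normalize(a)
  x <- collapse_log_ratios(a)
  st <- sam_statistic(x)
  st <- sam_qvalues(x, st, n_perm = n_perm, seed = seed)
  list(results = st, de = select_de(st, q_threshold))
}
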
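get_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else x
}

#' Normalise a UMI count matrix
#'
#' Scales each cell to the median library size (so row sums are equal on
#' the linear scale) and log-transforms: `log(1 + x)`.  The transformation
#' is order-preserving within each cell.
#'
#' @param x a `count_matrix` (from [simulate_counts()] or
#'   [read_counts_mtx()]) or a genes x cells matrix.
#' @return object of class `norm_counts`: list with `log_mat` (dense genes
#'   x cells, log scale), `linear_mat` (genes x cells, counts scaled to the
#'   median library), `size_factors`, `lib_sizes` and, when available,
#'   `cell_meta` / `gene_meta`.
#' @export
normalize_counts <- function(x) {
  counts <- get_counts(x)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero total counts")
  sf <- lib / median(lib)
  lin <- as.matrix(counts %*% Matrix::Diagonal(x = 1 / sf))
  dimnames(lin) <- dimnames(counts)
  structure(list(
    log_mat = log1p(lin), linear_mat = lin,
    size_factors = sf, lib_sizes = lib,
    cell_meta = if (inherits(x, "count_matrix")) x$cell_meta else NULL,
    gene_meta = if (inherits(x, "count_matrix")) x$gene_meta else NULL
  ), class = "norm_counts")
}

#' PCA embedding of normalised cells
#'
#' Selects the `n_hvg` most variable genes on the log scale and runs
#' centred PCA over cells.  PC1 approximates developmental progression; its
#' sign is arbitrary, so it can be oriented with a marker gene set whose
#' expression is known to increase (or decrease) along progression —
#' ribosomal genes, repressed as starvation proceeds, are the natural
#' decreasing choice.
#'
#' @param norm a [normalize_counts()] object.
#' @param n_hvg number of highly variable genes (capped at the gene count).
#' @param n_pcs number of components to keep.
#' @param orient_genes optional character vector of marker genes used to
#'   orient PC1.
#' @param orient_direction `"increasing"` or `"decreasing"`: whether the
#'   marker score should rise or fall with PC1.
#' @return object of class `cell_embedding`: `scores` (cells x PCs),
#'   `var_explained`, `hvg` and the orientation sign applied.
#' @export
embed_cells <- function(norm, n_hvg = 2000, n_pcs = 30,
                        orient_genes = NULL,
                        orient_direction = c("decreasing", "increasing")) {
  orient_direction <- match.arg(orient_direction)
  if (!inherits(norm, "norm_counts")) stop_config("norm must be norm_counts")
  m <- norm$log_mat
  vars <- apply(m, 1, var)
  n_hvg <- min(n_hvg, sum(vars > 0))
  hvg <- names(sort(vars, decreasing = TRUE))[seq_len(n_hvg)]
  n_pcs <- min(n_pcs, length(hvg) - 1L, ncol(m) - 1L)
  pc <- prcomp(t(m[hvg, , drop = FALSE]), center = TRUE, scale. = FALSE,
               rank. = n_pcs)
  scores <- pc$x
  flip <- 1
  if (!is.null(orient_genes)) {
    sc <- gene_set_score(norm, orient_genes)
    r <- cor(scores[, 1], sc, method = "spearman")
    want <- if (orient_direction == "increasing") 1 else -1
    if (sign(r) != want) flip <- -1
    scores[, 1] <- flip * scores[, 1]
  }
  structure(list(scores = scores,
                 var_explained = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2),
                 hvg = hvg, orientation = flip),
            class = "cell_embedding")
}

#' Mean expression of a gene set per cell
#'
#' @param norm a [normalize_counts()] object.
#' @param genes non-empty character vector of gene identifiers.
#' @param scale `"log"` (default) or `"linear"`.
#' @return numeric vector, one value per cell.
#' @export
gene_set_score <- function(norm, genes, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (length(genes) == 0) stop("empty gene set")
  m <- if (scale == "log") norm$log_mat else norm$linear_mat
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop(sprintf("unknown genes: %s", paste(head(missing, 5), collapse = ", ")))
  colMeans(m[genes, , drop = FALSE])
}

#' Detect the transcriptome jump as a density gap along PC1
#'
#' Estimates the cell density along PC1 with a Gaussian kernel (Silverman
#' bandwidth), finds density modes, and scores every valley between
#' adjacent modes by its prominence (the lower flanking mode height divided
#' by the valley height).  The jump is the most prominent valley; it is
#' called only when that prominence reaches `prominence_threshold`.  Cells
#' are labelled `pre`/`post` by their side of the valley (assuming PC1 is
#' oriented along progression).  The result is invariant to cell order and
#' PC1 sign (up to the pre/post label swap).
#'
#' @param scores a `cell_embedding`, or a numeric vector of PC1 scores.
#' @param prominence_threshold minimum mode/valley density ratio.
#' @param min_mode_frac modes below this fraction of the density maximum
#'   are ignored (isolated outliers form negligible tail modes whose
#'   valleys would otherwise score arbitrarily high prominence).
#' @return object of class `jump_call`: `jump` (logical), `valley`
#'   (PC1 position), `prominence`, `side` (factor `pre`/`post` per cell),
#'   `n_pre`, `n_post`, `n_valley_region` (cells between the flanking
#'   modes with density below half the lower mode) and the `density`.
#' @export
detect_jump <- function(scores, prominence_threshold = 2,
                        min_mode_frac = 0.1) {
  x <- if (inherits(scores, "cell_embedding")) scores$scores[, 1] else
    as.numeric(scores)
  d <- stats::density(x, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
              FALSE)
  modes <- which(is_max)
  modes <- modes[y[modes] >= min_mode_frac * max(y)]
  no_jump <- function() structure(list(
    jump = FALSE, valley = NA_real_, prominence = NA_real_,
    side = factor(rep("pre", length(x)), levels = c("pre", "post")),
    n_pre = length(x), n_post = 0L, n_valley_region = NA_integer_,
    density = d), class = "jump_call")
  if (length(modes) < 2) return(no_jump())
  best <- NULL
  for (i in seq_len(length(modes) - 1)) {
    seg <- modes[i]:modes[i + 1]
    v <- seg[which.min(y[seg])]
    lower_mode <- min(y[modes[i]], y[modes[i + 1]])
    prom <- lower_mode / max(y[v], .Machine$double.eps)
    if (is.null(best) || prom > best$prom)
      best <- list(v = v, prom = prom, i = i)
  }
  if (best$prom < prominence_threshold) return(no_jump())
  valley <- d$x[best$v]
  side <- factor(ifelse(x <= valley, "pre", "post"),
                 levels = c("pre", "post"))
  lo_mode <- modes[best$i]; hi_mode <- modes[best$i + 1]
  half <- 0.5 * min(y[lo_mode], y[hi_mode])
  reg <- d$x[lo_mode:hi_mode][y[lo_mode:hi_mode] < half]
  n_valley <- if (length(reg)) sum(x >= min(reg) & x <= max(reg)) else 0L
  structure(list(jump = TRUE, valley = valley, prominence = best$prom,
                 side = side, n_pre = sum(side == "pre"),
                 n_post = sum(side == "post"),
                 n_valley_region = n_valley, density = d),
            class = "jump_call")
}

#' Cell-state clustering from the cell-cell correlation matrix
#'
#' Computes Pearson correlations between cells over (gene-centred) highly
#' variable genes, clusters the distance `1 - r` with average-linkage
#' hierarchical clustering, and chooses the number of clusters by maximum
#' mean silhouette width over `k_range`.  A flat, low silhouette profile
#' (below `low_confidence`) flags an unclustered dataset.
#'
#' @param norm a [normalize_counts()] object.
#' @param k_range candidate cluster numbers.
#' @param n_hvg genes used for the correlation.
#' @param low_confidence silhouette width below which the chosen k is
#'   flagged low-confidence.
#' @return list with `k`, `labels`, `silhouette` (named vector over
#'   `k_range`), `low_confidence`, `hclust` and `cut` (function giving
#'   labels at any k).
#' @export
correlation_clusters <- function(norm, k_range = 2:8, n_hvg = 2000,
                                 low_confidence = 0.25) {
  m <- norm$log_mat
  vars <- apply(m, 1, var)
  n_hvg <- min(n_hvg, sum(vars > 0))
  hvg <- names(sort(vars, decreasing = TRUE))[seq_len(n_hvg)]
  x <- m[hvg, , drop = FALSE]
  x <- x - rowMeans(x)                    # centre genes
  z <- scale(x)                            # standardise cells (columns)
  r <- crossprod(z) / (nrow(z) - 1)
  r[r > 1] <- 1; r[r < -1] <- -1
  dd <- as.dist(1 - r)
  hc <- hclust(dd, method = "average")
  k_range <- k_range[k_range < ncol(x)]
  sil <- vapply(k_range, function(k) {
    lab <- cutree(hc, k)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, dd)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  k <- k_range[which.max(sil)]
  list(k = k, labels = cutree(hc, k), silhouette = sil,
       low_confidence = max(sil, na.rm = TRUE) < low_confidence,
       hclust = hc, cut = function(k) cutree(hc, k))
}

#' Binned expression profiles along a cell ordering
#'
#' Means of linear-scale normalised expression in `n_bins` equal-size bins
#' of cells along an ordering (developmental progression for single-cell
#' data, collection time for a population time course).
#'
#' @param norm a [normalize_counts()] object.
#' @param order integer vector: cell indices in progression order.
#' @param n_bins number of bins.
#' @return matrix genes x bins, with attribute `bin_of_rank` mapping cell
#'   rank to bin.
#' @export
expression_profiles <- function(norm, order, n_bins = 20) {
  m <- norm$linear_mat[, order, drop = FALSE]
  n <- ncol(m)
  bin <- ceiling(seq_len(n) / n * n_bins)
  prof <- vapply(seq_len(n_bins), function(b)
    rowMeans(m[, bin == b, drop = FALSE]), numeric(nrow(m)))
  dimnames(prof) <- list(rownames(m), NULL)
  attr(prof, "bin_of_rank") <- bin
  prof
}

#' Categorise genes relative to the jump boundary
#'
#' Assigns each gene to one of the three jump-related expression programs
#' using three windows along the progression: a boundary-spanning window
#' (a `span_frac` share of cells centred on the boundary), the same-width
#' window immediately before it (the local pre-jump baseline), and all
#' cells after it.  A gene is `pre_jump` when its post/pre expression ratio
#' falls to `theta_down` or below (repressed at the jump); an induced gene
#' (ratio at least `theta_up`) is `jump` when induction is already evident
#' before the boundary -- its mean expression over the cells immediately
#' preceding the boundary reaches at least `pre_induction_frac` of its full
#' profile amplitude -- and `post_jump` when it is not; anything else
#' (constant genes, genes repressed well before the boundary) is
#' `unclassified`.
#'
#' @param norm a [normalize_counts()] object.
#' @param order cell indices in progression order (e.g. `order(PC1)`).
#' @param boundary_rank rank (within `order`) of the jump boundary, e.g.
#'   `n_pre` from [detect_jump()].
#' @param span_frac width of the boundary-spanning window as a fraction of
#'   all cells.
#' @param theta_down,theta_up repression / induction ratio thresholds.
#' @param pre_induction_frac fraction of a gene's profile amplitude that
#'   must be reached before the boundary for the gene to span the jump.
#' @param n_bins bins for the profiles.
#' @return data.frame `gene`, `category`, `post_pre_ratio`,
#'   `span_pre_frac` (pre-boundary induction evidence), `halfmax_bin`
#'   (interpolated half-maximum position, in bins, as a diagnostic);
#'   attribute `windows` records the window rank ranges.
#' @export
categorize_genes <- function(norm, order, boundary_rank, span_frac = 0.2,
                             theta_down = 0.5, theta_up = 2,
                             pre_induction_frac = 0.15, n_bins = 20) {
  n <- length(order)
  w <- round(span_frac * n)
  span_lo <- max(1L, round(boundary_rank - w / 2))
  span_hi <- min(n, span_lo + w - 1L)
  pre_lo <- max(1L, span_lo - w)
  pre_hi <- span_lo - 1L
  if (pre_hi < pre_lo) stop("boundary too close to the start of the ordering")
  post_lo <- span_hi + 1L
  if (post_lo > n) stop("boundary too close to the end of the ordering")
  m <- norm$linear_mat[, order, drop = FALSE]
  pre_mean <- rowMeans(m[, pre_lo:pre_hi, drop = FALSE])
  post_mean <- rowMeans(m[, post_lo:n, drop = FALSE])
  ratio <- post_mean / pmax(pre_mean, 1e-8)

  prof <- expression_profiles(norm, order, n_bins)
  bin_of_rank <- attr(prof, "bin_of_rank")
  boundary_bin <- bin_of_rank[boundary_rank]
  # cells immediately before the boundary: where spanning induction shows.
  # The baseline is the pre-window mean rather than the profile minimum:
  # library-size normalisation carries a composition bias (cells with large
  # induced programs get bigger libraries), so the uninduced plateau of a
  # late gene drifts across bins and its minimum is not a stable reference.
  edge_n <- max(20L, round(0.03 * n))
  edge <- max(1L, boundary_rank - edge_n + 1L):boundary_rank
  amp <- apply(prof, 1, max) - pre_mean
  span_pre_frac <- (rowMeans(m[, edge, drop = FALSE]) - pre_mean) /
    pmax(amp, 1e-8)
  halfmax_bin <- apply(prof, 1, function(p) {
    lo <- min(p); hi <- max(p)
    if (hi - lo < 1e-8) return(NA_real_)
    half <- (lo + hi) / 2
    cross <- which(p >= half)
    if (!length(cross)) return(NA_real_)
    j <- cross[1]
    if (j == 1) return(1)
    j - 1 + (half - p[j - 1]) / (p[j] - p[j - 1])
  })
  category <- rep("unclassified", nrow(m))
  category[ratio <= theta_down] <- "pre_jump"
  induced <- ratio >= theta_up
  category[induced & span_pre_frac >= pre_induction_frac] <- "jump"
  category[induced & span_pre_frac < pre_induction_frac] <- "post_jump"
  out <- data.frame(gene = rownames(m), category = category,
                    post_pre_ratio = ratio,
                    span_pre_frac = span_pre_frac,
                    halfmax_bin = halfmax_bin, row.names = NULL)
  attr(out, "windows") <- list(pre = c(pre_lo, pre_hi),
                               span = c(span_lo, span_hi),
                               post = c(post_lo, n),
                               boundary_bin = boundary_bin)
  out
}

#' Classify cAMP dependence from paired wild-type / acaA-null profiles
#'
#' Compares per-gene expression profiles between conditions.  Pre-jump
#' genes test whether repression still happens without cAMP: a gene whose
#' knockout late/early ratio stays at or above 0.5 while the wild-type
#' ratio falls to `theta_down` or below has `failed_repression`; otherwise
#' repression is intact.  Induced genes (jump / post-jump) compare peak
#' expression: knockout maximum at or above `retained_frac` of the
#' wild-type maximum is `retained`, within `[partial_frac, retained_frac)`
#' is `partial_induction`, below `partial_frac` is `complete_loss`.
#'
#' @param wt_profiles,ko_profiles genes x bins matrices from
#'   [expression_profiles()] (wild-type ordered by inferred progression;
#'   knockout by its known collection-time axis).
#' @param categories data.frame from [categorize_genes()] (or any with
#'   `gene` and `category`).
#' @param theta_down wild-type repression threshold.
#' @param retained_frac,partial_frac knockout/wild-type peak-ratio cuts.
#' @param edge_frac fraction of bins in the early and late windows.
#' @return data.frame `gene`, `category`, `dependence`, `wt_ratio`,
#'   `ko_ratio`, `peak_ratio`.
#' @export
classify_dependence <- function(wt_profiles, ko_profiles, categories,
                                theta_down = 0.5, retained_frac = 0.5,
                                partial_frac = 0.1, edge_frac = 0.2) {
  genes <- intersect(rownames(wt_profiles), rownames(ko_profiles))
  cat_map <- setNames(categories$category, categories$gene)
  nb <- ncol(wt_profiles)
  k <- max(1L, round(edge_frac * nb))
  early <- seq_len(k); late <- (nb - k + 1L):nb
  res <- lapply(genes, function(g) {
    wt <- wt_profiles[g, ]; ko <- ko_profiles[g, ]
    wt_ratio <- mean(wt[late]) / max(mean(wt[early]), 1e-8)
    ko_ratio <- mean(ko[late]) / max(mean(ko[early]), 1e-8)
    peak_ratio <- max(ko) / max(max(wt), 1e-8)
    cat_g <- if (g %in% names(cat_map)) cat_map[[g]] else "unclassified"
    dep <- if (cat_g == "pre_jump") {
      if (ko_ratio >= 0.5 && wt_ratio <= theta_down) "failed_repression"
      else "repression_intact"
    } else if (cat_g %in% c("jump", "post_jump")) {
      if (peak_ratio >= retained_frac) "retained"
      else if (peak_ratio >= partial_frac) "partial_induction"
      else "complete_loss"
    } else "n/a"
    data.frame(gene = g, category = cat_g, dependence = dep,
               wt_ratio = wt_ratio, ko_ratio = ko_ratio,
               peak_ratio = peak_ratio)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
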
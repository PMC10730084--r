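#' Configuration for synthetic single-cell count matrices
#'
#' Emulates a continuous single-cell transcriptomics time course across the
#' developmental niche: cells are positioned on a pseudotime axis s in
#' \[0, 1\] drawn from a four-state mixture (feeding, starving, aggregating,
#' mound) with an excluded open interval around the jump position (the
#' "gap"), and genes follow sigmoid programs over s.  The gene panel mirrors
#' the three jump-related programs — genes repressed at the jump (pre-jump),
#' induced spanning the jump (jump) and induced after the jump (post-jump) —
#' plus ribosomal genes (repressed earlier, during the feeding-to-starving
#' transition) and constant housekeeping genes.  Counts are negative
#' binomial with log-normal library-size factors.  The `acaA_null` condition
#' modifies the programs gene-by-gene according to the cAMP-dependence
#' flags: flagged pre-jump genes fail to be repressed, a subset of jump
#' genes retains partial induction (`partial_scale` of the wild-type
#' amplitude), flagged complete-loss genes stay at the low plateau, and the
#' single retained post-jump gene keeps its wild-type program.
#'
#' @param replicate_sizes cells per replicate (two replicates of 2671 and
#'   2072 cells by default, 4743 in total).
#' @param jump_position,gap_halfwidth jump centre s_J and gap half-width
#'   delta; no cell has pseudotime inside (s_J - delta, s_J + delta).
#' @param n_pre_jump,n_pre_dependent pre-jump panel size and how many fail
#'   repression without cAMP (46 of 54).
#' @param n_jump,n_jump_partial jump panel size and how many show partial
#'   induction without cAMP (16 of 22; the remainder lose induction
#'   completely).
#' @param n_post_jump,n_post_retained post-jump panel size and how many
#'   retain detectable induction without cAMP (1 of 82).
#' @param n_ribosomal,n_housekeeping,n_mound_program background panel
#'   sizes: ribosomal genes (repressed at the feeding-to-starving
#'   transition), constant housekeeping genes, and the broad
#'   aggregate-upregulated program induced at the mound stage (sizes follow
#'   the marker gene sets used to annotate the map: 78 ribosomal, 215
#'   upregulated in aggregates).
#' @param low_mean,high_mean low/high plateau means (counts at the median
#'   library size).
#' @param hk_mean housekeeping mean.
#' @param ribo_high,ribo_low ribosomal plateaus.
#' @param slope,ribo_slope sigmoid steepnesses (per unit s).
#' @param partial_scale fraction of the wild-type induction amplitude kept
#'   by partially cAMP-dependent jump genes in the `acaA_null` condition.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_sdlog sd of the log-normal library-size factor.
#' @param state_weights,state_centres,state_sds four-component mixture for
#'   pseudotime (feeding, starving, aggregating, mound); components are
#'   truncated to their side of the gap.
#' @param conditions which conditions to simulate.
#' @param rng_seed integer seed.
#' @return an object of class `counts_config`.
#' @export
counts_config <- function(replicate_sizes = c(2671L, 2072L),
                          jump_position = 0.5, gap_halfwidth = 0.05,
                          n_pre_jump = 54L, n_pre_dependent = 46L,
                          n_jump = 22L, n_jump_partial = 16L,
                          n_post_jump = 82L, n_post_retained = 1L,
                          n_ribosomal = 78L, n_housekeeping = 100L,
                          n_mound_program = 215L,
                          low_mean = 0.4, high_mean = 6,
                          hk_mean = 3, ribo_high = 6, ribo_low = 0.6,
                          slope = 40, ribo_slope = 60,
                          partial_scale = 0.3,
                          dispersion = 0.1, libsize_sdlog = 0.3,
                          state_weights = c(0.28, 0.26, 0.26, 0.20),
                          state_centres = c(0.12, 0.34, 0.63, 0.88),
                          state_sds = c(0.04, 0.04, 0.035, 0.04),
                          conditions = c("WT", "acaA_null"),
                          rng_seed = 1L) {
  if (jump_position <= 0 || jump_position >= 1)
    stop_config("jump_position must be in (0, 1)")
  if (gap_halfwidth < 0 || jump_position - gap_halfwidth <= 0 ||
      jump_position + gap_halfwidth >= 1)
    stop_config("gap must fit inside (0, 1)")
  if (n_pre_dependent > n_pre_jump || n_jump_partial > n_jump ||
      n_post_retained > n_post_jump)
    stop_config("dependence-flag counts exceed panel sizes")
  if (low_mean < 0 || high_mean < 0 || hk_mean < 0)
    stop_config("means must be >= 0")
  if (dispersion <= 0) stop_config("dispersion must be > 0")
  if (length(state_weights) != 4 || any(state_weights <= 0))
    stop_config("state_weights must be 4 positive values")
  conditions <- match.arg(conditions, c("WT", "acaA_null"),
                          several.ok = TRUE)
  structure(as.list(environment()), class = "counts_config")
}

sigmoid <- function(s, centre, slope) 1 / (1 + exp(-slope * (s - centre)))

# gene panel with per-gene program parameters and truth labels
build_gene_panel <- function(cfg) {
  up <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))
  centres_pre <- runif(cfg$n_pre_jump,
                       cfg$jump_position - cfg$gap_halfwidth / 2,
                       cfg$jump_position + cfg$gap_halfwidth / 2)
  centres_jump <- runif(cfg$n_jump,
                        cfg$jump_position - 1.8 * cfg$gap_halfwidth,
                        cfg$jump_position - 1.2 * cfg$gap_halfwidth)
  n_early <- ceiling(cfg$n_post_jump / 2)
  centres_post <- c(
    runif(n_early, cfg$jump_position + 0.8 * cfg$gap_halfwidth,
          cfg$jump_position + 1.6 * cfg$gap_halfwidth),
    runif(cfg$n_post_jump - n_early, 0.72, 0.76))
  centres_ribo <- runif(cfg$n_ribosomal, 0.23, 0.27)
  centres_mound <- runif(cfg$n_mound_program, 0.73, 0.77)
  hk_means <- cfg$hk_mean * exp(rnorm(cfg$n_housekeeping, 0, 0.2))

  panel <- rbind(
    data.frame(gene = up(cfg$n_pre_jump, "pre"), category = "pre_jump",
               direction = "down", centre = centres_pre, slope = cfg$slope,
               low = cfg$low_mean, high = cfg$high_mean,
               dependence_truth = rep(c("failed_repression",
                                        "repression_intact"),
                                      c(cfg$n_pre_dependent,
                                        cfg$n_pre_jump - cfg$n_pre_dependent))),
    data.frame(gene = up(cfg$n_jump, "jump"), category = "jump",
               direction = "up", centre = centres_jump, slope = cfg$slope,
               low = cfg$low_mean, high = cfg$high_mean,
               dependence_truth = rep(c("partial_induction", "complete_loss"),
                                      c(cfg$n_jump_partial,
                                        cfg$n_jump - cfg$n_jump_partial))),
    data.frame(gene = up(cfg$n_post_jump, "post"), category = "post_jump",
               direction = "up", centre = centres_post, slope = cfg$slope,
               low = cfg$low_mean, high = cfg$high_mean,
               dependence_truth = rep(c("retained", "complete_loss"),
                                      c(cfg$n_post_retained,
                                        cfg$n_post_jump - cfg$n_post_retained))),
    data.frame(gene = up(cfg$n_ribosomal, "ribo"), category = "background",
               direction = "down", centre = centres_ribo,
               slope = cfg$ribo_slope, low = cfg$ribo_low,
               high = cfg$ribo_high, dependence_truth = "n/a"),
    data.frame(gene = up(cfg$n_housekeeping, "hk"), category = "background",
               direction = "flat", centre = NA_real_, slope = NA_real_,
               low = hk_means, high = hk_means, dependence_truth = "n/a"),
    data.frame(gene = up(cfg$n_mound_program, "mnd"), category = "background",
               direction = "up", centre = centres_mound, slope = cfg$slope,
               low = cfg$low_mean, high = cfg$high_mean,
               dependence_truth = "n/a")
  )
  # null-condition behaviour per gene: how the program changes without cAMP
  panel$ko_behaviour <- "wt"
  panel$ko_behaviour[panel$dependence_truth == "failed_repression"] <- "high_plateau"
  panel$ko_behaviour[panel$dependence_truth == "partial_induction"] <- "partial"
  panel$ko_behaviour[panel$dependence_truth == "complete_loss"] <- "low_plateau"
  panel$ko_behaviour[startsWith(panel$gene, "mnd")] <- "low_plateau"
  rownames(panel) <- NULL
  panel
}

# expected expression (counts at the median library size) per gene x cell
expected_expression <- function(panel, s, condition) {
  n_genes <- nrow(panel)
  mu <- matrix(0, n_genes, length(s))
  for (g in seq_len(n_genes)) {
    p <- panel[g, ]
    base <- switch(p$direction,
      flat = rep(p$low, length(s)),
      up = p$low + (p$high - p$low) * sigmoid(s, p$centre, p$slope),
      down = p$low + (p$high - p$low) * (1 - sigmoid(s, p$centre, p$slope))
    )
    if (condition == "acaA_null") {
      base <- switch(p$ko_behaviour,
        wt = base,
        high_plateau = rep(p$high, length(s)),             # repression fails
        partial = p$low + attr(panel, "partial_scale") *
          (p$high - p$low) * sigmoid(s, p$centre, p$slope),
        low_plateau = rep(p$low, length(s))
      )
    }
    mu[g, ] <- base
  }
  mu
}

# four-state truncated-normal mixture over pseudotime with an excluded gap
sample_pseudotime <- function(n, cfg) {
  w <- cfg$state_weights / sum(cfg$state_weights)
  states <- c("feeding", "starving", "aggregating", "mound")
  comp <- sample.int(4, n, replace = TRUE, prob = w)
  lo <- ifelse(comp <= 2, 0, cfg$jump_position + cfg$gap_halfwidth)
  hi <- ifelse(comp <= 2, cfg$jump_position - cfg$gap_halfwidth, 1)
  s <- rnorm(n, cfg$state_centres[comp], cfg$state_sds[comp])
  bad <- which(s < lo | s > hi)
  while (length(bad)) {
    s[bad] <- rnorm(length(bad), cfg$state_centres[comp[bad]],
                    cfg$state_sds[comp[bad]])
    bad <- bad[s[bad] < lo[bad] | s[bad] > hi[bad]]
  }
  list(s = s, state = states[comp])
}

#' Simulate paired single-cell count matrices
#'
#' Draws UMI count matrices for each configured condition under a shared
#' gene panel.  Every cell gets a pseudotime (its position in the
#' developmental progression; for the `acaA_null` condition this is the
#' collection-time axis of a population time course), a state label, a
#' replicate label and a log-normal library-size factor; counts are
#' negative binomial around the program mean scaled by the library factor.
#'
#' @param cfg a [counts_config()].
#' @return list of class `counts_sim` with one `count_matrix` per condition
#'   (`counts`: sparse genes x cells; `cell_meta`: `barcode`, `replicate`,
#'   `condition`, `pseudotime`, `state`, `lib_factor`), a shared
#'   `gene_truth` table and the `config`.
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "counts_config")) stop_config("cfg must be a counts_config")
  withr::with_seed(cfg$rng_seed, {
    panel <- build_gene_panel(cfg)
    attr(panel, "partial_scale") <- cfg$partial_scale
    n_cells <- sum(cfg$replicate_sizes)
    size <- 1 / cfg$dispersion
    out <- list()
    for (cond in cfg$conditions) {
      pt <- sample_pseudotime(n_cells, cfg)
      ord <- order(pt$s)                      # barcode order follows time
      s <- pt$s[ord]; state <- pt$state[ord]
      replicate <- sample(rep.int(seq_along(cfg$replicate_sizes),
                                  cfg$replicate_sizes))
      lib <- rlnorm(n_cells, 0, cfg$libsize_sdlog)
      mu <- expected_expression(panel, s, cond)
      mu <- sweep(mu, 2, lib, `*`)
      counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                       nrow = nrow(panel))
      dimnames(counts) <- list(panel$gene,
                               sprintf("%s_cell%04d", cond, seq_len(n_cells)))
      out[[cond]] <- structure(list(
        counts = Matrix::Matrix(counts, sparse = TRUE),
        cell_meta = data.frame(
          barcode = colnames(counts), replicate = replicate,
          condition = cond, pseudotime = s, state = state,
          lib_factor = lib, stringsAsFactors = FALSE),
        gene_meta = data.frame(gene = panel$gene,
                               category = panel$category,
                               stringsAsFactors = FALSE)
      ), class = "count_matrix")
    }
    structure(list(conditions = out, gene_truth = panel, config = cfg),
              class = "counts_sim")
  })
}
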
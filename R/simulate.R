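#' Parameters for the synthetic limb single-cell generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a latent differentiation pseudotime t ~ U(0,1) per cell; nested activation
#' of the five posterior Hoxd genes along t (a cell's on-set is, up to rare
#' flips, a prefix of the panel ordered by activation threshold, Hoxd13
#' switching on first); quantitative collinearity of expression levels
#' (mean expression increasing from Hoxd9 to Hoxd13); target-gene modules
#' whose means are linearly coupled to the on/off state of one panel gene;
#' a Gfp reporter coupled to Hoxd11; constant-input ERCC spike-ins distorted
#' only by per-cell capture efficiency; negative-binomial counts; a
#' multiplicative batch effect; and a contaminating fraction of low-quality
#' cells with collapsed endogenous depth and hence inflated spike fraction.
#' Zeugopod cells couple activation to t more weakly (higher flip
#' probability), so they order poorly along any recovered pseudotime.
#'
#' @param n_cells Named integer vector, cells per tissue.
#' @param n_batches Number of batches (cells assigned round-robin).
#' @param n_target_genes,n_background_genes,n_spikes Gene-universe sizes.
#' @param tau Named activation thresholds on t for the panel genes; must obey
#'   tau(Hoxd13) < tau(Hoxd11) <= tau(Hoxd12) < tau(Hoxd10) < tau(Hoxd9).
#' @param mu Named mean expression of "on" panel genes; must decrease from
#'   Hoxd13 to Hoxd9 (quantitative collinearity).
#' @param mu_off Mean of "off" panel genes (well below the calling threshold
#'   after normalization).
#' @param epsilon,zeugopod_epsilon Per-gene activation flip probabilities for
#'   autopod and zeugopod cells.
#' @param target_on,target_off Means of module target genes when their panel
#'   gene is on / off.
#' @param nb_size Negative-binomial size (dispersion = 1/size); large values
#'   approach Poisson.
#' @param capture_sdlog Lognormal sd of per-cell capture efficiency
#'   (meanlog 0).
#' @param batch_mult Multiplicative batch effect on endogenous genes,
#'   recycled over batches.
#' @param spike_mean Mean spike-in count per spike gene at capture 1.
#' @param low_quality_fraction Fraction of cells rendered low-quality
#'   (endogenous depth x `low_quality_depth`, spikes untouched). Must lie in
#'   [0, 0.5].
#' @param low_quality_depth Depth multiplier applied to low-quality cells'
#'   endogenous means.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_cells = c(autopod = 100, zeugopod = 100),
                         n_batches = 2,
                         n_target_genes = 50,
                         n_background_genes = 200,
                         n_spikes = 50,
                         tau = c(Hoxd13 = 0.10, Hoxd11 = 0.35, Hoxd12 = 0.40,
                                 Hoxd10 = 0.60, Hoxd9 = 0.80),
                         mu = c(Hoxd9 = 12, Hoxd10 = 25, Hoxd11 = 45,
                                Hoxd12 = 70, Hoxd13 = 110),
                         mu_off = 0.2,
                         epsilon = 0.02,
                         zeugopod_epsilon = 0.15,
                         target_on = 15, target_off = 2,
                         nb_size = 10,
                         capture_sdlog = 0.3,
                         batch_mult = c(1, 1.2),
                         spike_mean = 8,
                         low_quality_fraction = 0.1,
                         low_quality_depth = 0.02,
                         seed = 1) {
  p <- as.list(environment())
  ord <- c("Hoxd13", "Hoxd11", "Hoxd12", "Hoxd10", "Hoxd9")
  if (!all(ord %in% names(tau))) stop("tau must name all five panel genes")
  tv <- tau[ord]
  if (!(tv[1] < tv[2] && tv[2] <= tv[3] && tv[3] < tv[4] && tv[4] < tv[5])) {
    stop("activation thresholds out of order: need ",
         "tau(Hoxd13) < tau(Hoxd11) <= tau(Hoxd12) < tau(Hoxd10) < tau(Hoxd9)",
         call. = FALSE)
  }
  if (any(tau <= 0 | tau >= 1)) stop("thresholds must lie in (0,1)")
  mu_ord <- mu[c("Hoxd13", "Hoxd12", "Hoxd11", "Hoxd10", "Hoxd9")]
  if (any(diff(mu_ord) >= 0) || any(mu <= 0)) {
    stop("means must be strictly positive and decrease from Hoxd13 to Hoxd9")
  }
  if (low_quality_fraction < 0 || low_quality_fraction > 0.5) {
    stop("low_quality_fraction must lie in [0, 0.5]")
  }
  structure(p, class = "synth_params")
}

#' Simulate a count matrix with ground truth
#'
#' Draws a genes x cells raw count matrix (panel, reporter, Hoxa, target,
#' background and ERCC spike-in rows) plus truth labels, with the structure
#' described in [synth_params()]. Panel gene g is on in cell c iff
#' `t_c > tau_g`, XOR a Bernoulli(epsilon) flip; on-genes draw
#' NB(mu_g * capture_c * batch_c), off-genes NB(mu_off * ...); targets couple
#' linearly to their module's state; spike-ins draw from a fixed input times
#' capture only. Low-quality cells have endogenous means scaled down so they
#' fail depth/complexity QC and exceed the spike-fraction bound.
#'
#' @param params A [synth_params()] object.
#' @return A list with elements `counts` (a [hox_counts()]), `cell_truth`
#'   (tibble: cell_id, tissue, batch, embryo, t, capture, low_quality, and
#'   one logical `on_<gene>` column per panel gene) and `gene_truth`
#'   (tibble: gene_id, type, module).
#' @export
simulate_counts <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  p <- params

  panel <- c("Hoxd9", "Hoxd10", "Hoxd11", "Hoxd12", "Hoxd13")
  targets <- sprintf("Tgt%03d", seq_len(p$n_target_genes))
  background <- sprintf("Bg%03d", seq_len(p$n_background_genes))
  hoxa <- c("Hoxa9", "Hoxa10", "Hoxa11", "Hoxa13")
  spikes <- sprintf("ERCC-%05d", seq_len(p$n_spikes))
  genes <- c(panel, "Gfp", hoxa, targets, background, spikes)
  target_module <- panel[(seq_len(p$n_target_genes) - 1L) %% length(panel) + 1L]

  tissues <- rep(names(p$n_cells), p$n_cells)
  n <- length(tissues)
  cell_ids <- unlist(lapply(names(p$n_cells), function(ts) {
    sprintf("%s_c%03d", toupper(substr(ts, 1, 2)), seq_len(p$n_cells[[ts]]))
  }))
  batch <- paste0("b", (seq_len(n) - 1L) %% p$n_batches + 1L)
  embryo <- paste0("e", (seq_len(n) - 1L) %% 4L + 1L)

  t_lat <- stats::runif(n)
  capture <- stats::rlnorm(n, meanlog = 0, sdlog = p$capture_sdlog)
  n_lq <- floor(p$low_quality_fraction * n)
  low_quality <- rep(FALSE, n)
  if (n_lq > 0) low_quality[sample.int(n, n_lq)] <- TRUE

  eps <- ifelse(tissues == "zeugopod", p$zeugopod_epsilon, p$epsilon)
  on_state <- sapply(panel, function(g) {
    base <- t_lat > p$tau[[g]]
    flip <- stats::runif(n) < eps
    xor(base, flip)
  })  # n x 5 logical

  batch_eff <- p$batch_mult[(match(batch, unique(batch)) - 1L) %%
                              length(p$batch_mult) + 1L]
  depth <- ifelse(low_quality, p$low_quality_depth, 1) * capture * batch_eff

  bg_base <- stats::rlnorm(p$n_background_genes, meanlog = log(8), sdlog = 0.6)

  mean_mat <- matrix(0, nrow = length(genes), ncol = n,
                     dimnames = list(genes, cell_ids))
  for (g in panel) {
    mean_mat[g, ] <- ifelse(on_state[, g], p$mu[[g]], p$mu_off) * depth
  }
  mean_mat["Gfp", ] <- (p$target_off +
                          (25 - p$target_off) * on_state[, "Hoxd11"]) * depth
  for (g in hoxa) mean_mat[g, ] <- 3 * depth
  for (i in seq_along(targets)) {
    st <- on_state[, target_module[i]]
    mean_mat[targets[i], ] <- (p$target_off +
                                 (p$target_on - p$target_off) * st) * depth
  }
  mean_mat[background, ] <- outer(bg_base, depth)
  mean_mat[spikes, ] <- outer(rep(p$spike_mean, p$n_spikes), capture)

  vals <- matrix(
    stats::rnbinom(length(mean_mat), size = p$nb_size, mu = as.vector(mean_mat)),
    nrow = length(genes), dimnames = dimnames(mean_mat)
  )

  gene_type <- c(rep("panel", length(panel)), "reporter",
                 rep("hoxa", length(hoxa)), rep("target", length(targets)),
                 rep("background", length(background)),
                 rep("spike", length(spikes)))
  gene_module <- c(panel, "Hoxd11", rep(NA, length(hoxa)), target_module,
                   rep(NA, length(background) + length(spikes)))
  gene_meta <- tibble::tibble(
    gene_id = genes, symbol = genes,
    length_bp = as.integer(round(stats::runif(length(genes), 500, 5000))),
    is_hox = grepl("^Hox[ad]", genes)
  )
  cell_meta <- tibble::tibble(cell_id = cell_ids, tissue = tissues,
                              batch = batch, embryo = embryo)
  cm <- hox_counts(vals, cell_meta = cell_meta, gene_meta = gene_meta)

  cell_truth <- tibble::tibble(
    cell_id = cell_ids, tissue = tissues, batch = batch, embryo = embryo,
    t = t_lat, capture = capture, low_quality = low_quality
  )
  for (g in panel) cell_truth[[paste0("on_", g)]] <- on_state[, g]
  gene_truth <- tibble::tibble(gene_id = genes, type = gene_type,
                               module = gene_module)
  list(counts = cm, cell_truth = cell_truth, gene_truth = gene_truth)
}

#' QC configuration matched to the synthetic gene universe
#'
#' The published cell filters assume a genome-scale gene universe (>2000
#' detected genes); the synthetic matrix has a few hundred genes, so the
#' complexity threshold is rescaled to half the simulated gene universe
#' (healthy cells detect most genes, low-quality cells mostly spikes), while
#' the read-depth and spike-fraction bounds keep their published defaults.
#'
#' @param params The [synth_params()] the data were drawn with.
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
synth_qc_config <- function(params = synth_params(), ...) {
  n_genes <- 10L + params$n_target_genes + params$n_background_genes +
    params$n_spikes
  pipeline_config(min_genes_expressed = ceiling(0.5 * n_genes), ...)
}

#' Simulate two-channel flow-cytometry events
#'
#' Draws events from a log-normal mixture: each population contributes a
#' fraction of events with channel intensities exp(N(mean, sd)) on the log
#' scale. Population labels are retained as truth.
#'
#' @param n_events Number of events.
#' @param populations List of populations, each a list with `fraction`
#'   (fractions must sum to 1 within 1e-9), `mean` (named per channel, log
#'   scale) and `sd` (named per channel, log scale).
#' @param seed Integer seed.
#' @return A tibble with one row per event: channel columns plus
#'   `population`.
#' @export
simulate_flow_events <- function(n_events, populations, seed = 1) {
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", sum(fr), ")",
         call. = FALSE)
  }
  channels <- names(populations[[1]]$mean)
  set.seed(seed)
  if (n_events == 0) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(channels)), channels))
    out$population <- integer(0)
    return(out)
  }
  lab <- sample.int(length(populations), n_events, replace = TRUE, prob = fr)
  vals <- vapply(channels, function(ch) {
    m <- vapply(populations, function(p) p$mean[[ch]], numeric(1))[lab]
    s <- vapply(populations, function(p) p$sd[[ch]], numeric(1))[lab]
    exp(stats::rnorm(n_events, m, s))
  }, numeric(n_events))
  out <- tibble::as_tibble(as.data.frame(vals))
  out$population <- lab
  out
}
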
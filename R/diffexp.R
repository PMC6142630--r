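#' Empirical-Bayes moderated two-group test
#'
#' Per gene, ordinary two-sample statistics on log2(normalized + 1), with the
#' gene-wise residual variances shrunk towards a common prior: the prior
#' (d0, s0^2) is fitted by matching moments of log s^2_g (digamma/trigamma
#' identities for the log of a scaled chi-square, with the prior df obtained
#' by trigamma inversion), the posterior variance is
#' s~^2 = (d0 s0^2 + d_g s^2_g) / (d0 + d_g), and the moderated t uses
#' d0 + d_g degrees of freedom. Genes with zero variance in both groups get
#' p = 1 when their means agree and are flagged degenerate otherwise.
#' Significance combines an absolute log2 fold-change floor with a BH FDR
#' bound (defaults |log2FC| >= 2, adjusted p < 0.01).
#'
#' @param norm A [normalize_counts()] result.
#' @param group1,group2 Disjoint character vectors of cell ids, each of size
#'   >= 2.
#' @param cfg A [pipeline_config()].
#' @param contrast Label stored with the result.
#' @param prior Optional list `list(d0 = , s0_sq = )` overriding the fitted
#'   variance prior; `d0 = 0` gives the ordinary (unmoderated) two-sample t.
#' @return A tibble of class `hox_de`, one row per gene: `gene_id`,
#'   `mean_log2_1`, `mean_log2_2`, `log2_fc`, `t`, `df`, `p_value`,
#'   `p_adjusted`, `significant`, `degenerate`; attributes `d0`, `s0_sq`,
#'   `contrast`, `n1`, `n2`.
#' @export
moderated_two_group_test <- function(norm, group1, group2,
                                     cfg = pipeline_config(),
                                     contrast = "group1_vs_group2",
                                     prior = NULL) {
  stopifnot(inherits(norm, "hox_norm"))
  if (length(intersect(group1, group2))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 cells", call. = FALSE)
  }
  missing <- setdiff(c(group1, group2), colnames(norm$values))
  if (length(missing)) stop("unknown cells: ", paste(missing, collapse = ", "))

  x1 <- log_expr(norm, cells = group1)
  x2 <- log_expr(norm, cells = group2)
  n1 <- length(group1); n2 <- length(group2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg

  fit <- if (is.null(prior)) fit_variance_prior(s2, dg) else prior
  d0 <- fit$d0; s0_sq <- fit$s0_sq
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  } else {
    s2_post <- rep(s0_sq, length(s2))
    df_total <- Inf
  }
  delta <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  degenerate <- s2 == 0 & delta != 0
  p[s2 == 0 & delta == 0] <- 1

  padj <- bh_adjust(p)
  out <- tibble::tibble(
    gene_id = rownames(norm$values),
    mean_log2_1 = unname(m1), mean_log2_2 = unname(m2),
    log2_fc = unname(delta), t = unname(tstat), df = df_total,
    p_value = unname(p), p_adjusted = unname(padj),
    significant = unname(abs(delta) >= cfg$de_min_abs_lfc &
                           padj < cfg$de_max_fdr),
    degenerate = unname(degenerate)
  )
  class(out) <- c("hox_de", class(out))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "contrast") <- contrast
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

# Moment fit of the scaled-inverse-chi-square variance prior on log s^2.
# e_g = log s2_g - digamma(dg/2) + log(dg/2) has mean log s0^2 + digamma(d0/2)
# - log(d0/2) and excess variance trigamma(d0/2); d0 from trigamma inversion.
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = mean(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  ev <- stats::var(e) - trigamma(dg / 2)
  if (is.na(ev) || ev <= 0) {
    # no excess variability: infinite prior df, all variances equal the prior
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= the raw values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Overlap counts between significant gene sets
#'
#' Exact region counts (as in a Venn diagram) of the significant-gene sets
#' of two or more differential-expression results sharing a gene universe.
#'
#' @param results Named list of `hox_de` tibbles (>= 2) with identical
#'   `gene_id` universes.
#' @return A tibble with one row per membership region: one logical column
#'   per result plus `n_genes`.
#' @export
deg_overlap <- function(results) {
  stopifnot(length(results) >= 2)
  if (is.null(names(results))) names(results) <- paste0("set", seq_along(results))
  universe <- sort(results[[1]]$gene_id)
  for (r in results[-1]) {
    if (!identical(sort(r$gene_id), universe)) {
      stop("results do not share a gene universe", call. = FALSE)
    }
  }
  sets <- lapply(results, function(r) r$gene_id[r$significant])
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(universe, names(results)))
  keep <- rowSums(member) > 0
  if (!any(keep)) {
    out <- tibble::as_tibble(as.data.frame(member[0, , drop = FALSE]))
    out$n_genes <- integer(0)
    return(out)
  }
  region <- apply(member[keep, , drop = FALSE], 1, paste, collapse = "/")
  counts <- table(region)
  key <- do.call(rbind, strsplit(names(counts), "/"))
  out <- tibble::as_tibble(as.data.frame(key == "TRUE"))
  names(out) <- names(results)
  out$n_genes <- as.integer(counts)
  out
}
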
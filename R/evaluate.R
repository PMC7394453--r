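#' Mutual information between two volumes
#'
#' Histogram estimator: a `bins` x `bins` joint histogram of equal-width
#' bins spanning each image's masked intensity range, with
#' `MI = sum p log(p / (p_a p_b))` in nats and the `0 log 0 = 0` convention.
#' Used as a proxy for geometric alignment between a b0 and the undistorted
#' T1: the better the distortion correction, the higher the MI.
#'
#' @param a,b `b0_volume`s (or 3D arrays) on the same grid.
#' @param mask binary `b0_volume`/array; MI is computed over mask voxels.
#'   Mask count must be at least `10 * bins`.
#' @param bins number of histogram bins per image (default 64).
#' @return scalar MI in nats.
#' @export
mutual_information <- function(a, b, mask = NULL, bins = 64L) {
  av <- if (inherits(a, "b0_volume")) as.vector(a$data) else as.vector(a)
  bv <- if (inherits(b, "b0_volume")) as.vector(b$data) else as.vector(b)
  if (length(av) != length(bv)) stop("volumes must share the grid")
  m <- if (is.null(mask)) rep(TRUE, length(av))
       else (if (inherits(mask, "b0_volume")) as.vector(mask$data) else as.vector(mask)) > 0.5
  av <- av[m]; bv <- bv[m]
  if (length(av) < 10L * bins)
    stop("mask too small for ", bins, " bins: need >= ", 10L * bins, " voxels")
  ra <- range(av); rb <- range(bv)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("constant image: mutual information undefined")
  ia <- pmin(pmax(floor((av - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor((bv - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, 1L), bins)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) / length(av)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz]))
}

#' Shannon entropy of a volume's binned intensity distribution
#' @inheritParams mutual_information
#' @return scalar entropy in nats.
#' @export
binned_entropy <- function(a, mask = NULL, bins = 64L) {
  av <- if (inherits(a, "b0_volume")) as.vector(a$data) else as.vector(a)
  m <- if (is.null(mask)) rep(TRUE, length(av))
       else (if (inherits(mask, "b0_volume")) as.vector(mask$data) else as.vector(mask)) > 0.5
  av <- av[m]
  ra <- range(av)
  if (ra[1] == ra[2]) stop("constant image: entropy of binning undefined")
  ia <- pmin(pmax(floor((av - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, 1L), bins)
  p <- tabulate(ia, nbins = bins) / length(av)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Masked mean-squared error between two volumes
#'
#' @param a,b `b0_volume`s (or arrays) on the same grid.
#' @param mask binary mask; `NULL` uses all voxels.
#' @return scalar MSE.
#' @export
masked_mse <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "b0_volume")) as.vector(a$data) else as.vector(a)
  bv <- if (inherits(b, "b0_volume")) as.vector(b$data) else as.vector(b)
  if (length(av) != length(bv)) stop("volumes must share the grid")
  m <- if (is.null(mask)) rep(TRUE, length(av))
       else (if (inherits(mask, "b0_volume")) as.vector(mask$data) else as.vector(mask)) > 0.5
  if (!any(m)) stop("empty mask")
  mean((av[m] - bv[m])^2)
}

#' Evaluate a cohort of corrected subjects
#'
#' For every subject and condition (e.g. uncorrected / corrected /
#' oracle-corrected b0) computes MI with the subject's T1 (geometric
#' similarity) and MSE against the gold-standard b0 (correction plus
#' contrast accuracy), all on one shared mask per subject.  Cohort
#' summaries include per-condition means/medians, the fraction of subjects
#' whose corrected MI exceeds the uncorrected MI, and a two-sided paired
#' t-test on the MI differences.
#'
#' @param cohort list of per-subject entries: list(`id`, `t1`, `gold`,
#'   `mask`, `conditions` = named list of `b0_volume`s).  Condition names
#'   `"uncorrected"` and `"corrected"` drive the paired statistics.
#' @param bins histogram bins for MI.
#' @return object of class `eval_report`: list(`table` long data.frame,
#'   `summary` per-condition data.frame, `improvement_fraction`,
#'   `paired_t` htest or NULL).
#' @export
evaluate_cohort <- function(cohort, bins = 64L) {
  stopifnot(length(cohort) >= 1)
  cond_names <- names(cohort[[1]]$conditions)
  rows <- list()
  for (s in cohort) {
    missing <- setdiff(cond_names, names(s$conditions))
    if (length(missing) > 0)
      stop("subject ", s$id, " is missing condition(s): ",
           paste(missing, collapse = ", "))
    for (cn in cond_names) {
      v <- s$conditions[[cn]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, condition = cn,
        mi_t1 = mutual_information(v, s$t1, s$mask, bins = bins),
        mse_gold = masked_mse(v, s$gold, s$mask))
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$condition), function(g) {
    data.frame(condition = g$condition[1],
               mi_mean = mean(g$mi_t1), mi_median = stats::median(g$mi_t1),
               mse_mean = mean(g$mse_gold), mse_median = stats::median(g$mse_gold))
  }))
  rownames(summ) <- NULL
  imp <- NA_real_
  tt <- NULL
  if (all(c("uncorrected", "corrected") %in% cond_names)) {
    mi_u <- tab$mi_t1[tab$condition == "uncorrected"]
    mi_c <- tab$mi_t1[tab$condition == "corrected"]
    imp <- mean(mi_c > mi_u)
    if (length(mi_u) >= 2 && stats::sd(mi_c - mi_u) > 0)
      tt <- stats::t.test(mi_c, mi_u, paired = TRUE)
  }
  structure(list(table = tab, summary = summ, improvement_fraction = imp,
                 paired_t = tt),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Cohort evaluation (", length(unique(x$table$subject)), " subjects, ",
      length(unique(x$table$condition)), " conditions)\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$improvement_fraction))
    cat(sprintf("MI improvement fraction (corrected > uncorrected): %.2f\n",
                x$improvement_fraction))
  if (!is.null(x$paired_t))
    cat(sprintf("paired t on MI differences: t = %.3f, p = %.3g\n",
                x$paired_t$statistic, x$paired_t$p.value))
  invisible(x)
}
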
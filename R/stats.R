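#' Bootstrap estimation of a mean difference
#'
#' Estimation-plot style effect size: the difference in group means
#' `mean(groupB) - mean(groupA)` with a percentile bootstrap sampling
#' distribution and 95% confidence interval (each group resampled with
#' replacement independently). The percentile CI is the convention of
#' Gardner-Altman estimation plots; BCa is out of scope.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `estimation_result`: `mean_diff`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, and a five-number summary of the bootstrap
#'   distribution (`boot_summary`), plus the distribution itself
#'   (`boot_dist`).
#' @export
bootstrap_mean_diff <- function(group_a, group_b, n_boot = 5000, seed = 1,
                                conf = 0.95) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  na <- length(group_a)
  nb <- length(group_b)
  ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), nrow = n_boot)
  ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = n_boot)
  boot <- rowMeans(matrix(group_b[ib], nrow = n_boot)) -
    rowMeans(matrix(group_a[ia], nrow = n_boot))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(
    list(mean_diff = mean(group_b) - mean(group_a),
         ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, seed = seed, conf = conf,
         boot_summary = stats::fivenum(boot), boot_dist = boot),
    class = "estimation_result"
  )
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> mean diff %.4g, %g%% CI [%.4g, %.4g] (%d resamples)\n",
              x$mean_diff, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

# rank-sum statistic of group A under mid-ranks
.rank_sum_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)])
}

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' The rank-sum statistic of the first group under mid-ranks, with a
#' two-sided p-value from one of three null models:
#'
#' * `exact`: full enumeration of all group assignments (combined n <= 12);
#'   p = min(1, 2 min(P(W <= w), P(W >= w))).
#' * `permutation`: `n_perm` random label permutations, same two-sided
#'   doubling, with add-one smoothing ((count + 1)/(n_perm + 1) per tail).
#' * `asymptotic`: normal approximation with tie-corrected variance and
#'   continuity correction.
#'
#' Degenerate all-equal data gives p = 1.
#'
#' @param group_a,group_b numeric vectors (n >= 1 each).
#' @param mode `"exact"`, `"permutation"`, or `"asymptotic"`.
#' @param n_perm permutations for permutation mode.
#' @param seed seed for permutation mode.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(group_a, group_b,
                          mode = c("exact", "permutation", "asymptotic"),
                          n_perm = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("each group needs n >= 1", call. = FALSE)
  }
  na <- length(group_a)
  pooled <- c(group_a, group_b)
  n <- length(pooled)
  if (length(unique(pooled)) == 1L) return(1)
  w <- .rank_sum_stat(group_a, group_b)
  r <- rank(pooled)

  if (mode == "exact") {
    if (n > 12) stop("exact mode limited to combined n <= 12", call. = FALSE)
    combos <- utils::combn(n, na)
    ws <- colSums(matrix(r[combos], nrow = na))
    p_lo <- mean(ws <= w + 1e-9)
    p_hi <- mean(ws >= w - 1e-9)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  if (mode == "permutation") {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(seed)
    ws <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      sum(r[idx])
    }, numeric(1))
    p_lo <- (sum(ws <= w + 1e-9) + 1) / (n_perm + 1)
    p_hi <- (sum(ws >= w - 1e-9) + 1) / (n_perm + 1)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  # asymptotic, tie-corrected
  nb <- n - na
  mu <- na * (n + 1) / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Efficiency-corrected relative expression ratio with randomization test
#'
#' The relative expression of a target gene in the treated group versus the
#' control group, corrected for per-gene amplification efficiency and
#' normalized to the reference genes:
#'
#' \deqn{ratio = E_t^{\Delta Ct_t} / \mathrm{geomean}_r\, E_r^{\Delta Ct_r}}
#'
#' with \eqn{\Delta Ct = \bar{Ct}_{control} - \bar{Ct}_{treated}} per gene
#' and the geometric mean taken over the reference genes. Significance comes
#' from randomly reallocating group labels within each gene (preserving
#' group sizes) and recomputing the ratio `n_rand` times; the two-sided
#' p-value is the exceedance of the observed |log ratio| with add-one
#' smoothing, `(count + 1) / (n_rand + 1)`.
#'
#' @param ct a Ct table as produced by [simulate_ct_table()]: columns
#'   `gene`, `role` (`target`/`reference`), `group` (`control`/`treated`),
#'   `ct`, `efficiency`; at least 2 replicates per gene x group and at least
#'   one reference gene. Efficiencies must exceed 1.
#' @param target the target gene name.
#' @param n_rand randomizations (default 2000).
#' @param seed integer seed.
#' @return list with `ratio` and `p`.
#' @export
rest_ratio <- function(ct, target, n_rand = 2000, seed = 1) {
  ct <- tibble::as_tibble(ct)
  refs <- unique(ct$gene[ct$role == "reference"])
  if (length(refs) == 0L) stop("no reference gene in table", call. = FALSE)
  if (!target %in% ct$gene) stop("target gene not in table", call. = FALSE)
  if (any(ct$efficiency <= 1)) stop("efficiencies must be > 1", call. = FALSE)
  counts <- table(ct$gene, ct$group)
  if (any(counts < 2)) {
    stop("need >= 2 replicates per gene x group", call. = FALSE)
  }

  genes <- c(target, refs)
  sub <- lapply(genes, function(g) ct[ct$gene == g, ])
  names(sub) <- genes

  gene_factor <- function(d, grp_labels) {
    dct <- mean(d$ct[grp_labels == "control"]) -
      mean(d$ct[grp_labels == "treated"])
    d$efficiency[1]^dct
  }
  compute_ratio <- function(label_list) {
    ft <- gene_factor(sub[[target]], label_list[[target]])
    fr <- vapply(refs, function(g) gene_factor(sub[[g]], label_list[[g]]),
                 numeric(1))
    ft / exp(mean(log(fr)))
  }

  obs_labels <- lapply(sub, function(d) d$group)
  ratio <- compute_ratio(obs_labels)

  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  obs_stat <- abs(log(ratio))
  count <- 0L
  for (i in seq_len(n_rand)) {
    perm <- lapply(sub, function(d) sample(d$group))
    if (abs(log(compute_ratio(perm))) >= obs_stat - 1e-12) count <- count + 1L
  }
  list(ratio = ratio, p = (count + 1) / (n_rand + 1))
}
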
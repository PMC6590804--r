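#' Sign-flip permutation paired t-test
#'
#' Paired t-test whose null distribution is built by randomly negating the
#' paired differences (the exact null for a symmetric paired design). The
#' p-value uses the add-one rule `p = (b + 1) / (n_perm + 1)` with
#' `b = #{|t*| >= |t|}`, so it is never zero and is bounded below by
#' `1/(n_perm + 1)`. Deterministic given `seed`.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param n_perm number of sign-flip permutations (default 2000).
#' @param seed optional integer seed.
#' @return list with `t`, `df`, `p_perm`, `n_perm`, `degenerate` (TRUE when
#'   all differences are zero, in which case `t = 0`, `p_perm = 1`).
#' @export
perm_paired_t <- function(x, y, n_perm = 2000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2, n_perm >= 1)
  d <- x - y
  n <- length(d)
  if (all(d == 0))
    return(list(t = 0, df = n - 1, p_perm = 1, n_perm = n_perm,
                degenerate = TRUE))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  ss <- sum(d^2)
  t_of_mean <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v <= 0, Inf * sign(m), m / sqrt(v / n))
  }
  t_obs <- t_of_mean(mean(d))
  # sum of squares is invariant under sign flips, so t* depends only on the
  # permuted mean; draw all sign patterns as one matrix
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  t_star <- t_of_mean(as.vector(signs %*% d) / n)
  b <- sum(abs(t_star) >= abs(t_obs) - 1e-12)
  list(t = t_obs, df = n - 1, p_perm = (b + 1) / (n_perm + 1),
       n_perm = n_perm, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate within one
#' family of tests (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Two-sample (unpaired) t-test
#'
#' Welch's t by default (no equal-variance assumption); pooled-variance t on
#' request. Used for between-condition contrasts of per-subject ERSP
#' magnitudes.
#'
#' @param x,y numeric samples (each length >= 2).
#' @param var_equal use the pooled-variance statistic.
#' @return list with `t`, `df`, `p`, `degenerate` (TRUE when both samples
#'   have zero variance).
#' @export
unpaired_t <- function(x, y, var_equal = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       degenerate = FALSE)
}

#' Two-way within-subject (repeated-measures) ANOVA
#'
#' Both factors are manipulated within every subject; the subject is the
#' blocking unit. Sums of squares are decomposed on the per-subject cell
#' means and each effect is tested against its own subject-interaction error
#' term (A against A x subject, B against B x subject, A x B against
#' A x B x subject), without sphericity correction. For factors with a and b
#' levels and n subjects the effect/error degrees of freedom are
#' (a-1, (a-1)(n-1)), (b-1, (b-1)(n-1)) and ((a-1)(b-1), (a-1)(b-1)(n-1)).
#'
#' @param data data frame holding one value per subject x factor cell (if
#'   several rows per cell are present, e.g. trials, they are averaged
#'   first).
#' @param dv name of the response column.
#' @param subject,factor_a,factor_b names of the subject and factor columns.
#' @return An `anova_table` data frame: `effect`, `df_num`, `df_den`, `ss`,
#'   `ms`, `F`, `p`.
#' @export
rm_anova <- function(data, dv, subject = "subject", factor_a = "pool",
                     factor_b = "distance") {
  stopifnot(all(c(dv, subject, factor_a, factor_b) %in% names(data)))
  s <- factor(data[[subject]]); a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]]); y <- data[[dv]]
  ns <- nlevels(s); na <- nlevels(a); nb <- nlevels(b)
  if (ns < 2) stop("within-subject ANOVA needs >= 2 subjects")
  cells <- tapply(y, list(s, a, b), mean)
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    stop("incomplete design; missing cell(s): ",
         paste(apply(miss, 1, function(i)
           paste0("(", levels(s)[i[1]], ", ", levels(a)[i[2]], ", ",
                  levels(b)[i[3]], ")")), collapse = " "))
  }
  gm <- mean(cells)
  m_s <- apply(cells, 1, mean); m_a <- apply(cells, 2, mean)
  m_b <- apply(cells, 3, mean)
  m_sa <- apply(cells, c(1, 2), mean); m_sb <- apply(cells, c(1, 3), mean)
  m_ab <- apply(cells, c(2, 3), mean)

  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_as <- nb * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + gm)^2)
  ss_bs <- na * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + gm)^2)
  resid <- cells
  for (i in seq_len(ns)) for (j in seq_len(na)) for (k in seq_len(nb))
    resid[i, j, k] <- cells[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - gm
  ss_abs <- sum(resid^2)

  df <- list(a = c(na - 1, (na - 1) * (ns - 1)),
             b = c(nb - 1, (nb - 1) * (ns - 1)),
             ab = c((na - 1) * (nb - 1), (na - 1) * (nb - 1) * (ns - 1)))
  row <- function(effect, ss_eff, ss_err, dd) {
    f <- (ss_eff / dd[1]) / (ss_err / dd[2])
    data.frame(effect = effect, df_num = dd[1], df_den = dd[2],
               ss = ss_eff, ms = ss_eff / dd[1], F = f,
               p = stats::pf(f, dd[1], dd[2], lower.tail = FALSE))
  }
  out <- rbind(row(factor_a, ss_a, ss_as, df$a),
               row(factor_b, ss_b, ss_bs, df$b),
               row(paste0(factor_a, ":", factor_b), ss_ab, ss_abs, df$ab))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Bonferroni-adjusted pairwise post-hoc contrasts
#'
#' All pairwise paired t-tests between the levels of one within-subject
#' factor, on per-subject means (averaged over trials and the other factor).
#' Raw p-values are multiplied by the number of comparisons and capped at 1.
#'
#' @param data data frame with subject, factor and response columns.
#' @param dv response column name.
#' @param subject,factor column names.
#' @return data frame: `level_1`, `level_2`, `t`, `df`, `p_raw`, `p_bonf`.
#' @export
posthoc_bonferroni <- function(data, dv, subject = "subject",
                               factor = "distance") {
  s <- factor(data[[subject]]); f <- factor(data[[factor]])
  if (nlevels(f) < 2) stop("post-hoc contrasts need >= 2 factor levels")
  m <- tapply(data[[dv]], list(s, f), mean)
  pairs <- utils::combn(levels(f), 2)
  n_cmp <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_cmp), function(k) {
    x <- m[, pairs[1, k]]; y <- m[, pairs[2, k]]
    d <- x - y
    if (stats::sd(d) == 0) {
      return(data.frame(level_1 = pairs[1, k], level_2 = pairs[2, k],
                        t = 0, df = length(d) - 1, p_raw = 1, p_bonf = 1))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(level_1 = pairs[1, k], level_2 = pairs[2, k],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_bonf = min(1, tt$p.value * n_cmp))
  }))
  rownames(out) <- NULL
  out
}
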
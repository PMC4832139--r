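#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Classical within-subject one-way ANOVA for a subjects x conditions matrix
#' of one kernel property: `F = MS_condition / MS_(condition x subject)` with
#' `df = (k-1, (k-1)(n-1))`, partial eta squared
#' `SS_cond / (SS_cond + SS_err)`, Mauchly's sphericity test on the k-1
#' orthonormal contrasts (chi-square approximation), and the
#' Greenhouse-Geisser epsilon from the contrast covariance, with the
#' epsilon-corrected p value `pf(F, eps*df1, eps*df2)`.
#'
#' @param m numeric matrix or data frame, subjects in rows (n >= 3),
#'   conditions in columns (k >= 2; 3 in the standard design: express,
#'   regular, explicit).
#' @return list: `F, df1, df2, p, partial_eta_sq, mauchly_W, mauchly_p,
#'   gg_epsilon, corrected_p, flag` (`flag` is `"zero_error_variance"` when F
#'   is undefined, else `NA`).
#' @export
rm_anova_one_way <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("rm_anova_one_way: need at least 3 subjects", call. = FALSE)
  if (k < 2) stop("rm_anova_one_way: need at least 2 conditions",
                  call. = FALSE)
  if (any(!is.finite(m))) stop("rm_anova_one_way: missing cells",
                               call. = FALSE)

  grand <- mean(m)
  col_m <- colMeans(m)
  row_m <- rowMeans(m)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2

  flag <- NA_character_
  if (ms_err <= 0) {
    if (ss_cond == 0) {
      f_stat <- 0; p <- 1
    } else {
      f_stat <- NA_real_; p <- NA_real_
    }
    flag <- "zero_error_variance"
  } else {
    f_stat <- ms_cond / ms_err
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  eta <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0

  # orthonormal contrasts of the conditions
  C <- contr_helmert_orthonormal(k)
  S <- t(C) %*% stats::cov(m) %*% C
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  p_c <- k - 1

  if (any(lam <= 0) || sum(lam) <= 0) {
    W <- NA_real_; mauchly_p <- NA_real_
    eps <- NA_real_; corrected_p <- NA_real_
    if (is.na(flag)) flag <- "singular_contrast_covariance"
  } else {
    W <- prod(lam) / (sum(lam) / p_c)^p_c
    df_w <- p_c * (p_c + 1) / 2 - 1
    fc <- (2 * p_c^2 + p_c + 2) / (6 * p_c * (n - 1))
    chisq <- -(n - 1) * (1 - fc) * log(W)
    mauchly_p <- if (df_w > 0)
      stats::pchisq(chisq, df_w, lower.tail = FALSE) else NA_real_
    eps <- sum(lam)^2 / (p_c * sum(lam^2))
    corrected_p <- if (is.finite(f_stat))
      stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
    else NA_real_
  }

  list(F = f_stat, df1 = df1, df2 = df2, p = p,
       partial_eta_sq = eta,
       mauchly_W = W, mauchly_p = mauchly_p,
       gg_epsilon = eps, corrected_p = corrected_p,
       flag = flag)
}

# normalized Helmert contrasts: k x (k-1), columns orthonormal and orthogonal
# to the unit vector
contr_helmert_orthonormal <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Paired two-tailed t test
#'
#' Classical paired t statistic `t = mean(d) / (sd(d)/sqrt(n))` on the
#' differences `d = a - b`, with `df = n - 1`. Degenerate cases are flagged:
#' identical vectors give `t = 0, p = 1` (flag `"zero_variance"`); a constant
#' nonzero difference has undefined t (`NA`, same flag).
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return list: `t, df, p, mean_diff, flag`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired_t: lengths differ", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("paired_t: need at least 2 pairs", call. = FALSE)
  d <- a - b
  s <- stats::sd(d)
  md <- mean(d)
  if (s == 0) {
    if (md == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                  flag = "zero_variance"))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, mean_diff = md,
                flag = "zero_variance"))
  }
  t_stat <- md / (s / sqrt(n))
  list(t = t_stat, df = n - 1,
       p = 2 * stats::pt(abs(t_stat), n - 1, lower.tail = FALSE),
       mean_diff = md, flag = NA_character_)
}

#' Group statistics over a kernel table
#'
#' Runs one [rm_anova_one_way()] per kernel property (area, eccentricity,
#' shift, orientation) on a subjects x conditions layout extracted from a
#' kernel table, plus uncorrected post-hoc paired t tests between condition
#' pairs (a Holm adjustment of the post-hoc p values is available but off by
#' default, matching the convention of reporting uncorrected pairwise tests).
#'
#' @param kernels data frame in [kernel_row()] layout (`subject, category`,
#'   property columns).
#' @param conditions ordered categories forming the within-subject factor.
#' @param properties kernel properties to analyze.
#' @param holm apply Holm adjustment to post-hoc p values.
#' @return list with `anova` (data frame, one row per property) and
#'   `post_hoc` (data frame of pairwise paired t tests).
#' @export
kernel_stats <- function(kernels,
                         conditions = c("express_only", "regular_only",
                                        "explicit_only"),
                         properties = c("area", "eccentricity", "shift",
                                        "orientation"),
                         holm = FALSE) {
  res <- list(); ph <- list()
  for (prop in properties) {
    mat <- property_matrix(kernels, prop, conditions)
    a <- rm_anova_one_way(mat)
    res[[prop]] <- data.frame(property = prop, F = a$F, df1 = a$df1,
                              df2 = a$df2, p = a$p,
                              eta_p2 = a$partial_eta_sq,
                              mauchly_W = a$mauchly_W,
                              mauchly_p = a$mauchly_p,
                              gg_eps = a$gg_epsilon,
                              corrected_p = a$corrected_p)
    pairs <- utils::combn(conditions, 2, simplify = FALSE)
    for (pr in pairs) {
      tt <- paired_t(mat[, pr[1]], mat[, pr[2]])
      ph[[length(ph) + 1L]] <- data.frame(property = prop,
                                          a = pr[1], b = pr[2],
                                          t = tt$t, df = tt$df, p = tt$p)
    }
  }
  post_hoc <- do.call(rbind, ph)
  if (holm) {
    for (prop in properties) {
      sel <- post_hoc$property == prop
      post_hoc$p[sel] <- stats::p.adjust(post_hoc$p[sel], method = "holm")
    }
  }
  list(anova = do.call(rbind, res), post_hoc = post_hoc)
}

#' Subjects x conditions matrix for one kernel property
#'
#' @param kernels kernel table ([kernel_row()] layout).
#' @param property column name of the property.
#' @param conditions ordered condition (category) names.
#' @return numeric matrix, subjects in rows, `conditions` in columns.
#' @export
property_matrix <- function(kernels, property,
                            conditions = c("express_only", "regular_only",
                                           "explicit_only")) {
  subjects <- sort(unique(kernels$subject))
  m <- matrix(NA_real_, length(subjects), length(conditions),
              dimnames = list(subjects, conditions))
  for (i in seq_along(subjects)) {
    for (j in seq_along(conditions)) {
      v <- kernels[kernels$subject == subjects[i] &
                     kernels$category == conditions[j], property]
      if (length(v) == 1) m[i, j] <- v
    }
  }
  if (any(is.na(m)))
    stop("property_matrix: missing cells (every subject needs every ",
         "condition)", call. = FALSE)
  m
}

#' Write the group-statistics tables
#' @param stats result of [kernel_stats()].
#' @param dir output directory.
#' @export
write_stats <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(stats$anova, file.path(dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(stats$post_hoc, file.path(dir, "post_hoc.csv"),
                   row.names = FALSE)
  invisible(dir)
}
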
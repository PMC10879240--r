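#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For tie-free samples with n1 + n2 <= 12 the
#' p-value comes from the exact null distribution of U; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. The branch taken is recorded in `method`.
#'
#' @param x,y numeric samples.
#' @return list `u` (U statistic for `x`), `p_value` (two-sided),
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  all_vals <- c(x, y)
  if (length(unique(all_vals)) == 1L) {
    warning("all values identical across both samples", call. = FALSE)
    return(list(u = n1 * n2 / 2, p_value = 1, method = "degenerate"))
  }
  rk <- rank(all_vals)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_vals))
  if (!ties && n1 + n2 <= 12L) {
    # exact: two-sided p as twice the smaller tail, capped at 1
    p <- 2 * min(pwilcox(u1, n1, n2),
                 1 - pwilcox(u1 - 1, n1, n2))
    return(list(u = u1, p_value = min(1, p), method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(all_vals)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  list(u = u1, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal_approx")
}

#' Cohen's d with confidence interval
#'
#' d = (mean(x) - mean(y)) / s_pooled, with the pooled-variance standard
#' deviation. The 95% CI uses the normal-approximation standard error
#' SE = sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2))).
#'
#' @param x,y numeric samples with >= 2 values each.
#' @param conf confidence level.
#' @return list `d`, `ci_low`, `ci_high`, `se`, `undefined` (TRUE when
#'   the pooled sd is zero).
#' @export
cohens_d <- function(x, y, conf = 0.95) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    return(list(d = NaN, ci_low = NaN, ci_high = NaN, se = NaN,
                undefined = TRUE))
  }
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  zc <- qnorm(1 - (1 - conf) / 2)
  list(d = d, ci_low = d - zc * se, ci_high = d + zc * se, se = se,
       undefined = FALSE)
}

#' Cohen's f-squared from a determination coefficient
#'
#' f^2 = R^2 / (1 - R^2); `Inf` (flagged) at R^2 = 1.
#'
#' @param r_squared determination coefficient in `[0, 1]`.
#' @return f-squared value.
#' @export
cohens_f2 <- function(r_squared) {
  stopifnot(all(r_squared >= 0), all(r_squared <= 1))
  ifelse(r_squared < 1, r_squared / (1 - r_squared), Inf)
}

#' Rotated PCA lipid signature with factor-score ANOVA
#'
#' Variables are z-scored, the correlation matrix eigendecomposed, the
#' retained loadings varimax-rotated, factor scores obtained by the
#' regression method, and each rotated component's scores submitted to a
#' one-way ANOVA on group.
#'
#' @param mat numeric matrix/data.frame, subjects x variables.
#' @param groups factor/character of group labels per subject.
#' @param n_components components to retain (default 2).
#' @return list `loadings` (rotated, variables x components),
#'   `variance_fraction` (per retained component, unrotated eigenvalue
#'   share of total variance), `rotated_variance_fraction`, `scores`
#'   (subjects x components, zero column mean), `anova_f`, `anova_p`,
#'   `dropped` (constant variables removed).
#' @export
pca_signature <- function(mat, groups, n_components = 2) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 3, nrow(mat) == length(groups))
  sds <- apply(mat, 2, sd)
  dropped <- colnames(mat)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[, !(colnames(mat) %in% dropped), drop = FALSE]
  }
  Z <- scale(mat)
  Rcor <- cor(mat)
  eig <- eigen(Rcor, symmetric = TRUE)
  k <- min(n_components, ncol(mat))
  evals <- pmax(eig$values, 0)
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(evals[seq_len(k)]), k)
  rownames(L) <- colnames(mat)
  if (k > 1) {
    rot <- varimax(L)
    Lr <- L %*% rot$rotmat
  } else {
    Lr <- L
  }
  colnames(Lr) <- paste0("PC", seq_len(k))
  # regression-method factor scores: Z R^- L (pseudoinverse: closed
  # compositional tables make R exactly singular)
  W <- MASS::ginv(Rcor) %*% Lr
  scores <- Z %*% W
  colnames(scores) <- colnames(Lr)
  groups <- factor(groups)
  av <- lapply(seq_len(k), function(j) {
    a <- anova(lm(scores[, j] ~ groups))
    c(f = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  list(
    loadings = Lr,
    variance_fraction = evals[seq_len(k)] / sum(evals),
    rotated_variance_fraction = colSums(Lr^2) / sum(evals),
    scores = scores,
    anova_f = vapply(av, `[`, numeric(1), "f"),
    anova_p = vapply(av, `[`, numeric(1), "p"),
    dropped = dropped,
    eigenvalues = evals
  )
}

#' Per-group correlation heatmap with between-group difference effect sizes
#'
#' Pearson r and R^2 per (row variable, column variable) pair within each
#' group, plus a difference map: Cohen's q = |z(r1) - z(r2)| via the
#' Fisher transform (the package's interpretation of an effect size for
#' a between-group correlation difference).
#'
#' @param cohort a `raft_cohort` (may be augmented with extra columns).
#' @param row_vars,col_vars column names to correlate.
#' @param groups pair of group labels to contrast.
#' @return list with per-group `r` and `r_squared` matrices (rows =
#'   `row_vars`), and `q_diff` of Cohen's q values. Zero-variance pairs
#'   are `NA`.
#' @export
correlation_heatmap <- function(cohort, row_vars, col_vars,
                                groups = c("NSL", "ALS")) {
  per_group <- lapply(groups, function(gl) {
    sub <- cohort[cohort$group == gl, , drop = FALSE]
    if (nrow(sub) < 3) stop("need >= 3 subjects in group ", gl, call. = FALSE)
    r <- matrix(NA_real_, length(row_vars), length(col_vars),
                dimnames = list(row_vars, col_vars))
    for (a in row_vars) for (b in col_vars) {
      xa <- sub[[a]]; xb <- sub[[b]]
      if (sd(xa) > 0 && sd(xb) > 0) r[a, b] <- cor(xa, xb)
    }
    r
  })
  names(per_group) <- groups
  z <- function(r) atanh(pmin(pmax(r, -0.999999), 0.999999))
  q <- abs(z(per_group[[1]]) - z(per_group[[2]]))
  list(r = per_group,
       r_squared = lapply(per_group, function(m) m^2),
       q_diff = q)
}

#' Per-group regression slopes and slope-heterogeneity test
#'
#' Ordinary least squares slope of y on x within each group, with the
#' heterogeneity F statistic taken from the group-by-x interaction term
#' of the pooled two-slope model (1 and n - 4 degrees of freedom) — the
#' ANCOVA test of homogeneity of regression slopes.
#'
#' @param x,y numeric vectors.
#' @param groups group label per observation (exactly two levels).
#' @return list `beta_by_group`, `intercept_by_group`,
#'   `r_squared_by_group`, `f_stat`, `p_value`, `df`.
#' @export
compare_slopes <- function(x, y, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, length(x) == length(y),
            length(x) == length(groups))
  for (gl in levels(groups)) {
    xs <- x[groups == gl]
    if (sum(groups == gl) < 3) stop("need >= 3 subjects in group ", gl,
                                    call. = FALSE)
    if (sd(xs) == 0) stop("x has no variance within group ", gl,
                          call. = FALSE)
  }
  per <- lapply(levels(groups), function(gl) {
    f <- lm(y[groups == gl] ~ x[groups == gl])
    c(beta = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
      r2 = summary(f)$r.squared)
  })
  names(per) <- levels(groups)
  pooled <- lm(y ~ x * groups)
  a <- anova(pooled)
  irow <- which(rownames(a) == "x:groups")
  list(
    beta_by_group = vapply(per, `[`, numeric(1), "beta"),
    intercept_by_group = vapply(per, `[`, numeric(1), "intercept"),
    r_squared_by_group = vapply(per, `[`, numeric(1), "r2"),
    f_stat = a$`F value`[irow],
    p_value = a$`Pr(>F)`[irow],
    df = c(a$Df[irow], a$Df[nrow(a)])
  )
}

#' Effect-size forest table
#'
#' Per token: Cohen's d (sign convention NSL minus ALS, so a decrease in
#' ALS plots positive), its 95% CI, Mann-Whitney U and two-sided p,
#' percent change of the ALS mean relative to NSL, and a large-effect
#' flag at |d| > 0.8.
#'
#' @param cohort a `raft_cohort`.
#' @param tokens columns to test; defaults to every species, class and
#'   derived-index column (indexes are computed and appended).
#' @param include_indexes append the derived indexes to the candidate
#'   token set.
#' @return data.frame, one row per token: `token`, `d`, `ci_low`,
#'   `ci_high`, `u_stat`, `p_value`, `pct_change`, `large_effect`.
#' @export
forest_table <- function(cohort, tokens = NULL, include_indexes = TRUE) {
  stopifnot(all(c("NSL", "ALS") %in% cohort$group))
  dat <- as.data.frame(cohort, check.names = FALSE)
  if (include_indexes) {
    idx <- derive_indexes(cohort)
    dat <- cbind(dat, idx[, setdiff(names(idx), c("subject_id", "group")),
                          drop = FALSE])
  }
  if (is.null(tokens)) {
    tokens <- setdiff(names(dat), COHORT_META)
  }
  rows <- lapply(tokens, function(tok) {
    xn <- dat[[tok]][dat$group == "NSL"]
    xa <- dat[[tok]][dat$group == "ALS"]
    d <- cohens_d(xn, xa)
    mw <- suppressWarnings(mann_whitney(xn, xa))
    data.frame(
      token = tok, d = d$d, ci_low = d$ci_low, ci_high = d$ci_high,
      u_stat = mw$u, p_value = mw$p_value,
      pct_change = 100 * (mean(xa) / mean(xn) - 1),
      large_effect = is.finite(d$d) && abs(d$d) > 0.8,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment helper for a forest table
#'
#' Off by default in the pipeline (raw Mann-Whitney p-values are
#' reported); provided for users who want FDR control.
#'
#' @param forest a [forest_table()] result.
#' @return the table with a `p_adjusted` column.
#' @export
adjust_forest_fdr <- function(forest) {
  forest$p_adjusted <- stats::p.adjust(forest$p_value, method = "BH")
  forest
}
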